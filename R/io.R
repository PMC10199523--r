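#' Write a genome assembly as FASTA with index and type map
#'
#' Writes `<path>` (FASTA, fixed line width), `<path>.fai` (the standard
#' 5-column index: name, length, byte offset of the first sequence line,
#' bases per line, bytes per line) and, when `types_path` is given, a
#' 2-column chromosome-type TSV.
#'
#' @param genome A [genome_assembly()].
#' @param path Output FASTA path.
#' @param types_path Optional path for the chromosome-type map TSV.
#' @param width FASTA line width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, types_path = NULL,
                               width = 70) {
  stopifnot(inherits(genome, "genome_assembly"))
  Biostrings::writeXStringSet(genome$seqs, path, width = width)
  lens <- chrom_lengths(genome)
  offset <- 0
  fai <- character(length(lens))
  for (i in seq_along(lens)) {
    header <- nchar(names(lens)[i]) + 2L  # ">" and newline
    nlines <- ceiling(lens[i] / width)
    fai[i] <- paste(names(lens)[i], lens[i], offset + header, width,
                    width + 1L, sep = "\t")
    offset <- offset + header + lens[i] + nlines
  }
  writeLines(fai, paste0(path, ".fai"))
  if (!is.null(types_path)) {
    utils::write.table(genome$chrom_types, types_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a genome assembly from FASTA and a type map
#'
#' @param path FASTA path.
#' @param types_path Chromosome-type TSV (`chrom`, `type`).
#' @return A [genome_assembly()].
#' @export
read_genome_fasta <- function(path, types_path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  types <- utils::read.table(types_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  genome_assembly(seqs, types)
}

#' Write markers and genotypes as VCF
#'
#' Minimal VCF 4.2 with a GT field. With `hap1`/`hap2` supplied the
#' genotypes are written phased (`0|1`); otherwise unphased dosage codes
#' are written (`0/1`), `NA` as `./.`.
#'
#' @param markers Marker data.frame (`marker_id`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param path Output path.
#' @param genotypes Optional dosage matrix (individuals x markers).
#' @param hap1,hap2 Optional phased allele matrices.
#' @return `path`, invisibly.
#' @export
write_markers_vcf <- function(markers, path, genotypes = NULL,
                              hap1 = NULL, hap2 = NULL) {
  phased <- !is.null(hap1) && !is.null(hap2)
  header <- c("##fileformat=VCFv4.2",
              "##source=radseqsim",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  gt <- NULL
  if (phased) {
    ids <- rownames(hap1)
    gt <- matrix(paste0(t(hap1), "|", t(hap2)), nrow = ncol(hap1))
    colnames(gt) <- ids
  } else if (!is.null(genotypes)) {
    ids <- rownames(genotypes)
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    g <- t(genotypes)
    gt <- matrix("./.", nrow(g), ncol(g), dimnames = list(NULL, ids))
    ok <- !is.na(g)
    gt[ok] <- code[as.character(g[ok])]
  }
  if (!is.null(gt)) cols <- c(cols, "FORMAT", colnames(gt))
  body <- data.frame(markers$chrom, markers$pos, markers$marker_id,
                     markers$ref, markers$alt, ".", ".", ".",
                     stringsAsFactors = FALSE)
  if (!is.null(gt)) body <- cbind(body, "GT", as.data.frame(gt))
  lines <- c(header, paste(cols, collapse = "\t"),
             do.call(paste, c(body, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read markers (and genotypes) from a VCF
#'
#' Parses the minimal GT-only VCF written by [write_markers_vcf()] (or
#' any plain-text VCF whose first FORMAT key is GT). Phased and unphased
#' genotypes are both returned as dosage codes; phase is preserved in
#' `hap1`/`hap2` when every genotype is phased.
#'
#' @param path VCF path.
#' @return List with `markers`, `genotypes` (or NULL), and `hap1`,
#'   `hap2` when fully phased.
#' @export
read_markers_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- utils::read.table(con, header = TRUE, sep = "\t",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(tab)[1] <- "CHROM"
  markers <- data.frame(marker_id = as.character(tab$ID),
                        chrom = as.character(tab$CHROM),
                        pos = as.integer(tab$POS),
                        ref = as.character(tab$REF),
                        alt = as.character(tab$ALT),
                        stringsAsFactors = FALSE)
  out <- list(markers = markers, genotypes = NULL)
  if ("FORMAT" %in% names(tab) && ncol(tab) > 9) {
    sample_cols <- setdiff(names(tab), c("CHROM", "POS", "ID", "REF",
                                         "ALT", "QUAL", "FILTER", "INFO",
                                         "FORMAT"))
    gtfield <- vapply(tab[sample_cols], function(col)
      sub(":.*$", "", col), character(nrow(tab)))
    if (nrow(tab) == 1) gtfield <- matrix(gtfield, nrow = 1)
    phased <- all(grepl("\\|", gtfield))
    a1 <- substr(gtfield, 1, 1)
    a2 <- substr(gtfield, 3, 3)
    dose <- matrix(NA_integer_, nrow(tab), length(sample_cols))
    ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
    dose[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
    genotypes <- t(dose)
    dimnames(genotypes) <- list(sample_cols, markers$marker_id)
    out$genotypes <- genotypes
    if (phased) {
      h1 <- t(matrix(as.integer(a1), nrow(tab), length(sample_cols)))
      h2 <- t(matrix(as.integer(a2), nrow(tab), length(sample_cols)))
      dimnames(h1) <- dimnames(h2) <- dimnames(genotypes)
      out$hap1 <- h1
      out$hap2 <- h2
    }
  }
  out
}

#' Write read windows as 6-column BED
#'
#' 0-based half-open intervals; name = `fragment_id/read`, score =
#' fragment size, strand ".".
#'
#' @param windows A `window_table` from [make_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$win_start, windows$win_end,
                    paste0(windows$fragment_id, "/", windows$read),
                    windows$win_end - windows$win_start, ".",
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED of read windows
#' @param path BED path.
#' @return A `window_table`.
#' @export
read_windows_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  name <- strsplit(bed$V4, "/", fixed = TRUE)
  out <- data.frame(chrom = bed$V1, win_start = bed$V2, win_end = bed$V3,
                    fragment_id = vapply(name, `[`, "", 1),
                    read = as.integer(vapply(name, `[`, "", 2)),
                    stringsAsFactors = FALSE)
  class(out) <- c("window_table", "data.frame")
  out
}

#' Write and read simple delimited tables
#'
#' Pedigree and phenotype tables are plain CSV; the panel list is one
#' marker id per line.
#'
#' @param x Object to write.
#' @param path File path.
#' @return `path` (writers, invisibly) or the parsed object (readers).
#' @name tables_io
NULL

#' @rdname tables_io
#' @export
write_pedigree_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tables_io
#' @export
read_pedigree_csv <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  ped$sire[ped$sire %in% c("", "NA", "0")] <- NA
  ped$dam[ped$dam %in% c("", "NA", "0")] <- NA
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @rdname tables_io
#' @export
write_panel_list <- function(x, path) {
  writeLines(x, path)
  invisible(path)
}

#' @rdname tables_io
#' @export
read_panel_list <- function(path) readLines(path)
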