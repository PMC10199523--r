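#' Genome assembly with chromosome type labels
#'
#' Bundles chromosome sequences (a [Biostrings::DNAStringSet]) with a
#' chromosome-type map assigning each chromosome to one of the avian size
#' classes: `macro`, `intermediate`, `micro` or `Z`. The classes matter
#' because micro-chromosomes are short, GC-rich and gene dense, so
#' GC-containing recognition sites cut them more often per Mb.
#'
#' @param seqs A `DNAStringSet` (or named character vector) of chromosome
#'   sequences.
#' @param chrom_types data.frame with columns `chrom` and `type`; `type`
#'   must be one of `macro`, `intermediate`, `micro`, `Z`.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(seqs, chrom_types) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(methods::is(seqs, "DNAStringSet"),
            !is.null(names(seqs)), all(nzchar(names(seqs))),
            is.data.frame(chrom_types),
            all(c("chrom", "type") %in% names(chrom_types)))
  chrom_types$chrom <- as.character(chrom_types$chrom)
  chrom_types$type <- as.character(chrom_types$type)
  if (!setequal(names(seqs), chrom_types$chrom)) {
    stop("chromosome names in sequences and type map differ")
  }
  if (!all(chrom_types$type %in% chromosome_types())) {
    stop("chromosome types must be one of: ",
         paste(chromosome_types(), collapse = ", "))
  }
  chrom_types <- chrom_types[match(names(seqs), chrom_types$chrom), ,
                             drop = FALSE]
  rownames(chrom_types) <- NULL
  structure(list(seqs = seqs, chrom_types = chrom_types),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  len <- chrom_lengths(x)
  cat("<genome_assembly> ", length(len), " chromosome(s), ",
      format(sum(len), big.mark = ","), " bp total\n", sep = "")
  df <- data.frame(chrom = names(len), type = x$chrom_types$type,
                   length = unname(len),
                   gc = round(gc_content(x), 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Recognised chromosome type labels
#' @return Character vector of labels.
#' @export
chromosome_types <- function() c("macro", "intermediate", "micro", "Z")

#' Chromosome lengths of a genome assembly
#' @param genome A [genome_assembly()].
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  stats::setNames(Biostrings::width(genome$seqs), names(genome$seqs))
}

#' GC content per chromosome
#' @param genome A [genome_assembly()].
#' @return Named numeric vector of GC fractions (ambiguous bases excluded
#'   from the denominator).
#' @export
gc_content <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  freq <- Biostrings::alphabetFrequency(genome$seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  stats::setNames(rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt,
                  names(genome$seqs))
}
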