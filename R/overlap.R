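#' Extract markers falling inside paired-end read windows
#'
#' A marker at 1-based position `p` is detected if `win_start < p <=
#' win_end` for at least one window (a 1-based point inside a 0-based
#' half-open interval). A marker covered by both reads of a fragment, or
#' by windows of several fragments, is reported once.
#'
#' @param markers Marker data.frame with columns `marker_id`, `chrom`,
#'   `pos` (1-based).
#' @param windows A `window_table` from [make_windows()].
#' @return The subset of `markers` inside at least one window, original
#'   order preserved.
#' @export
extract_snps_in_windows <- function(markers, windows) {
  stopifnot(all(c("chrom", "pos") %in% names(markers)),
            all(c("chrom", "win_start", "win_end") %in% names(windows)))
  if (nrow(markers) == 0 || nrow(windows) == 0) {
    return(markers[integer(0), , drop = FALSE])
  }
  keep <- logical(nrow(markers))
  for (ch in unique(markers$chrom)) {
    mi <- which(markers$chrom == ch)
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (nrow(w) == 0) next
    q <- IRanges::IRanges(markers$pos[mi], markers$pos[mi])
    s <- IRanges::IRanges(w$win_start + 1L, w$win_end)
    hit <- IRanges::overlapsAny(q, s)
    keep[mi] <- hit
  }
  out <- markers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between detected markers and a chip panel
#'
#' Marker identity is `(chrom, pos)`: the physical position match used
#' when comparing sequencing-detected variants with array markers. The
#' shared proportion is reported on the detected denominator, as a
#' percentage at two decimals.
#'
#' @param detected Marker data.frame of detected variants.
#' @param panel Either a character vector of panel marker ids or a marker
#'   data.frame with `marker_id` (ids are of the form `chrom_pos` when
#'   produced by this package; otherwise supply a data.frame with `chrom`
#'   and `pos`).
#' @param markers Optional full marker data.frame used to resolve panel
#'   ids to `(chrom, pos)` when `panel` is an id vector.
#' @return List with `n_detected`, `n_panel`, `n_shared`,
#'   `proportion_shared` (percent, 2 decimals) and `shared` (data.frame of
#'   shared markers).
#' @export
overlap_with_panel <- function(detected, panel, markers = NULL) {
  key <- function(df) paste(df$chrom, df$pos, sep = ":")
  if (is.character(panel)) {
    if (is.null(markers)) {
      stop("supply 'markers' to resolve panel ids to positions")
    }
    panel <- markers[markers$marker_id %in% panel, , drop = FALSE]
  }
  stopifnot(all(c("chrom", "pos") %in% names(panel)))
  dk <- key(detected); pk <- key(panel)
  shared <- detected[dk %in% pk, , drop = FALSE]
  rownames(shared) <- NULL
  n_det <- nrow(detected)
  list(n_detected = n_det,
       n_panel = nrow(panel),
       n_shared = nrow(shared),
       proportion_shared = if (n_det > 0)
         percent_of(nrow(shared), n_det) else NA_real_,
       shared = shared)
}

#' Marker density per chromosome type
#'
#' Per chromosome, markers per Mb; per type, the mean and sample standard
#' deviation across chromosomes of that type. A singleton type (the Z
#' chromosome) is reported with `sd = NA` since there is nothing to vary
#' across.
#'
#' @param markers Marker data.frame with `chrom`.
#' @param genome A [genome_assembly()].
#' @return List with `per_chrom` and `per_type` data.frames.
#' @export
snp_density_by_type <- function(markers, genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  lens <- chrom_lengths(genome)
  if (any(lens == 0)) stop("zero-length chromosome")
  counts <- table(factor(markers$chrom, levels = names(lens)))
  per_chrom <- data.frame(
    chrom = names(lens), type = genome$chrom_types$type,
    n_snps = as.integer(counts),
    per_mb = as.numeric(counts) / (unname(lens) / 1e6),
    stringsAsFactors = FALSE)
  per_type <- do.call(rbind, lapply(
    split(per_chrom, per_chrom$type), function(d) {
      data.frame(type = d$type[1], n_chrom = nrow(d),
                 mean_per_mb = mean(d$per_mb),
                 sd_per_mb = if (nrow(d) > 1) stats::sd(d$per_mb) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    }))
  per_type <- per_type[order(match(per_type$type, chromosome_types())), ,
                       drop = FALSE]
  rownames(per_type) <- NULL
  list(per_chrom = per_chrom, per_type = per_type)
}

#' Distances between consecutive markers, by chromosome type
#'
#' Per chromosome, the distances between consecutive marker positions
#' (never crossing a chromosome boundary); per type, the mean of the
#' per-chromosome mean distances and its sample standard deviation across
#' chromosomes, in kb. Chromosomes carrying fewer than two markers are
#' excluded with a warning.
#'
#' @param markers Marker data.frame with `chrom`, `pos`.
#' @param genome A [genome_assembly()] (for the type map).
#' @return List with `per_chrom` (chrom, type, n_snps, mean_kb) and
#'   `per_type` (type, n_chrom, mean_kb, sd_kb) data.frames.
#' @export
inter_snp_distances <- function(markers, genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  tmap <- genome$chrom_types
  parts <- lapply(tmap$chrom, function(ch) {
    p <- sort(markers$pos[markers$chrom == ch])
    if (length(p) < 2) {
      warning("chromosome ", ch, " has fewer than 2 markers; skipped")
      return(NULL)
    }
    data.frame(chrom = ch, type = tmap$type[tmap$chrom == ch],
               n_snps = length(p), mean_kb = mean(diff(p)) / 1000,
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, parts)
  if (is.null(per_chrom)) {
    stop("no chromosome has 2 or more markers")
  }
  per_type <- do.call(rbind, lapply(
    split(per_chrom, per_chrom$type), function(d) {
      data.frame(type = d$type[1], n_chrom = nrow(d),
                 mean_kb = mean(d$mean_kb),
                 sd_kb = if (nrow(d) > 1) stats::sd(d$mean_kb) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    }))
  per_type <- per_type[order(match(per_type$type, chromosome_types())), ,
                       drop = FALSE]
  rownames(per_type) <- NULL
  list(per_chrom = per_chrom, per_type = per_type)
}

#' Fragments required to tag a genome at a given LD extent
#'
#' One well-placed fragment per LD block suffices to tag the variation in
#' that block, so the required number of fragments is the genome size
#' divided by the extent of useful linkage disequilibrium, rounded to the
#' nearest integer.
#'
#' @param genome_size_bp Genome size in bp.
#' @param ld_extent_bp Extent of useful LD (r2 > 0.3) in bp.
#' @return Integer fragment count.
#' @export
#' @examples
#' required_fragment_count(1e9, 100e3)
required_fragment_count <- function(genome_size_bp, ld_extent_bp) {
  stopifnot(genome_size_bp > 0, ld_extent_bp > 0)
  as.integer(round(genome_size_bp / ld_extent_bp))
}
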