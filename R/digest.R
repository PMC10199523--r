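#' Scan a genome for restriction sites
#'
#' Finds every start position where the (possibly degenerate) recognition
#' sequence matches, including overlapping matches. Matching is
#' case-insensitive on the forward strand only, which is exact for
#' reverse-complement-closed recognition sets (enforced by [enzyme()]).
#' Ambiguous bases (`N`) in the genome never match.
#'
#' @param x A [genome_assembly()], a `DNAStringSet`, or a character vector
#'   of sequences.
#' @param enz An [enzyme()] specification.
#' @return A `site_list`: data.frame with columns `chrom`, `start` (0-based
#'   position of the first base of the match) and `enzyme`, sorted by
#'   chromosome then position.
#' @export
#' @examples
#' scan_sites("GAATTCAAGAATTC", radseq_enzymes()$EcoRI)
scan_sites <- function(x, enz) {
  stopifnot(inherits(enz, "enzyme_spec"))
  seqs <- as_seqset(x)
  res <- lapply(names(seqs), function(ch) {
    m <- Biostrings::matchPattern(
      enz$recognition, seqs[[ch]],
      fixed = c(pattern = FALSE, subject = TRUE))
    st <- IRanges::start(m) - 1L
    data.frame(chrom = rep(ch, length(st)),
               start = st,
               enzyme = rep(enz$name, length(st)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("site_list", "data.frame")
  out
}

#' @keywords internal
as_seqset <- function(x) {
  if (inherits(x, "genome_assembly")) return(x$seqs)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- if (length(x) == 1) "seq" else
      paste0("seq", seq_along(x))
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) {
    s <- Biostrings::DNAStringSet(x)
    names(s) <- "seq"
    return(s)
  }
  stop("cannot interpret 'x' as genome sequence(s)")
}

empty_fragment_table <- function() {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    left_enzyme = character(), right_enzyme = character(),
                    size = integer(), stringsAsFactors = FALSE)
  class(out) <- c("fragment_table", "data.frame")
  out
}

#' Build fragments from a single-enzyme digest
#'
#' One fragment per pair of consecutive sites on a chromosome (k sites give
#' k - 1 fragments). Fragment coordinates run from the start of the left
#' recognition site to the start of the right recognition site; terminal
#' segments before the first and after the last site are not sequencable
#' fragments (no enzyme site at both ends) and are excluded.
#'
#' @param sites A `site_list` from [scan_sites()] (one enzyme).
#' @return A `fragment_table`: data.frame with columns `chrom`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), `left_enzyme`,
#'   `right_enzyme`, `size`.
#' @export
build_fragments_single <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "start", "enzyme") %in% names(sites)))
  if (length(unique(sites$enzyme)) > 1) {
    stop("single-enzyme fragment construction received sites from ",
         "multiple enzymes; use build_fragments_double()")
  }
  if (nrow(sites) == 0) return(empty_fragment_table())
  parts <- lapply(split(sites, sites$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    k <- nrow(s)
    if (k < 2) return(NULL)
    data.frame(chrom = s$chrom[1],
               start = s$start[-k], end = s$start[-1],
               left_enzyme = s$enzyme[-k], right_enzyme = s$enzyme[-1],
               stringsAsFactors = FALSE)
  })
  finish_fragments(do.call(rbind, parts))
}

#' Build fragments from a double digest (ddRADseq rule)
#'
#' All sites of both enzymes are merged and sorted; a fragment is emitted
#' for each pair of consecutive sites whose enzyme labels differ. Intervals
#' flanked by two sites of the same enzyme cannot be sequenced in a
#' ddRADseq library and are dropped, which is why the double-digest
#' fragment set is not the union of the two single digests.
#'
#' @param sitesA,sitesB `site_list`s for two distinct enzymes.
#' @return A `fragment_table` (see [build_fragments_single()]) in which
#'   `left_enzyme != right_enzyme` on every row.
#' @export
build_fragments_double <- function(sitesA, sitesB) {
  enzA <- unique(sitesA$enzyme); enzB <- unique(sitesB$enzyme)
  if (length(intersect(enzA, enzB)) > 0) {
    stop("double digest requires two distinct enzymes")
  }
  sites <- rbind(as.data.frame(sitesA), as.data.frame(sitesB))
  if (nrow(sites) == 0) return(empty_fragment_table())
  parts <- lapply(split(sites, sites$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    k <- nrow(s)
    if (k < 2) return(NULL)
    keep <- s$enzyme[-k] != s$enzyme[-1]
    if (!any(keep)) return(NULL)
    data.frame(chrom = s$chrom[1],
               start = s$start[-k][keep], end = s$start[-1][keep],
               left_enzyme = s$enzyme[-k][keep],
               right_enzyme = s$enzyme[-1][keep],
               stringsAsFactors = FALSE)
  })
  finish_fragments(do.call(rbind, parts))
}

#' @keywords internal
finish_fragments <- function(fr) {
  if (is.null(fr) || nrow(fr) == 0) return(empty_fragment_table())
  fr$size <- fr$end - fr$start
  fr <- fr[order(fr$chrom, fr$start), , drop = FALSE]
  rownames(fr) <- NULL
  class(fr) <- c("fragment_table", "data.frame")
  fr
}

#' Size-select fragments
#'
#' Retains fragments whose size is within `[min_bp, max_bp]`, both bounds
#' inclusive. The default 200-500 bp window is the fragment length range
#' suited to paired-end short-read sequencing.
#'
#' @param fragments A `fragment_table`.
#' @param min_bp,max_bp Inclusive size bounds in bp.
#' @return The filtered `fragment_table`.
#' @export
size_select <- function(fragments, min_bp = 200, max_bp = 500) {
  stopifnot(min_bp <= max_bp)
  out <- fragments[fragments$size >= min_bp & fragments$size <= max_bp, ,
                   drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_table", "data.frame")
  out
}

#' Paired-end read windows for selected fragments
#'
#' For each fragment, emits the read-1 window covering the first
#' `read_length` bp from the fragment start and the read-2 window covering
#' the last `read_length` bp before the fragment end. For fragments shorter
#' than `2 * read_length` the two windows overlap.
#'
#' @param fragments A size-selected `fragment_table`; every fragment must
#'   be at least `read_length` bp.
#' @param read_length Read length in bp (default 150).
#' @return A `window_table`: data.frame with columns `chrom`, `win_start`,
#'   `win_end` (0-based half-open), `fragment_id`, `read` (1 or 2), sorted
#'   by chromosome and start, ready to be written as BED.
#' @export
make_windows <- function(fragments, read_length = 150) {
  if (nrow(fragments) == 0) {
    out <- data.frame(chrom = character(), win_start = integer(),
                      win_end = integer(), fragment_id = character(),
                      read = integer(), stringsAsFactors = FALSE)
    class(out) <- c("window_table", "data.frame")
    return(out)
  }
  if (any(fragments$size < read_length)) {
    stop("all fragments must be at least read_length bp; size-select first")
  }
  fid <- sprintf("%s:%d-%d", fragments$chrom, fragments$start,
                 fragments$end)
  out <- data.frame(
    chrom = rep(fragments$chrom, 2L),
    win_start = c(fragments$start, fragments$end - read_length),
    win_end = c(fragments$start + read_length, fragments$end),
    fragment_id = rep(fid, 2L),
    read = rep(1:2, each = nrow(fragments)),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$win_start, out$read), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_table", "data.frame")
  out
}

#' Fragment summaries per chromosome, chromosome type and overall
#'
#' Computes, on the size-selected set, the fragment count and density
#' (fragments per Mb) per chromosome; the mean and sample standard
#' deviation of the per-chromosome densities within each chromosome type
#' (singleton types, e.g. the single Z chromosome, report sd 0); and the
#' overall total fragment count, in-window count and in-window percentage
#' at two decimals.
#'
#' @param fragments The full (unselected) `fragment_table`.
#' @param genome A [genome_assembly()] providing lengths and the
#'   chromosome-type map.
#' @param min_bp,max_bp Inclusive size-selection bounds.
#' @return List with elements `per_chrom` (data.frame), `per_type`
#'   (data.frame with `type`, `n_chrom`, `mean_per_mb`, `sd_per_mb`) and
#'   `overall` (list with `total_fragments`, `in_window_fragments`,
#'   `percent_in_window`).
#' @export
fragment_stats <- function(fragments, genome, min_bp = 200, max_bp = 500) {
  stopifnot(inherits(genome, "genome_assembly"))
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(fragments$chrom), names(lens))
  if (length(unknown) > 0) {
    stop("fragments on chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "))
  }
  sel <- size_select(fragments, min_bp, max_bp)
  counts <- table(factor(sel$chrom, levels = names(lens)))
  per_chrom <- data.frame(
    chrom = names(lens),
    type = genome$chrom_types$type,
    length_bp = unname(lens),
    n_fragments = as.integer(counts),
    per_mb = as.numeric(counts) / (unname(lens) / 1e6),
    stringsAsFactors = FALSE)
  per_type <- do.call(rbind, lapply(
    split(per_chrom, per_chrom$type), function(d) {
      data.frame(type = d$type[1], n_chrom = nrow(d),
                 mean_per_mb = mean(d$per_mb), sd_per_mb = sd0(d$per_mb),
                 stringsAsFactors = FALSE)
    }))
  per_type <- per_type[order(match(per_type$type, chromosome_types())), ,
                       drop = FALSE]
  rownames(per_type) <- NULL
  list(per_chrom = per_chrom,
       per_type = per_type,
       overall = list(
         total_fragments = nrow(fragments),
         in_window_fragments = nrow(sel),
         percent_in_window = percent_of(nrow(sel), max(nrow(fragments), 1))))
}

#' Run a complete in silico digest
#'
#' Convenience wrapper: site scanning (one or two enzymes), fragment
#' construction (single-enzyme or ddRADseq rule), size selection and
#' paired-end window extraction.
#'
#' @param genome A [genome_assembly()].
#' @param enz Primary [enzyme()].
#' @param enz2 Optional second enzyme for a double digest.
#' @param min_bp,max_bp Inclusive size-selection bounds.
#' @param read_length Paired-end read length in bp.
#' @return List with `sites` (named list of site_lists), `fragments`
#'   (full table), `selected` (size-selected table), `windows`
#'   (window_table) and `stats` (from [fragment_stats()]).
#' @export
digest_genome <- function(genome, enz, enz2 = NULL,
                          min_bp = 200, max_bp = 500, read_length = 150) {
  sitesA <- scan_sites(genome, enz)
  if (is.null(enz2)) {
    sites <- stats::setNames(list(sitesA), enz$name)
    fragments <- build_fragments_single(sitesA)
  } else {
    sitesB <- scan_sites(genome, enz2)
    sites <- stats::setNames(list(sitesA, sitesB), c(enz$name, enz2$name))
    fragments <- build_fragments_double(sitesA, sitesB)
  }
  selected <- size_select(fragments, min_bp, max_bp)
  windows <- make_windows(selected, read_length)
  list(sites = sites, fragments = fragments, selected = selected,
       windows = windows,
       stats = fragment_stats(fragments, genome, min_bp, max_bp))
}
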