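#' Build a haplotype library from phased reference individuals
#'
#' Deduplicates the reference haplotypes per chromosome, recording how
#' often each distinct haplotype occurs and which individuals carry it,
#' plus the marker allele frequencies of the reference set. The input must
#' be truly phased (two allele matrices); the library is lossless: every
#' input haplotype is one of its rows.
#'
#' @param hap1,hap2 Integer 0/1 matrices (reference individuals x
#'   markers), the two phased haplotypes per individual. Pass the
#'   ground-truth haplotypes of a simulated population, or externally
#'   phased data.
#' @param markers Marker data.frame (`marker_id`, `chrom`, `pos`) matching
#'   the matrix columns.
#' @return A `haplotype_library`: per chromosome, a list with `haps`
#'   (distinct haplotypes x markers), `count`, `carriers` (list of
#'   carrier ids per haplotype) and `freq` (reference alternate-allele
#'   frequency per marker).
#' @export
build_library <- function(hap1, hap2, markers) {
  if (is.null(hap1) || is.null(hap2)) {
    stop("phased haplotypes are required; supply simulation truth or ",
         "externally phased data")
  }
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            identical(dim(hap1), dim(hap2)),
            identical(colnames(hap1), markers$marker_id))
  if (nrow(hap1) == 0) {
    stop("the haplotype library needs at least one reference individual")
  }
  ids <- rownames(hap1)
  lib <- lapply(split(seq_len(nrow(markers)), markers$chrom), function(idx) {
    H <- rbind(hap1[, idx, drop = FALSE], hap2[, idx, drop = FALSE])
    carrier <- rep(ids, 2)
    key <- apply(H, 1, paste0, collapse = "")
    first <- !duplicated(key)
    haps <- H[first, , drop = FALSE]
    rownames(haps) <- NULL
    kf <- key[first]
    count <- as.integer(table(key)[kf])
    carriers <- split(carrier, factor(key, levels = kf))
    list(haps = haps, count = count,
         carriers = unname(carriers)[match(kf, names(carriers))] ,
         freq = colMeans(rbind(hap1[, idx, drop = FALSE],
                               hap2[, idx, drop = FALSE])))
  })
  structure(list(by_chrom = lib,
                 markers = markers,
                 reference_ids = ids),
            class = "haplotype_library")
}

#' @export
print.haplotype_library <- function(x, ...) {
  n <- vapply(x$by_chrom, function(l) nrow(l$haps), integer(1))
  cat("<haplotype_library> ", length(x$reference_ids),
      " reference individuals; distinct haplotypes per chromosome: ",
      paste(n, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# score(c, h) = number of typed markers where haplotype h is inconsistent
# with candidate genotype g: g = 0 forces allele 0, g = 2 forces allele 1,
# g = 1 is compatible with either.
hap1_violations <- function(G, H) {
  A0 <- (!is.na(G) & G == 0) * 1
  A2 <- (!is.na(G) & G == 2) * 1
  A0 %*% t(H) + A2 %*% t(1 - H)
}

#' Impute candidates to the full marker set with a haplotype library
#'
#' A deterministic greedy window matcher: the typed markers of each
#' chromosome are cut into windows of `window_sizes[1]` typed markers with
#' 50% overlap; within each window the library haplotype most consistent
#' with the candidate's observed genotypes is selected as the first
#' haplotype (ties broken towards haplotypes carried by the candidate's
#' parents, then the most frequent, then the lowest index), then the
#' second haplotype most consistent with the residual dosage. If the pair
#' explains every typed genotype in the window exactly, the window's
#' untyped markers are filled with the pair's dosage; a marker covered by
#' two overlapping consistent windows keeps the value of the earlier one
#' (majority vote with ties to the earlier window). Markers left unfilled
#' fall through to the next smaller window size, and finally to the
#' allele-frequency fill `round(2p)`. Typed markers are always passed
#' through unchanged, so a fully typed candidate is returned as-is.
#'
#' @param cand Integer matrix (candidates x all markers) with `NA` at
#'   untyped markers.
#' @param library A [build_library()] result over the same markers.
#' @param pedigree Optional pedigree; when given, the sire and dam of each
#'   candidate seed the tie-break preference.
#' @param window_sizes Decreasing integer vector of window sizes in typed
#'   markers (default `c(64, 32, 16, 8)`).
#' @return Integer matrix of complete dosages in `{0, 1, 2}`, same
#'   dimensions as `cand`.
#' @export
impute_candidates <- function(cand, library, pedigree = NULL,
                              window_sizes = c(64, 32, 16, 8)) {
  stopifnot(inherits(library, "haplotype_library"),
            identical(colnames(cand), library$markers$marker_id),
            all(diff(window_sizes) < 0) || length(window_sizes) == 1)
  markers <- library$markers
  out <- cand
  chrom_idx <- split(seq_len(nrow(markers)), markers$chrom)
  for (ch in names(chrom_idx)) {
    idx <- chrom_idx[[ch]]
    lib <- library$by_chrom[[ch]]
    Gc <- cand[, idx, drop = FALSE]
    out[, idx] <- impute_chromosome(Gc, lib, pedigree, window_sizes,
                                    rownames(cand))
  }
  storage.mode(out) <- "integer"
  out
}

#' @keywords internal
impute_chromosome <- function(G, lib, pedigree, window_sizes, cand_ids) {
  n_cand <- nrow(G); n_mark <- ncol(G)
  H <- lib$haps
  fallback <- pmin(pmax(round(2 * lib$freq), 0), 2)
  filled <- !is.na(G)          # typed markers stay as observed
  res <- G
  typed <- which(colSums(!is.na(G)) > 0)
  if (length(typed) == 0 || nrow(H) == 0) {
    if (nrow(H) == 0 || length(typed) == 0) {
      warning("no typed markers or empty library on a chromosome; ",
              "frequency fill used throughout")
    }
    for (j in seq_len(n_mark)) res[!filled[, j], j] <- fallback[j]
    return(res)
  }
  maxfreq <- max(lib$count)
  M <- (maxfreq + 2)^2
  # parental tie-break preference
  P <- matrix(0, n_cand, nrow(H))
  if (!is.null(pedigree)) {
    par_of <- pedigree[match(cand_ids, pedigree$id), c("sire", "dam")]
    for (h in seq_len(nrow(H))) {
      carr <- lib$carriers[[h]]
      hit <- (par_of$sire %in% carr) | (par_of$dam %in% carr)
      P[hit, h] <- 1
    }
  }
  tie <- sweep(P * (maxfreq + 1), 2, lib$count, "+")

  for (w in window_sizes) {
    if (all(filled)) break
    nt <- length(typed)
    starts <- if (nt <= w) 1L else
      unique(c(seq(1L, nt - w + 1L, by = max(1L, w %/% 2L)), nt - w + 1L))
    for (si in seq_along(starts)) {
      s <- starts[si]
      tw <- typed[s:min(s + w - 1L, nt)]
      # genomic span: from the previous typed marker boundary (or chrom
      # start) to the next (or chrom end), so untyped flanks are covered
      lo <- if (s == 1L) 1L else tw[1]
      hi <- if (s + w - 1L >= nt) n_mark else tw[length(tw)]
      span <- lo:hi
      need <- which(rowSums(!filled[, span, drop = FALSE]) > 0)
      if (length(need) == 0) next
      Gw <- G[need, tw, drop = FALSE]
      Hw <- H[, tw, drop = FALSE]
      V1 <- hap1_violations(Gw, Hw)
      score1 <- V1 * M - tie[need, , drop = FALSE]
      h1 <- max.col(-score1, ties.method = "first")
      for (h in unique(h1)) {
        rows <- which(h1 == h)
        Gs <- Gw[rows, , drop = FALSE]
        r <- sweep(Gs, 2, Hw[h, ], "-")      # required h2 allele
        bad <- !is.na(r) & (r < 0 | r > 1)   # h1 already inconsistent
        R0 <- (!is.na(r) & r == 0) * 1
        R1 <- (!is.na(r) & r == 1) * 1
        V2 <- R0 %*% t(Hw) + R1 %*% t(1 - Hw) + rowSums(bad)
        score2 <- V2 * M - tie[need[rows], , drop = FALSE]
        h2 <- max.col(-score2, ties.method = "first")
        consistent <- V2[cbind(seq_along(rows), h2)] == 0
        if (!any(consistent)) next
        cr <- rows[consistent]
        dose <- sweep(H[h2[consistent], span, drop = FALSE], 2,
                      H[h, span], "+")
        tofill <- !filled[need[cr], span, drop = FALSE]
        block <- res[need[cr], span, drop = FALSE]
        block[tofill] <- dose[tofill]
        res[need[cr], span] <- block
        filled[need[cr], span] <- TRUE
      }
    }
  }
  for (j in seq_len(n_mark)) {
    miss <- is.na(res[, j])
    if (any(miss)) res[miss, j] <- fallback[j]
  }
  res
}

#' SNP-wise imputation accuracy report
#'
#' Pearson correlation between true and imputed dosage codes, computed
#' marker by marker across candidates; markers with zero variance in
#' either vector have an undefined correlation and are excluded from the
#' mean (and counted). The overall accuracy is the mean of the remaining
#' per-marker correlations; per chromosome type, the mean of the
#' per-chromosome mean correlations and its sample standard deviation
#' across chromosomes are reported (a singleton type such as Z has no
#' sd).
#'
#' @param true,imputed Dosage matrices (same individuals x markers).
#' @param markers Marker data.frame matching the columns.
#' @param chrom_types Optional data.frame (`chrom`, `type`) for the
#'   per-type aggregation.
#' @return List with `per_marker` (data.frame `marker_id`, `chrom`, `r`),
#'   `mean_correlation`, `n_excluded_zero_variance`, and `per_type` when
#'   types are supplied.
#' @export
snpwise_accuracy <- function(true, imputed, markers, chrom_types = NULL) {
  shared <- intersect(rownames(true), rownames(imputed))
  if (length(shared) == 0) stop("no overlapping individuals")
  stopifnot(identical(colnames(true), colnames(imputed)),
            identical(colnames(true), markers$marker_id))
  x <- true[shared, , drop = FALSE]
  y <- imputed[shared, , drop = FALSE]
  n <- length(shared)
  sx <- colSums(x); sy <- colSums(y)
  sxx <- colSums(x^2); syy <- colSums(y^2); sxy <- colSums(x * y)
  vx <- sxx - sx^2 / n; vy <- syy - sy^2 / n
  r <- (sxy - sx * sy / n) / sqrt(vx * vy)
  r[vx <= 1e-12 | vy <= 1e-12] <- NA_real_
  per_marker <- data.frame(marker_id = markers$marker_id,
                           chrom = markers$chrom, r = unname(r),
                           stringsAsFactors = FALSE)
  out <- list(per_marker = per_marker,
              mean_correlation = mean(r, na.rm = TRUE),
              n_excluded_zero_variance = sum(is.na(r)))
  if (!is.null(chrom_types)) {
    per_chrom <- do.call(rbind, lapply(
      split(per_marker, per_marker$chrom), function(d) {
        data.frame(chrom = d$chrom[1], mean_r = mean(d$r, na.rm = TRUE),
                   stringsAsFactors = FALSE)
      }))
    per_chrom$type <- chrom_types$type[match(per_chrom$chrom,
                                             chrom_types$chrom)]
    per_type <- do.call(rbind, lapply(
      split(per_chrom, per_chrom$type), function(d) {
        data.frame(type = d$type[1], n_chrom = nrow(d),
                   mean_r = mean(d$mean_r),
                   sd_r = if (nrow(d) > 1) stats::sd(d$mean_r) else
                     NA_real_,
                   stringsAsFactors = FALSE)
      }))
    per_type <- per_type[order(match(per_type$type, chromosome_types())), ,
                         drop = FALSE]
    rownames(per_type) <- NULL
    out$per_chrom <- per_chrom
    out$per_type <- per_type
  }
  out
}
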