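#' Genotype matrix with marker metadata
#'
#' Dosage codes count alternate alleles: 0, 1, 2 or `NA` for a missing
#' call. Rows are individuals, columns markers; the marker table travels
#' with the matrix so location-based filters can resolve chromosomes.
#'
#' @param codes Integer matrix (individuals x markers) over
#'   `{0, 1, 2, NA}` with row and column names.
#' @param markers Marker data.frame with `marker_id` matching the matrix
#'   columns, and `chrom`, `pos`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(codes, markers) {
  stopifnot(is.matrix(codes), !is.null(rownames(codes)),
            !is.null(colnames(codes)),
            all(codes %in% c(0L, 1L, 2L, NA)),
            is.data.frame(markers), "marker_id" %in% names(markers),
            identical(colnames(codes), markers$marker_id))
  structure(list(codes = codes, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$codes), " individuals x ",
      ncol(x$codes), " markers (",
      round(100 * mean(is.na(x$codes)), 2), "% missing)\n", sep = "")
  invisible(x)
}

qc_entry <- function(step, removed, unit, threshold) {
  data.frame(step = step, removed = as.integer(removed), unit = unit,
             threshold = threshold, stringsAsFactors = FALSE)
}

drop_markers <- function(gm, drop) {
  gm$codes <- gm$codes[, !drop, drop = FALSE]
  gm$markers <- gm$markers[!drop, , drop = FALSE]
  rownames(gm$markers) <- NULL
  gm
}

#' Filter individuals on call rate
#'
#' Removes individuals whose fraction of non-missing calls is strictly
#' below the threshold (an individual at exactly the threshold is kept).
#'
#' @param gm A [genotype_matrix()].
#' @param threshold Minimum call rate in (0, 1].
#' @return List with the filtered `gm` and a one-row `report` data.frame.
#' @export
filter_individual_call_rate <- function(gm, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  cr <- rowMeans(!is.na(gm$codes))
  drop <- cr < threshold
  if (all(drop)) stop("all individuals removed by call-rate filter")
  gm$codes <- gm$codes[!drop, , drop = FALSE]
  list(gm = gm,
       report = qc_entry(sprintf("Individual call rate (< %g%%)",
                                 100 * threshold),
                         sum(drop), "individuals", threshold))
}

#' Alternate-allele frequencies of a genotype matrix
#' @keywords internal
alt_freq <- function(gm) colMeans(gm$codes, na.rm = TRUE) / 2

#' Filter markers on minor allele frequency
#'
#' The minor allele frequency is `min(p, 1 - p)` with `p` the alternate
#' allele frequency computed on non-missing calls of the currently
#' retained individuals; markers with MAF strictly below `min_maf` are
#' removed. Called with a tiny `min_maf` this removes exactly the
#' monomorphic markers.
#'
#' @param gm A [genotype_matrix()].
#' @param min_maf Minimum MAF (strict).
#' @param label Optional report label.
#' @return List with filtered `gm` and `report`.
#' @export
filter_maf <- function(gm, min_maf = 0.05, label = NULL) {
  p <- alt_freq(gm)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # marker with no calls at all
  drop <- maf < min_maf
  if (is.null(label)) label <- sprintf("MAF (< %g)", min_maf)
  list(gm = drop_markers(gm, drop),
       report = qc_entry(label, sum(drop), "markers", min_maf))
}

#' Filter markers on call rate
#'
#' Mirror of [filter_individual_call_rate()] across individuals: markers
#' with a strictly lower fraction of non-missing calls are removed.
#'
#' @param gm A [genotype_matrix()].
#' @param threshold Minimum call rate in (0, 1].
#' @return List with filtered `gm` and `report`.
#' @export
filter_snp_call_rate <- function(gm, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  cr <- colMeans(!is.na(gm$codes))
  drop <- cr < threshold
  list(gm = drop_markers(gm, drop),
       report = qc_entry(sprintf("SNP call rate (< %g%%)", 100 * threshold),
                         sum(drop), "markers", threshold))
}

#' Exact two-sided Hardy-Weinberg equilibrium test
#'
#' The exact test conditional on the observed allele counts: under random
#' union of gametes the heterozygote count follows the classical
#' `2^k`-weighted hypergeometric-type distribution, and the two-sided
#' p-value sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed count. This is the
#' standard exact HWE test used by genotype-QC tools, preferred over the
#' chi-square approximation for the low-count markers it is applied to.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact two-sided p-value (1 for an empty or monomorphic marker).
#' @export
#' @examples
#' hwe_exact_test(50, 0, 50)   # extreme heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(1)
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  n_minor <- min(nA, nB)
  if (n_minor == 0) return(1)
  ks <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- ks * log(2) + lfactorial(n) + lfactorial(nA) + lfactorial(nB) -
    lfactorial((nA - ks) / 2) - lfactorial(ks) -
    lfactorial((nB - ks) / 2) - lfactorial(2 * n)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[ks == n_Aa]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

#' Filter markers on Hardy-Weinberg disequilibrium
#'
#' Removes markers whose exact HWE p-value (see [hwe_exact_test()]),
#' computed on non-missing calls, is strictly below `alpha`.
#'
#' @param gm A [genotype_matrix()].
#' @param alpha Significance threshold (default 1e-4).
#' @param method `"exact"` (default) or `"chisq"` for the chi-square
#'   approximation.
#' @return List with filtered `gm` and `report`.
#' @export
filter_hwe <- function(gm, alpha = 1e-4, method = c("exact", "chisq")) {
  method <- match.arg(method)
  pvals <- apply(gm$codes, 2, function(g) {
    g <- g[!is.na(g)]
    nAA <- sum(g == 2); nAa <- sum(g == 1); naa <- sum(g == 0)
    if (method == "exact") return(hwe_exact_test(nAA, nAa, naa))
    n <- length(g)
    if (n == 0) return(1)
    p <- (2 * nAA + nAa) / (2 * n)
    if (p == 0 || p == 1) return(1)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stats::pchisq(sum((c(nAA, nAa, naa) - e)^2 / e), df = 1,
                  lower.tail = FALSE)
  })
  drop <- pvals < alpha
  list(gm = drop_markers(gm, drop),
       report = qc_entry(sprintf("Hardy-Weinberg equilibrium (P < %g)",
                                 alpha),
                         sum(drop), "markers", alpha))
}

#' Filter markers by genomic location
#'
#' Removes markers with an unknown location (missing or "unknown"
#' chromosome) and markers on an excluded chromosome list (e.g.
#' hard-to-impute chromosomes or the sex chromosome not carried by all
#' individuals).
#'
#' @param gm A [genotype_matrix()].
#' @param excluded_chroms Character vector of chromosome names to drop.
#' @param drop_unplaced Drop markers with `NA`/"unknown" chromosome
#'   (default TRUE).
#' @return List with filtered `gm` and a two-row `report` (unplaced,
#'   excluded).
#' @export
filter_by_location <- function(gm, excluded_chroms = character(),
                               drop_unplaced = TRUE) {
  ch <- gm$markers$chrom
  unplaced <- if (drop_unplaced) is.na(ch) | ch %in% c("", "unknown") else
    rep(FALSE, length(ch))
  rep1 <- qc_entry("SNP with unknown location", sum(unplaced), "markers",
                   NA)
  gm <- drop_markers(gm, unplaced)
  excl <- gm$markers$chrom %in% excluded_chroms
  label2 <- if (length(excluded_chroms) > 0) {
    paste0("SNP on excluded chromosome(s): ",
           paste(excluded_chroms, collapse = ","))
  } else "SNP on excluded chromosome(s)"
  rep2 <- qc_entry(label2, sum(excl), "markers", NA)
  list(gm = drop_markers(gm, excl), report = rbind(rep1, rep2))
}

#' Mendelian consistency check on parent-offspring pairs
#'
#' Counts opposing-homozygote conflicts (parent 0 with offspring 2, or
#' parent 2 with offspring 0) for every genotyped parent-offspring pair.
#' Gene-dropped genotypes without genotyping error are conflict-free, so
#' any positive count flags either pedigree or genotyping errors. The
#' check reports; it does not remove.
#'
#' @param gm A [genotype_matrix()].
#' @param pedigree Pedigree data.frame (`id`, `sire`, `dam`).
#' @return data.frame with `offspring`, `parent`, `relation`,
#'   `n_conflicts`, `n_compared`.
#' @export
mendel_check <- function(gm, pedigree) {
  ids <- rownames(gm$codes)
  out <- list()
  for (i in seq_len(nrow(pedigree))) {
    off <- pedigree$id[i]
    if (!(off %in% ids)) next
    for (rel in c("sire", "dam")) {
      par <- pedigree[[rel]][i]
      if (is.na(par) || !(par %in% ids)) next
      g_off <- gm$codes[off, ]
      g_par <- gm$codes[par, ]
      ok <- !is.na(g_off) & !is.na(g_par)
      confl <- sum((g_par[ok] == 0 & g_off[ok] == 2) |
                     (g_par[ok] == 2 & g_off[ok] == 0))
      out[[length(out) + 1]] <- data.frame(
        offspring = off, parent = par, relation = rel,
        n_conflicts = confl, n_compared = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(offspring = character(), parent = character(),
                      relation = character(), n_conflicts = integer(),
                      n_compared = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Run the full genotype QC chain
#'
#' Applies, in order: individual call rate, monomorphic-marker removal,
#' MAF, SNP call rate, exact HWE, location filters, and a Mendelian
#' consistency report. Allele frequencies and call rates are recomputed
#' after each step, so the chain is a sequence of successive filters; run
#' on its own output it removes nothing.
#'
#' @param gm A [genotype_matrix()].
#' @param pedigree Optional pedigree for the Mendelian report.
#' @param excluded_chroms Chromosomes to exclude.
#' @param ind_cr,snp_cr Call-rate thresholds.
#' @param min_maf MAF threshold.
#' @param hwe_alpha HWE significance threshold.
#' @return List with the filtered `gm`, the `report` data.frame (one row
#'   per step plus retained totals as attributes), and `mendel` (the
#'   conflict report, NULL without a pedigree).
#' @export
qc_pipeline <- function(gm, pedigree = NULL,
                        excluded_chroms = character(),
                        ind_cr = 0.95, snp_cr = 0.95, min_maf = 0.05,
                        hwe_alpha = 1e-4) {
  steps <- list()
  r <- filter_individual_call_rate(gm, ind_cr)
  steps[[1]] <- r$report; gm <- r$gm
  r <- filter_maf(gm, 1e-9, label = "MAF (= 0)")
  steps[[2]] <- r$report; gm <- r$gm
  r <- filter_maf(gm, min_maf)
  steps[[3]] <- r$report; gm <- r$gm
  r <- filter_snp_call_rate(gm, snp_cr)
  steps[[4]] <- r$report; gm <- r$gm
  r <- filter_hwe(gm, hwe_alpha)
  steps[[5]] <- r$report; gm <- r$gm
  r <- filter_by_location(gm, excluded_chroms)
  steps[[6]] <- r$report; gm <- r$gm
  mendel <- NULL
  n_mendel <- 0L
  if (!is.null(pedigree)) {
    mendel <- mendel_check(gm, pedigree)
    n_mendel <- sum(mendel$n_conflicts > 0)
  }
  report <- rbind(do.call(rbind, steps),
                  qc_entry("Pedigree incompatibility problem (reported)",
                           n_mendel, "pairs", NA))
  attr(report, "markers_retained") <- ncol(gm$codes)
  attr(report, "individuals_retained") <- nrow(gm$codes)
  list(gm = gm, report = report, mendel = mendel)
}
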