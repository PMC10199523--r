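#' Eggshell colour score from tristimulus colour measurements
#'
#' `ESC = 100 - (L* - a* - b*)`: darker, redder, yellower shells score
#' higher.
#'
#' @param L,a,b Lightness, redness and yellowness readings.
#' @return The ESC value.
#' @export
#' @examples
#' derive_esc(60, 20, 15)
derive_esc <- function(L, a, b) {
  stopifnot(is.finite(L), is.finite(a), is.finite(b))
  100 - (L - a - b)
}

#' Probability that a heterozygote shows both alleles at a read depth
#'
#' With `n` independent reads from a heterozygous site, each read shows
#' either allele with probability 1/2; both alleles are observed unless
#' all reads agree, so the probability is `1 - 2 / 2^n`. At depth 2 the
#' probability of reading the same allele twice (and thus miscalling the
#' heterozygote) is 50%.
#'
#' @param n_reads Read depth, at least 1.
#' @return Probability both alleles are observed.
#' @export
#' @examples
#' heterozygote_call_probability(2)  # 0.5
heterozygote_call_probability <- function(n_reads) {
  if (any(n_reads < 1)) stop("read depth must be at least 1")
  1 - 2 / 2^n_reads
}

#' Solve single-trait mixed model equations
#'
#' Henderson's MME for `y = X b + Z u + e` with `u ~ (0, H sigma2_u)`:
#' `[X'X  X'Z; Z'X  Z'Z + Hinv * lambda] [b; u] = [X'y; Z'y]` with
#' `lambda = sigma2_e / sigma2_u`. Returns breeding values for every
#' individual in `Hinv`, phenotyped or not. A rank-deficient fixed-effect
#' block is handled by dropping redundant columns (the usual first-level
#' constraint), with a message.
#'
#' @param y Numeric response vector (one record per observation).
#' @param X Fixed-effect design matrix (rows = observations).
#' @param Z Random-effect incidence matrix (rows = observations, columns
#'   = all individuals, in `Hinv` order).
#' @param Hinv Inverse relationship matrix (pedigree, genomic or
#'   single-step H).
#' @param lambda Variance ratio `sigma2_e / sigma2_u`, positive.
#' @return List with `b` (fixed-effect solutions, NA for dropped columns)
#'   and `u` (named GEBV vector).
#' @export
solve_mme <- function(y, X, Z, Hinv, lambda) {
  stopifnot(lambda > 0, nrow(X) == length(y), nrow(Z) == length(y),
            ncol(Z) == nrow(Hinv))
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  if (qx$rank < ncol(X)) {
    message("fixed-effect design rank-deficient: ",
            ncol(X) - qx$rank, " column(s) constrained to zero")
  }
  Xk <- X[, sort(keep), drop = FALSE]
  nf <- ncol(Xk)
  lhs <- rbind(cbind(crossprod(Xk), crossprod(Xk, Z)),
               cbind(crossprod(Z, Xk), crossprod(Z) + Hinv * lambda))
  rhs <- c(crossprod(Xk, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  b <- rep(NA_real_, ncol(X))
  b[sort(keep)] <- sol[seq_len(nf)]
  names(b) <- colnames(X)
  u <- sol[-seq_len(nf)]
  names(u) <- rownames(Hinv)
  list(b = b, u = u)
}

#' Single-trait single-step GBLUP evaluation
#'
#' Assembles and solves the MME for one trait: fixed effects are an
#' intercept plus the hatch-batch factor, the random effect is the
#' additive animal effect with covariance `H`. Repeated records per
#' individual are collapsed to their mean first.
#'
#' @param phenotypes data.frame with `id`, `value`, `batch` for one
#'   trait.
#' @param pedigree Pedigree data.frame (parents before offspring).
#' @param genotypes Complete dosage matrix of the genotyped individuals
#'   (rownames = ids), or NULL for plain pedigree BLUP.
#' @param var_u,var_e Additive and residual variance components (known /
#'   supplied; not estimated here).
#' @param blend,tau,omega Passed to [build_Hinv()].
#' @return Named GEBV vector covering every pedigree individual.
#' @export
ssgblup_evaluate <- function(phenotypes, pedigree, genotypes = NULL,
                             var_u, var_e, blend = 0.05, tau = 1,
                             omega = 1) {
  stopifnot(var_u > 0, var_e > 0)
  # collapse repeated measures to individual means, keeping first batch
  agg <- stats::aggregate(value ~ id, data = phenotypes, FUN = mean)
  agg$batch <- phenotypes$batch[match(agg$id, phenotypes$id)]
  agg <- agg[agg$id %in% pedigree$id, , drop = FALSE]
  y <- agg$value
  X <- stats::model.matrix(~ factor(batch), data = agg)
  Z <- matrix(0, nrow(agg), nrow(pedigree),
              dimnames = list(NULL, pedigree$id))
  Z[cbind(seq_len(nrow(agg)), match(agg$id, pedigree$id))] <- 1
  A <- build_A(pedigree)
  Ainv <- solve(A)
  if (is.null(genotypes)) {
    Hinv <- Ainv
  } else {
    gids <- rownames(genotypes)
    stopifnot(all(gids %in% pedigree$id))
    G <- build_G(genotypes)
    A22 <- A[gids, gids]
    Hinv <- build_Hinv(Ainv, A22, G, gids, blend = blend, tau = tau,
                       omega = omega)
  }
  solve_mme(y, X, Z, Hinv, lambda = var_e / var_u)$u
}

#' Run the three genomic evaluation scenarios
#'
#' * `Full_HD`: phenotypes of all generations, true panel genotypes of
#'   all individuals - the reference evaluation.
#' * `Ancestry_true`: phenotypes of the founder generation only, true
#'   panel genotypes of generations 0 and 1 - what the candidates' GEBV
#'   would be with perfect low-density-to-HD recovery.
#' * `Ancestry_imputed`: as `Ancestry_true` but the candidates'
#'   genotypes replaced by their imputed dosages - the realistic RADseq
#'   scenario.
#'
#' Variance components are the simulation truth (`sigma2_u = h2 * var_p`)
#' and are held identical across scenarios.
#'
#' @param sim A `radseq_sim` population.
#' @param imputed Imputed dosage matrix for the generation-1 candidates
#'   over the HD panel markers (rownames = candidate ids). Required for
#'   the `Ancestry_imputed` scenario.
#' @param traits Trait names to evaluate (default: all in the plan).
#' @param scenarios Subset of the three scenario names.
#' @param blend Blend weight passed to [build_Hinv()].
#' @return A `gebv_table` data.frame with columns `scenario`, `trait`,
#'   `id`, `gebv`.
#' @export
run_scenarios <- function(sim, imputed = NULL, traits = NULL,
                          scenarios = c("Full_HD", "Ancestry_true",
                                        "Ancestry_imputed"),
                          blend = 0.05) {
  stopifnot(inherits(sim, "radseq_sim"))
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  tp <- sim$config$trait_plan
  if (is.null(traits)) traits <- tp$name
  panel_idx <- match(sim$hd_panel, colnames(sim$genotypes))
  hd <- sim$genotypes[, panel_idx, drop = FALSE]
  ids_g0 <- sim$pedigree$id[sim$pedigree$generation == 0]
  ids_g1 <- sim$pedigree$id[sim$pedigree$generation == 1]
  if ("Ancestry_imputed" %in% scenarios) {
    if (is.null(imputed)) stop("Ancestry_imputed requires imputed dosages")
    stopifnot(identical(colnames(imputed), colnames(hd)),
              all(rownames(imputed) %in% ids_g1))
  }
  out <- list()
  for (tr in traits) {
    row <- tp[tp$name == tr, ]
    if (nrow(row) == 0) stop("unknown trait: ", tr)
    var_u <- row$h2 * row$var_p
    var_e <- (1 - row$h2) * row$var_p
    ph <- sim$phenotypes[sim$phenotypes$trait == tr, , drop = FALSE]
    for (sc in scenarios) {
      if (sc == "Full_HD") {
        ph_use <- ph
        geno <- hd
      } else {
        ph_use <- ph[ph$id %in% ids_g0, , drop = FALSE]
        g1 <- if (sc == "Ancestry_true")
          hd[ids_g1, , drop = FALSE] else imputed[ids_g1, , drop = FALSE]
        geno <- rbind(hd[ids_g0, , drop = FALSE], g1)
      }
      u <- ssgblup_evaluate(ph_use, sim$pedigree, geno,
                            var_u = var_u, var_e = var_e, blend = blend)
      out[[length(out) + 1]] <- data.frame(
        scenario = sc, trait = tr, id = names(u), gebv = unname(u),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gebv_table", "data.frame")
  res
}

#' Identify breeders by offspring count
#'
#' @param pedigree Pedigree data.frame.
#' @param candidates Ids of the candidate generation.
#' @param min_offspring Minimum offspring in the next generation.
#' @return Character vector of breeder ids.
#' @export
breeder_ids <- function(pedigree, candidates, min_offspring = 10) {
  counts <- table(c(pedigree$sire, pedigree$dam))
  br <- names(counts)[counts >= min_offspring]
  intersect(candidates, br)
}

#' Ranking comparison between two genomic evaluations
#'
#' Quantifies the reordering of selection candidates when one evaluation
#' (e.g. with imputed genotypes) replaces another (the reference):
#' Spearman rank correlation over the top-K candidates of the reference
#' ranking, Spearman over the breeder subset (candidates with at least
#' `min_offspring` offspring in the next generation), the number of
#' reference top-K candidates still in the top K of the alternative, and
#' the Pearson correlation over the breeders (the relative-accuracy
#' comparison when the reference is the full-information evaluation).
#' Optional bootstrap standard errors (resampling individuals within each
#' subset) are the package's own convention for gauging the sampling
#' noise of these correlations.
#'
#' @param gebv_a Named numeric vector: reference GEBV of the candidates.
#' @param gebv_b Named numeric vector: alternative GEBV (same ids).
#' @param pedigree Pedigree (to find breeders).
#' @param K Size of the top group (default 150).
#' @param min_offspring Breeder definition (default 10).
#' @param n_boot Bootstrap replicates for standard errors (0 = none).
#' @param seed Seed for the bootstrap.
#' @return List with `spearman_topK`, `spearman_breeders`,
#'   `n_retained_in_topK`, `pearson_breeders`, `n_breeders`, `K` and,
#'   with `n_boot > 0`, `se_spearman_topK`, `se_spearman_breeders`.
#' @export
rank_comparison <- function(gebv_a, gebv_b, pedigree, K = 150,
                            min_offspring = 10, n_boot = 0, seed = 1) {
  shared <- intersect(names(gebv_a), names(gebv_b))
  if (length(shared) == 0) stop("no shared individuals")
  if (K > length(shared)) stop("K exceeds the number of candidates")
  a <- gebv_a[shared]; b <- gebv_b[shared]
  topA <- names(sort(a, decreasing = TRUE))[seq_len(K)]
  topB <- names(sort(b, decreasing = TRUE))[seq_len(K)]
  br <- breeder_ids(pedigree, shared, min_offspring)
  sp_top <- stats::cor(a[topA], b[topA], method = "spearman")
  sp_br <- if (length(br) >= 2)
    stats::cor(a[br], b[br], method = "spearman") else NA_real_
  pe_br <- if (length(br) >= 2)
    stats::cor(a[br], b[br], method = "pearson") else NA_real_
  out <- list(spearman_topK = sp_top, spearman_breeders = sp_br,
              n_retained_in_topK = length(intersect(topA, topB)),
              pearson_breeders = pe_br,
              n_breeders = length(br), K = K)
  if (n_boot > 0) {
    boot_se <- function(ids) {
      if (length(ids) < 2) return(NA_real_)
      reps <- with_seed(seed, {
        vapply(seq_len(n_boot), function(i) {
          s <- sample(ids, replace = TRUE)
          suppressWarnings(stats::cor(a[s], b[s], method = "spearman"))
        }, numeric(1))
      })
      stats::sd(reps, na.rm = TRUE)
    }
    out$se_spearman_topK <- boot_se(topA)
    out$se_spearman_breeders <- boot_se(br)
  }
  out
}

#' Extract one scenario/trait GEBV vector from a gebv_table
#'
#' @param gebv A `gebv_table` from [run_scenarios()].
#' @param scenario,trait Scenario and trait names.
#' @param ids Optional subset of individual ids.
#' @return Named numeric vector of GEBV.
#' @export
gebv_vector <- function(gebv, scenario, trait, ids = NULL) {
  d <- gebv[gebv$scenario == scenario & gebv$trait == trait, ]
  v <- stats::setNames(d$gebv, d$id)
  if (!is.null(ids)) v <- v[ids]
  v
}
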