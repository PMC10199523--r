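#' Pedigree additive relationship matrix (tabular method)
#'
#' Builds A by the tabular recursion: founders are assumed unrelated and
#' non-inbred; for each individual, the relationship with an older animal
#' is the average of the parents' relationships with it, and the diagonal
#' is 1 plus half the parents' relationship (inbreeding enters
#' automatically).
#'
#' @param pedigree data.frame (`id`, `sire`, `dam`) with parents listed
#'   before offspring; unknown parents are `NA`.
#' @return Symmetric numeric matrix with ids as dimnames.
#' @export
build_A <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  si <- pos[pedigree$sire]; di <- pos[pedigree$dam]
  if (any(!is.na(pedigree$sire) & is.na(si)) ||
      any(!is.na(pedigree$dam) & is.na(di))) {
    stop("parent id absent from pedigree")
  }
  if (any(si >= seq_len(n), na.rm = TRUE) ||
      any(di >= seq_len(n), na.rm = TRUE)) {
    stop("pedigree must list parents before offspring")
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      rel <- numeric(i - 1)
      if (!is.na(s)) rel <- rel + 0.5 * A[j, s]
      if (!is.na(d)) rel <- rel + 0.5 * A[j, d]
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Inverse of the additive relationship matrix
#'
#' `method = "direct"` inverts the tabular A numerically (exact at desk
#' scale). `method = "henderson"` assembles the inverse by Henderson's
#' rules with inbreeding coefficients taken from the tabular diagonal,
#' which scales linearly in pedigree size.
#'
#' @param pedigree data.frame (`id`, `sire`, `dam`), parents first.
#' @param method `"direct"` or `"henderson"`.
#' @return The inverse relationship matrix.
#' @export
build_Ainv <- function(pedigree, method = c("direct", "henderson")) {
  method <- match.arg(method)
  A <- build_A(pedigree)
  if (method == "direct") return(solve(A))
  ids <- pedigree$id
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  si <- pos[pedigree$sire]; di <- pos[pedigree$dam]
  Ainv <- matrix(0, n, n, dimnames = list(ids, ids))
  dg <- diag(A)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    # Mendelian sampling variance given known parents' inbreeding:
    # 1 - 0.25(1 + F_s) - 0.25(1 + F_d), missing-parent terms omitted
    mend <- 1 -
      (if (!is.na(s)) 0.25 * dg[s] else 0) -
      (if (!is.na(d)) 0.25 * dg[d] else 0)
    alpha <- 1 / mend
    par <- c(s, d); par <- par[!is.na(par)]
    Ainv[i, i] <- Ainv[i, i] + alpha
    for (p in par) {
      Ainv[i, p] <- Ainv[i, p] - alpha / 2
      Ainv[p, i] <- Ainv[p, i] - alpha / 2
    }
    for (p in par) for (q in par) {
      Ainv[p, q] <- Ainv[p, q] + alpha / 4
    }
  }
  Ainv
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / (2 * sum_j p_j (1 - p_j))` with `M` the allele-dosage
#' matrix column-centred at twice the allele frequency. Frequencies
#' default to those of the genotyped set.
#'
#' @param genotypes Complete dosage matrix (individuals x markers), no
#'   missing codes.
#' @param allele_freqs Optional per-marker alternate allele frequencies.
#' @return Symmetric genomic relationship matrix.
#' @export
build_G <- function(genotypes, allele_freqs = NULL) {
  if (anyNA(genotypes)) stop("genotypes must be complete (impute first)")
  p <- if (is.null(allele_freqs)) colMeans(genotypes) / 2 else allele_freqs
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: G denominator is zero")
  M <- sweep(genotypes, 2, 2 * p, "-")
  (M %*% t(M)) / denom
}

#' Inverse H matrix for single-step GBLUP
#'
#' Combines the pedigree inverse with the genomic information on the
#' genotyped block: `Hinv = Ainv + [0 0; 0 tau * Gb^-1 - omega *
#' A22^-1]`, where `Gb = (1 - blend) * G + blend * A22` is the blended
#' genomic matrix (blending guarantees invertibility and aligns G with
#' the pedigree base).
#'
#' @param Ainv Inverse pedigree relationship matrix (full pedigree).
#' @param A22 Pedigree relationship sub-matrix of the genotyped
#'   individuals.
#' @param G Genomic relationship matrix of the genotyped individuals (same
#'   order as `A22`).
#' @param genotyped Indices (or ids) of the genotyped individuals within
#'   `Ainv`.
#' @param blend Weight on `A22` in the blend (default 0.05).
#' @param tau,omega Scaling factors on `Gb^-1` and `A22^-1` (default 1).
#' @return The inverse H matrix, same dimension as `Ainv`.
#' @export
build_Hinv <- function(Ainv, A22, G, genotyped, blend = 0.05, tau = 1,
                       omega = 1) {
  stopifnot(nrow(A22) == nrow(G))
  if (is.character(genotyped)) genotyped <- match(genotyped, rownames(Ainv))
  stopifnot(!anyNA(genotyped), length(genotyped) == nrow(G))
  Gb <- (1 - blend) * G + blend * A22
  Gbinv <- tryCatch(solve(Gb), error = function(e) {
    stop("blended genomic matrix is singular; raise 'blend'")
  })
  Hinv <- Ainv
  Hinv[genotyped, genotyped] <- Hinv[genotyped, genotyped] +
    tau * Gbinv - omega * solve(A22)
  Hinv
}
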