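test_that("eggshell colour combines the tristimulus readings", {
  expect_equal(derive_esc(60, 20, 15), 75)
  expect_equal(derive_esc(100, 0, 0), 0)
  expect_equal(derive_esc(50, 10, 5), 65)
  expect_error(derive_esc(NA, 1, 1))
})

test_that("heterozygote detection probability follows 1 - 2/2^n", {
  expect_equal(heterozygote_call_probability(1), 0)
  expect_equal(heterozygote_call_probability(2), 0.5)
  expect_equal(heterozygote_call_probability(c(3, 10)),
               c(0.75, 1 - 2 / 1024))
  expect_error(heterozygote_call_probability(0), "at least 1")
  # Monte-Carlo cross-check at depth 3
  set.seed(61)
  reads <- matrix(stats::rbinom(3 * 20000, 1, 0.5), ncol = 3)
  seen_both <- rowSums(reads) %in% 1:2
  expect_lt(abs(mean(seen_both) - 0.75), 0.01)
})

test_that("the mixed-model solver matches a GLS-based BLUP derivation", {
  ped <- data.frame(
    id = sprintf("a%02d", 1:12),
    sire = c(NA, NA, NA, NA, "a01", "a01", "a03", "a03", "a05", "a05",
             "a07", "a07"),
    dam = c(NA, NA, NA, NA, "a02", "a02", "a04", "a04", "a06", "a06",
            "a08", "a08"),
    stringsAsFactors = FALSE)
  A <- build_A(ped)
  set.seed(62)
  obs <- c(2, 4, 5, 7, 8, 9, 10, 12)  # phenotyped subset
  y <- stats::rnorm(8, 10)
  x <- stats::rnorm(8)
  X <- cbind(1, x)
  Z <- matrix(0, 8, 12, dimnames = list(NULL, ped$id))
  Z[cbind(1:8, obs)] <- 1
  lambda <- 1.5
  sol <- solve_mme(y, X, Z, solve(A), lambda)
  # independent route: GLS on V = Z A Z' + lambda I  (sigma_u^2 = 1)
  V <- Z %*% A %*% t(Z) + lambda * diag(8)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- A %*% t(Z) %*% Vi %*% (y - X %*% b)
  expect_equal(unname(sol$b), as.numeric(b), tolerance = 1e-8)
  expect_equal(unname(sol$u), as.numeric(u), tolerance = 1e-8)
})

test_that("a single record is absorbed by the mean, leaving zero deviation", {
  sol <- solve_mme(5, matrix(1, 1, 1), matrix(1, 1, 1), matrix(1), 2)
  expect_equal(unname(sol$b[1]), 5)
  expect_equal(as.numeric(sol$u), 0)
})

test_that("infinite shrinkage drives all breeding values to zero", {
  set.seed(63)
  n <- 10
  y <- stats::rnorm(n, 5)
  X <- matrix(1, n, 1)
  Z <- diag(n)
  sol <- solve_mme(y, X, Z, diag(n), lambda = 1e8)
  expect_lt(max(abs(sol$u)), 1e-5)
})

test_that("rank-deficient fixed effects are constrained with a message", {
  set.seed(64)
  y <- stats::rnorm(6)
  X <- cbind(1, c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))  # redundant
  Z <- diag(6)
  expect_message(sol <- solve_mme(y, X, Z, diag(6), 1), "rank-deficient")
  expect_equal(sum(is.na(sol$b)), 1L)
  expect_length(sol$u, 6)
})

test_that("GEBV are invariant to adding a constant to all phenotypes", {
  sim <- small_sim()
  ph <- sim$phenotypes[sim$phenotypes$trait == "EW", ]
  ped <- sim$pedigree
  u1 <- ssgblup_evaluate(ph, ped, genotypes = NULL, var_u = 0.4,
                         var_e = 0.6)
  ph2 <- ph
  ph2$value <- ph2$value + 100
  u2 <- ssgblup_evaluate(ph2, ped, genotypes = NULL, var_u = 0.4,
                         var_e = 0.6)
  expect_equal(u1, u2, tolerance = 1e-8)
  expect_length(u1, nrow(ped))  # GEBV for every pedigree individual
})

test_that("scenario evaluations reuse identical inputs identically", {
  sim <- small_sim()
  panel_idx <- match(sim$hd_panel, colnames(sim$genotypes))
  ids_g1 <- sim$pedigree$id[sim$pedigree$generation == 1]
  true_g1 <- sim$genotypes[ids_g1, panel_idx, drop = FALSE]
  g1 <- run_scenarios(sim, imputed = true_g1, traits = "EW",
                      scenarios = c("Ancestry_true", "Ancestry_imputed"))
  at <- gebv_vector(g1, "Ancestry_true", "EW")
  ai <- gebv_vector(g1, "Ancestry_imputed", "EW")
  expect_equal(at, ai, tolerance = 1e-10)
  # determinism
  g2 <- run_scenarios(sim, imputed = true_g1, traits = "EW",
                      scenarios = "Ancestry_true")
  expect_equal(gebv_vector(g2, "Ancestry_true", "EW"), at)
  # a scenario referencing absent genotypes errors
  expect_error(run_scenarios(sim, imputed = NULL, traits = "EW",
                             scenarios = "Ancestry_imputed"),
               "imputed")
  expect_error(run_scenarios(sim, traits = "nope",
                             scenarios = "Full_HD"), "unknown trait")
})

test_that("full information ranks candidates closer to their true breeding values", {
  sim <- small_sim()
  g <- run_scenarios(sim, traits = "EW",
                     scenarios = c("Full_HD", "Ancestry_true"))
  ids_g1 <- sim$pedigree$id[sim$pedigree$generation == 1]
  tbv <- sim$tbv[ids_g1, "EW"]
  cor_full <- stats::cor(gebv_vector(g, "Full_HD", "EW", ids_g1), tbv)
  cor_anc <- stats::cor(gebv_vector(g, "Ancestry_true", "EW", ids_g1), tbv)
  expect_gt(cor_full, cor_anc)
  expect_gt(cor_anc, 0.3)
})

test_that("breeders are candidates with enough offspring in the next generation", {
  sim <- small_sim()
  ids_g1 <- sim$pedigree$id[sim$pedigree$generation == 1]
  br <- breeder_ids(sim$pedigree, ids_g1, min_offspring = 10)
  # 5 G1 sires each have 12 G2 offspring; dams only 4
  expect_length(br, 5)
  expect_length(breeder_ids(sim$pedigree, ids_g1, min_offspring = 4), 20)
})

test_that("identical rankings give perfect retention and unit correlations", {
  set.seed(65)
  ids <- sprintf("c%02d", 1:30)
  gebv <- stats::setNames(stats::rnorm(30), ids)
  ped <- data.frame(id = sprintf("k%02d", 1:30),
                    sire = rep(c("c01", "c02", "c03"), each = 10),
                    dam = "u", stringsAsFactors = FALSE)
  rc <- rank_comparison(gebv, gebv, ped, K = 10, min_offspring = 10)
  expect_equal(rc$spearman_topK, 1)
  expect_equal(rc$spearman_breeders, 1)
  expect_equal(rc$n_retained_in_topK, 10L)
  expect_equal(rc$pearson_breeders, 1)
  expect_equal(rc$n_breeders, 3L)
  # reversed evaluation flips the correlations
  rc2 <- rank_comparison(gebv, -gebv, ped, K = 30, min_offspring = 10)
  expect_equal(rc2$spearman_topK, -1)
  expect_equal(rc2$spearman_breeders, -1)
  expect_error(rank_comparison(gebv, gebv, ped, K = 31), "exceeds")
})

test_that("a single adjacent swap matches the hand Spearman formula", {
  ids <- sprintf("c%d", 1:6)
  a <- stats::setNames(as.numeric(1:6), ids)
  b <- a
  b[c("c3", "c4")] <- a[c("c4", "c3")]  # swap one adjacent pair
  ped <- data.frame(id = "k", sire = NA_character_, dam = NA_character_,
                    stringsAsFactors = FALSE)
  rc <- rank_comparison(a, b, ped, K = 6, min_offspring = 10)
  n <- 6
  expect_equal(rc$spearman_topK, 1 - 6 * 2 / (n * (n^2 - 1)))
  expect_equal(rc$n_breeders, 0L)
  expect_true(is.na(rc$spearman_breeders))
})

test_that("bootstrap standard errors are reported and small for exact agreement", {
  set.seed(66)
  ids <- sprintf("c%02d", 1:40)
  gebv <- stats::setNames(stats::rnorm(40), ids)
  noisy <- gebv + stats::rnorm(40, 0, 0.3)
  ped <- data.frame(id = sprintf("k%02d", 1:40),
                    sire = rep(c("c01", "c02", "c03", "c04"), each = 10),
                    dam = "u", stringsAsFactors = FALSE)
  rc <- rank_comparison(gebv, noisy, ped, K = 20, min_offspring = 10,
                        n_boot = 200, seed = 2)
  expect_true(is.finite(rc$se_spearman_topK))
  expect_gt(rc$se_spearman_topK, 0)
  rc_same <- rank_comparison(gebv, gebv, ped, K = 20, min_offspring = 10,
                             n_boot = 50, seed = 2)
  expect_equal(rc_same$se_spearman_topK, 0)
})
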