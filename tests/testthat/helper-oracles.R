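# Independent oracles and small fixtures shared across the test files.

# Naive position-by-position IUPAC scanner, used as an independent oracle
# for scan_sites(). Deliberately reimplements the IUPAC code table.
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

naive_scan <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  k <- length(pat)
  n <- length(chars)
  if (n < k) return(integer(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & chars[j:(n - k + j)] %in% iupac_sets[[pat[j]]]
  }
  which(ok) - 1L
}

random_dna <- function(n, gc = 0.45) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

toy_genome <- function(seqs, types = NULL) {
  if (is.null(types)) types <- rep("macro", length(seqs))
  genome_assembly(seqs, data.frame(chrom = names(seqs), type = types,
                                   stringsAsFactors = FALSE))
}

# Exhaustive-enumeration oracle for the exact HWE test: every arrangement
# of the nA alternate alleles over the 2n ordered allele slots is equally
# likely; slots are paired (1,2), (3,4), ... into individuals and the
# heterozygote-count distribution is tallied by full enumeration of
# choose(2n, nA) arrangements (feasible for small n).
hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(1)
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  slots <- 2 * n
  arr <- utils::combn(slots, nA)
  pair_of <- rep(seq_len(n), each = 2)
  hets <- apply(arr, 2, function(a) {
    x <- tabulate(pair_of[a], nbins = n)
    sum(x == 1)
  })
  tab <- table(hets) / ncol(arr)
  obs <- tab[as.character(n_Aa)]
  min(1, sum(tab[tab <= obs * (1 + 1e-9)]))
}

# Small, quick synthetic population reused by several test files.
small_config <- function(seed = 42) {
  sim_config(
    seed = seed,
    chromosome_plan = data.frame(
      name = c("chr1", "chr11"), type = c("macro", "micro"),
      length = c(400e3, 150e3), gc = c(0.40, 0.50),
      stringsAsFactors = FALSE),
    n_founders = 40, generations = 3,
    n_sires = 5, n_dams = 15, offspring_per_dam = 4,
    marker_density = 400, ld_decay_bp = 30e3,
    trait_plan = data.frame(name = "EW", h2 = 0.4, var_p = 1, mean = 10,
                            n_qtl = 100, stringsAsFactors = FALSE),
    panel_fraction = 0.6)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_population(small_config())
    cache
  }
})
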