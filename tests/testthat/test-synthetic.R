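test_that("simulated chromosomes hit their target lengths and GC content", {
  sim <- small_sim()
  g <- sim$genome
  expect_equal(unname(chrom_lengths(g)), c(400e3, 150e3))
  gc <- gc_content(g)
  expect_lt(abs(gc[["chr1"]] - 0.40), 0.01)
  expect_lt(abs(gc[["chr11"]] - 0.50), 0.01)
  expect_gt(gc[["chr11"]], gc[["chr1"]])  # micro GC-richer than macro
})

test_that("configurations violating the karyotype invariants are rejected", {
  plan <- default_chromosome_plan()
  plan$length[plan$type == "micro"] <- 9e6
  expect_error(sim_config(chromosome_plan = plan), "shorter")
  plan2 <- default_chromosome_plan()
  plan2$gc[plan2$type == "micro"] <- 0.30
  expect_error(sim_config(chromosome_plan = plan2), "GC")
  tp <- default_trait_plan()
  tp$h2[1] <- 1
  expect_error(sim_config(trait_plan = tp), "heritabilities")
})

test_that("the pedigree lists parents before offspring with the planned family sizes", {
  sim <- small_sim()
  ped <- sim$pedigree
  expect_equal(nrow(ped), 40 + 2 * 60)
  expect_true(all(is.na(ped$sire[ped$generation == 0])))
  off <- ped[ped$generation == 1, , drop = FALSE]
  expect_equal(length(unique(off$sire)), 5L)
  expect_equal(length(unique(off$dam)), 15L)
  expect_true(all(table(off$sire) == 12))  # 3 dams x 4 offspring per sire
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  nonf <- ped[!is.na(ped$sire), , drop = FALSE]
  expect_true(all(pos[nonf$sire] < pos[nonf$id]))
  expect_true(all(pos[nonf$dam] < pos[nonf$id]))
})

test_that("marker reference alleles are the genome bases at their positions", {
  sim <- small_sim()
  m <- sim$markers
  for (ch in unique(m$chrom)) {
    s <- as.character(sim$genome$seqs[[ch]])
    mm <- m[m$chrom == ch, , drop = FALSE]
    expect_equal(substring(s, mm$pos, mm$pos), mm$ref)
    expect_true(all(mm$alt != mm$ref))
    expect_true(all(mm$pos >= 1 & mm$pos <= nchar(s)))
  }
  expect_true(all(m$freq_alt >= 0.05 & m$freq_alt <= 0.5))
  expect_true(any(m$in_site))  # planted recognition-site variants exist
})

test_that("gene drop transmits parental alleles without Mendelian conflicts", {
  sim <- small_sim()
  ped <- sim$pedigree
  g <- sim$genotypes
  expect_true(all(g %in% 0:2))
  expect_identical(g, sim$hap1 + sim$hap2)
  set.seed(16)
  for (i in sample(which(ped$generation > 0), 20)) {
    gs <- g[ped$sire[i], ]; gd <- g[ped$dam[i], ]; go <- g[ped$id[i], ]
    expect_false(any((gs == 0 & go == 2) | (gs == 2 & go == 0)))
    expect_false(any((gd == 0 & go == 2) | (gd == 2 & go == 0)))
    # the paternal haplotype is a mosaic of the sire's two haplotypes
    h1 <- sim$hap1[ped$id[i], ]
    expect_true(all(h1 == sim$hap1[ped$sire[i], ] |
                      h1 == sim$hap2[ped$sire[i], ]))
  }
})

test_that("without recombination each gamete is an exact parental chromosome copy", {
  sim <- small_sim()
  ped <- sim$pedigree
  f_ids <- ped$id[ped$generation == 0]
  founders <- list(markers = sim$markers,
                   hap1 = sim$hap1[f_ids, , drop = FALSE],
                   hap2 = sim$hap2[f_ids, , drop = FALSE])
  haps <- gene_drop(ped, founders, sim$genome, recombination_rate = 0,
                    seed = 5)
  kids <- ped$id[ped$generation == 1][1:10]
  for (id in kids) {
    sire <- ped$sire[ped$id == id]
    for (ch in unique(sim$markers$chrom)) {
      idx <- which(sim$markers$chrom == ch)
      h <- haps$hap1[id, idx]
      expect_true(identical(h, haps$hap1[sire, idx]) ||
                    identical(h, haps$hap2[sire, idx]))
    }
  }
})

test_that("founder haplotypes carry linkage disequilibrium decaying with distance", {
  cfg <- sim_config(
    seed = 7,
    chromosome_plan = data.frame(name = "c1", type = "macro",
                                 length = 500e3, gc = 0.42,
                                 stringsAsFactors = FALSE),
    n_founders = 150, generations = 1, marker_density = 600,
    ld_decay_bp = 25e3)
  genome <- simulate_genome(cfg)
  fh <- simulate_founder_haplotypes(genome, cfg)
  H <- rbind(fh$hap1, fh$hap2)
  C <- suppressWarnings(stats::cor(H))
  d <- abs(outer(fh$markers$pos, fh$markers$pos, "-"))
  ut <- upper.tri(C)
  near <- C[ut & d < 10e3]^2
  far <- C[ut & d > 150e3]^2
  expect_gt(mean(near, na.rm = TRUE), 0.3)
  expect_lt(mean(far, na.rm = TRUE), 0.05)
  # realised founder frequencies track the drawn spectrum
  expect_gt(stats::cor(colMeans(H), fh$markers$freq_alt), 0.9)
  # zero LD extent gives independent markers
  cfg0 <- sim_config(
    seed = 7,
    chromosome_plan = cfg$chromosome_plan, n_founders = 150,
    generations = 1, marker_density = 600, ld_decay_bp = 0)
  fh0 <- simulate_founder_haplotypes(genome, cfg0)
  C0 <- suppressWarnings(stats::cor(rbind(fh0$hap1, fh0$hap2)))
  near0 <- C0[upper.tri(C0) & d < 10e3]^2
  expect_lt(mean(near0, na.rm = TRUE), 0.05)
})

test_that("phenotypic variance decomposes into the configured heritability", {
  set.seed(21)
  G <- matrix(stats::rbinom(2000 * 300, 2, 0.3), 2000, 300,
              dimnames = list(sprintf("i%04d", 1:2000),
                              sprintf("m%d", 1:300)))
  ped <- data.frame(id = rownames(G), sire = NA_character_,
                    dam = NA_character_, generation = 0L, sex = "F",
                    stringsAsFactors = FALSE)
  tp <- data.frame(name = "t", h2 = 0.4, var_p = 2, mean = 5, n_qtl = 150,
                   stringsAsFactors = FALSE)
  tr <- simulate_traits(G, ped, tp, batch_var_frac = 0, seed = 3)
  # TBV are rescaled to exactly h2 * var_p
  expect_equal(stats::var(tr$tbv[, 1]), 0.8, tolerance = 1e-10)
  v <- tr$phenotypes$value
  expect_lt(abs(stats::var(v) - 2), 0.2)
  expect_lt(abs(mean(v) - 5), 0.15)
  # regression of phenotype on TBV has slope ~ 1 (unbiased additive model)
  slope <- unname(stats::coef(stats::lm(v ~ tr$tbv[, 1]))[2])
  expect_gt(slope, 0.85); expect_lt(slope, 1.15)
  expect_lt(abs(stats::cor(v, tr$tbv[, 1])^2 - 0.4), 0.07)
})

test_that("the additive limit and identical genotypes behave exactly", {
  set.seed(22)
  G <- matrix(stats::rbinom(100 * 80, 2, 0.4), 100, 80,
              dimnames = list(sprintf("i%03d", 1:100),
                              sprintf("m%d", 1:80)))
  G[2, ] <- G[1, ]
  ped <- data.frame(id = rownames(G), sire = NA_character_,
                    dam = NA_character_, generation = 0L, sex = "F",
                    stringsAsFactors = FALSE)
  tp <- data.frame(name = "t", h2 = 0.999, var_p = 1, mean = 0,
                   n_qtl = 40, stringsAsFactors = FALSE)
  tr <- simulate_traits(G, ped, tp, batch_var_frac = 0, seed = 4)
  expect_identical(tr$tbv[1, 1], tr$tbv[2, 1])
  expect_gt(stats::cor(tr$phenotypes$value, tr$tbv[, 1]), 0.995)
})

test_that("the HD panel is a reproducible random subset of the markers", {
  m <- data.frame(marker_id = sprintf("m%d", 1:1000),
                  stringsAsFactors = FALSE)
  p1 <- sample_hd_panel(m, 0.5, seed = 1)
  expect_length(p1, 500)
  expect_true(all(p1 %in% m$marker_id))
  expect_identical(p1, sample_hd_panel(m, 0.5, seed = 1))
  expect_identical(sample_hd_panel(m, 1, seed = 1), m$marker_id)
  p2 <- sample_hd_panel(m, 0.5, seed = 2)
  expect_false(identical(p1, p2))
  # two independent halves share about half their markers
  expect_lt(abs(length(intersect(p1, p2)) / 500 - 0.5), 0.08)
})

test_that("the population generator is deterministic and RNG-clean", {
  sim <- small_sim()
  s2 <- simulate_population(small_config())
  expect_identical(s2$genotypes, sim$genotypes)
  expect_identical(s2$phenotypes$value, sim$phenotypes$value)
  expect_identical(s2$hd_panel, sim$hd_panel)
  expect_identical(s2$markers, sim$markers)
  # package simulation never disturbs the caller's RNG stream
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_genome(small_config()))
  expect_identical(.Random.seed, before)
})
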