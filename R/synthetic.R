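#' Default chromosome plan: a scaled-down avian karyotype
#'
#' Two macro-chromosomes, two intermediate chromosomes, three
#' micro-chromosomes and one Z, totalling about 26 Mb (roughly 1/40 of a
#' chicken genome). Micro-chromosomes are shorter and GC-richer than
#' macro-chromosomes, which is what makes GC-rich recognition sites cut
#' them more densely.
#'
#' @return data.frame with columns `name`, `type`, `length`, `gc`.
#' @export
default_chromosome_plan <- function() {
  data.frame(
    name = c("chr1", "chr2", "chr6", "chr7", "chr11", "chr12", "chr13",
             "chrZ"),
    type = c("macro", "macro", "intermediate", "intermediate",
             "micro", "micro", "micro", "Z"),
    length = c(8e6, 6e6, 3e6, 2.5e6, 1e6, 8e5, 6e5, 4e6),
    gc = c(0.40, 0.41, 0.44, 0.45, 0.50, 0.51, 0.52, 0.42),
    stringsAsFactors = FALSE)
}

#' Default polygenic trait plan: four egg-quality traits
#'
#' Egg weight (EW), eggshell colour (ESC), eggshell strength (ESS) and
#' albumen height (AH), with heritabilities typical of layer lines.
#' Phenotypic variances are standardised to 1 so effect sizes are in
#' phenotypic standard deviations.
#'
#' @return data.frame with columns `name`, `h2`, `var_p`, `mean`, `n_qtl`.
#' @export
default_trait_plan <- function() {
  data.frame(name = c("EW", "ESC", "ESS", "AH"),
             h2 = c(0.50, 0.40, 0.30, 0.25),
             var_p = 1, mean = 0, n_qtl = 300,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic population generator and
#' validates the invariants (positive lengths, GC and heritabilities in
#' (0,1), micro-chromosomes shorter and at least as GC-rich as
#' macro-chromosomes).
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   substream from it, so identical configurations give byte-identical
#'   output.
#' @param chromosome_plan data.frame(name, type, length, gc); see
#'   [default_chromosome_plan()].
#' @param n_founders Number of generation-0 individuals (half male, half
#'   female).
#' @param generations Total number of generations including founders
#'   (default 4: G0 founders through G3).
#' @param n_sires,n_dams Breeders selected per generation.
#' @param offspring_per_dam Offspring per mated dam.
#' @param marker_density Markers per Mb (default 300, a high-density-chip
#'   scale density).
#' @param ld_decay_bp Distance at which founder-haplotype r2 falls to the
#'   0.3 usefulness threshold (default 250 kb).
#' @param trait_plan data.frame(name, h2, var_p, mean, n_qtl); see
#'   [default_trait_plan()].
#' @param batches_per_generation Number of hatch batches per generation
#'   used as the single fixed effect (default 3).
#' @param panel_fraction Fraction of markers assigned to the HD chip panel
#'   (default 0.5; the rest are sequence-only variants).
#' @param site_variant_rate Fraction of markers deliberately placed inside
#'   restriction recognition-site matches (default 0.05), guaranteeing
#'   material for site creation/destruction analyses.
#' @param site_enzymes Names of built-in enzymes whose sites receive the
#'   planted markers.
#' @param recombination_rate Crossovers per bp per meiosis (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(seed = 1,
                       chromosome_plan = default_chromosome_plan(),
                       n_founders = 120,
                       generations = 4,
                       n_sires = 15,
                       n_dams = 60,
                       offspring_per_dam = 5,
                       marker_density = 300,
                       ld_decay_bp = 250e3,
                       trait_plan = default_trait_plan(),
                       batches_per_generation = 3,
                       panel_fraction = 0.5,
                       site_variant_rate = 0.05,
                       site_enzymes = c("TaqI", "PstI"),
                       recombination_rate = 1e-8) {
  cp <- chromosome_plan
  stopifnot(is.data.frame(cp),
            all(c("name", "type", "length", "gc") %in% names(cp)),
            nrow(cp) > 0)
  if (any(cp$length <= 0)) stop("chromosome lengths must be positive")
  if (any(cp$gc <= 0 | cp$gc >= 1)) stop("GC targets must be in (0,1)")
  if (!all(cp$type %in% chromosome_types())) {
    stop("unknown chromosome type in plan")
  }
  if (any(cp$type == "micro") && any(cp$type == "macro")) {
    if (max(cp$length[cp$type == "micro"]) >=
        min(cp$length[cp$type == "macro"])) {
      stop("micro-chromosomes must be shorter than macro-chromosomes")
    }
    if (min(cp$gc[cp$type == "micro"]) < max(cp$gc[cp$type == "macro"])) {
      stop("micro-chromosome GC targets must be >= macro-chromosome GC")
    }
  }
  tp <- trait_plan
  stopifnot(is.data.frame(tp), all(c("name", "h2", "var_p") %in% names(tp)))
  if (any(tp$h2 <= 0 | tp$h2 >= 1)) stop("heritabilities must be in (0,1)")
  if (any(tp$var_p <= 0)) stop("phenotypic variances must be positive")
  if (is.null(tp$mean)) tp$mean <- 0
  if (is.null(tp$n_qtl)) tp$n_qtl <- 300
  stopifnot(n_founders >= 2, generations >= 1, n_sires >= 1, n_dams >= 1,
            offspring_per_dam >= 1, marker_density > 0, ld_decay_bp >= 0,
            panel_fraction > 0, panel_fraction <= 1,
            site_variant_rate >= 0, site_variant_rate <= 1,
            recombination_rate >= 0)
  structure(list(seed = as.integer(seed), chromosome_plan = cp,
                 n_founders = as.integer(n_founders),
                 generations = as.integer(generations),
                 n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
                 offspring_per_dam = as.integer(offspring_per_dam),
                 marker_density = marker_density,
                 ld_decay_bp = ld_decay_bp, trait_plan = tp,
                 batches_per_generation = as.integer(batches_per_generation),
                 panel_fraction = panel_fraction,
                 site_variant_rate = site_variant_rate,
                 site_enzymes = site_enzymes,
                 recombination_rate = recombination_rate),
            class = "sim_config")
}

#' Simulate a genome assembly from a chromosome plan
#'
#' Bases are drawn i.i.d. with per-chromosome GC probability; at the
#' simulated lengths the realised GC is within a fraction of a percent of
#' target. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A [genome_assembly()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$chromosome_plan
  seqs <- with_seed(substream_seed(config$seed, "genome"), {
    lapply(seq_len(nrow(cp)), function(i) {
      probs <- c((1 - cp$gc[i]) / 2, cp$gc[i] / 2,
                 cp$gc[i] / 2, (1 - cp$gc[i]) / 2)
      paste0(sample(c("A", "C", "G", "T"), cp$length[i],
                    replace = TRUE, prob = probs), collapse = "")
    })
  })
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- cp$name
  genome_assembly(ss, data.frame(chrom = cp$name, type = cp$type,
                                 stringsAsFactors = FALSE))
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents. In each later generation,
#' the first `n_sires` males and `n_dams` females (by id order, so the
#' scheme is deterministic and not trait-selected) of the previous
#' generation are mated, dams assigned to sires round-robin, each dam
#' producing `offspring_per_dam` offspring of alternating sex. With the
#' default plan each selected sire gets several dams, so sires routinely
#' have well over 10 offspring - the breeder-subset metrics need such
#' sires.
#'
#' @param config A [sim_config()].
#' @return A `pedigree` data.frame with columns `id`, `sire`, `dam`
#'   (`NA` for unknown), `generation`, `sex` ("M"/"F"), parents always
#'   preceding offspring.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n0 <- config$n_founders
  ped <- data.frame(
    id = sprintf("G0_%04d", seq_len(n0)),
    sire = NA_character_, dam = NA_character_,
    generation = 0L,
    sex = rep_len(c("M", "F"), n0),
    stringsAsFactors = FALSE)
  for (g in seq_len(config$generations - 1L)) {
    prev <- ped[ped$generation == g - 1L, , drop = FALSE]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) < config$n_sires || length(females) < config$n_dams) {
      stop("infeasible mating plan: generation ", g - 1,
           " has too few males or females for ", config$n_sires,
           " sires x ", config$n_dams, " dams")
    }
    sires <- males[seq_len(config$n_sires)]
    dams <- females[seq_len(config$n_dams)]
    dam_sire <- rep_len(sires, length(dams))
    n_off <- length(dams) * config$offspring_per_dam
    off <- data.frame(
      id = sprintf("G%d_%04d", g, seq_len(n_off)),
      sire = rep(dam_sire, each = config$offspring_per_dam),
      dam = rep(dams, each = config$offspring_per_dam),
      generation = g,
      sex = rep_len(c("M", "F"), n_off),
      stringsAsFactors = FALSE)
    ped <- rbind(ped, off)
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Gaussian-copula AR(1) correlation length, in units of ld_decay_bp.
# Calibrated once so that the mean pairwise r-squared between founder
# haplotypes is about 0.35 for markers within ld_decay_bp of each other
# (above the 0.3 usefulness threshold) and near zero at 5 x ld_decay_bp.
.ld_corr_scale <- 4

#' Simulate markers and LD-structured founder haplotypes
#'
#' Biallelic markers are placed on each chromosome: a configured fraction
#' inside restriction recognition-site matches (so that downstream
#' site-disruption analyses have guaranteed material) and the rest
#' uniformly at random. The reference allele is the simulated genome base;
#' the alternate allele frequency is drawn from a U(0.05, 0.5) spectrum.
#' Founder haplotypes are generated by thresholding a first-order
#' autoregressive Gaussian process along each chromosome whose correlation
#' length is tuned so that pairwise r2 between haplotypes stays above the
#' 0.3 usefulness threshold out to `ld_decay_bp` on average; `ld_decay_bp
#' = 0` gives independent markers.
#'
#' @param genome A [genome_assembly()] from [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `markers` (data.frame: `marker_id`, `chrom`, `pos`
#'   1-based, `ref`, `alt`, `freq_alt`, `in_site`) and `hap1`, `hap2`
#'   (integer 0/1 matrices, founders x markers, allele 1 = alternate).
#' @export
simulate_founder_haplotypes <- function(genome, config) {
  stopifnot(inherits(genome, "genome_assembly"),
            inherits(config, "sim_config"))
  lens <- chrom_lengths(genome)
  enzs <- radseq_enzymes()[config$site_enzymes]
  with_seed(substream_seed(config$seed, "founders"), {
    marker_parts <- lapply(names(lens), function(ch) {
      L <- lens[[ch]]
      seq_ch <- as.character(genome$seqs[[ch]])
      n_mark <- round(config$marker_density * L / 1e6)
      if (n_mark > L) stop("marker density exceeds available positions on ",
                           ch)
      if (n_mark == 0) return(NULL)
      n_site <- round(config$site_variant_rate * n_mark)
      site_pos <- integer(0)
      if (n_site > 0 && length(enzs) > 0) {
        cand <- unlist(lapply(enzs, function(e) {
          st <- scan_sites(seq_ch, e)$start
          if (length(st) == 0) return(integer(0))
          # all 1-based positions covered by a recognition site
          rep(st, each = e$site_length) +
            rep(seq_len(e$site_length), times = length(st))
        }))
        cand <- unique(cand)
        if (length(cand) > 0) {
          site_pos <- sample(cand, min(n_site, length(cand)))
        }
      }
      unif_pos <- sample.int(L, n_mark - length(site_pos))
      pos <- sort(unique(c(site_pos, unif_pos)))
      data.frame(chrom = ch, pos = pos,
                 in_site = pos %in% site_pos,
                 ref = substring(seq_ch, pos, pos),
                 stringsAsFactors = FALSE)
    })
    markers <- do.call(rbind, marker_parts)
    rownames(markers) <- NULL
    markers$alt <- vapply(markers$ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
    markers$freq_alt <- stats::runif(nrow(markers), 0.05, 0.5)
    markers$marker_id <- sprintf("%s_%d", markers$chrom, markers$pos)
    markers <- markers[, c("marker_id", "chrom", "pos", "ref", "alt",
                           "freq_alt", "in_site")]

    n_h <- 2L * config$n_founders
    lambda <- .ld_corr_scale * config$ld_decay_bp
    hap <- matrix(0L, nrow = n_h, ncol = nrow(markers))
    col0 <- 0L
    for (ch in names(lens)) {
      m <- markers[markers$chrom == ch, , drop = FALSE]
      nm <- nrow(m)
      if (nm == 0) next
      rho <- if (lambda > 0) exp(-diff(m$pos) / lambda) else
        rep(0, max(nm - 1, 0))
      U <- matrix(0, n_h, nm)
      U[, 1] <- stats::rnorm(n_h)
      if (nm > 1) {
        eps <- matrix(stats::rnorm(n_h * (nm - 1)), n_h, nm - 1)
        for (j in 2:nm) {
          U[, j] <- rho[j - 1] * U[, j - 1] +
            sqrt(1 - rho[j - 1]^2) * eps[, j - 1]
        }
      }
      thr <- stats::qnorm(m$freq_alt)
      hap[, col0 + seq_len(nm)] <-
        (sweep(U, 2, thr, "<")) * 1L
      col0 <- col0 + nm
    }
    founder_ids <- sprintf("G0_%04d", seq_len(config$n_founders))
    hap1 <- hap[seq(1, n_h, by = 2), , drop = FALSE]
    hap2 <- hap[seq(2, n_h, by = 2), , drop = FALSE]
    dimnames(hap1) <- list(founder_ids, markers$marker_id)
    dimnames(hap2) <- list(founder_ids, markers$marker_id)
    list(markers = markers, hap1 = hap1, hap2 = hap2)
  })
}

#' Drop founder haplotypes through a pedigree with recombination
#'
#' Each non-founder inherits one recombined gamete per parent: the
#' crossover count per chromosome is Poisson with mean
#' `recombination_rate * length`, crossover positions are uniform, and the
#' transmitted haplotype is the corresponding mosaic of the parent's two
#' haplotypes. With `recombination_rate = 0` every gamete is an exact copy
#' of one parental haplotype.
#'
#' @param pedigree A pedigree from [simulate_pedigree()] (parents before
#'   offspring).
#' @param founder_haps List with `markers`, `hap1`, `hap2` from
#'   [simulate_founder_haplotypes()].
#' @param genome The [genome_assembly()] (for chromosome lengths).
#' @param recombination_rate Crossovers per bp per meiosis.
#' @param seed Integer seed.
#' @return List with `hap1`, `hap2`: integer matrices (all individuals x
#'   markers); `hap1` is the paternal, `hap2` the maternal haplotype.
#' @export
gene_drop <- function(pedigree, founder_haps, genome,
                      recombination_rate = 1e-8, seed = 1) {
  stopifnot(recombination_rate >= 0)
  markers <- founder_haps$markers
  lens <- chrom_lengths(genome)
  chrom_idx <- split(seq_len(nrow(markers)), markers$chrom)
  n_ind <- nrow(pedigree)
  n_mark <- nrow(markers)
  hap1 <- matrix(0L, n_ind, n_mark,
                 dimnames = list(pedigree$id, markers$marker_id))
  hap2 <- hap1
  founder_rows <- match(rownames(founder_haps$hap1), pedigree$id)
  if (anyNA(founder_rows)) stop("founder haplotypes for unknown individuals")
  hap1[founder_rows, ] <- founder_haps$hap1
  hap2[founder_rows, ] <- founder_haps$hap2
  row_of <- stats::setNames(seq_len(n_ind), pedigree$id)

  gamete <- function(parent_row) {
    g <- integer(n_mark)
    for (ch in names(chrom_idx)) {
      idx <- chrom_idx[[ch]]
      L <- lens[[ch]]
      ncross <- stats::rpois(1, recombination_rate * L)
      xpos <- if (ncross > 0) sort(stats::runif(ncross, 0, L)) else numeric(0)
      start <- sample.int(2L, 1L)
      seg <- findInterval(markers$pos[idx], xpos)
      use1 <- ((start + seg) %% 2L) == 0L
      v <- hap2[parent_row, idx]
      v[use1] <- hap1[parent_row, idx][use1]
      g[idx] <- v
    }
    g
  }

  with_seed(seed, {
    for (i in seq_len(n_ind)) {
      if (pedigree$generation[i] == 0) next
      s <- pedigree$sire[i]; d <- pedigree$dam[i]
      if (is.na(s) || is.na(d) || !(s %in% names(row_of)) ||
          !(d %in% names(row_of))) {
        stop("non-founder ", pedigree$id[i], " has missing parent(s)")
      }
      if (row_of[[s]] >= i || row_of[[d]] >= i) {
        stop("pedigree not sorted: parent of ", pedigree$id[i],
             " does not precede it")
      }
      hap1[i, ] <- gamete(row_of[[s]])
      hap2[i, ] <- gamete(row_of[[d]])
    }
  })
  list(hap1 = hap1, hap2 = hap2)
}

#' Simulate polygenic traits with batch fixed effects
#'
#' For each trait, additive effects are drawn for a random subset of
#' markers; the true breeding value (TBV) is the effect-weighted allele
#' dosage sum, centred and rescaled so its variance across all individuals
#' is `h2 * var_p`. The phenotype adds the trait mean, a hatch-batch fixed
#' effect (individuals are assigned cyclically to batches within
#' generation; batch effects are drawn once with 5% of the phenotypic
#' variance) and a normal residual of variance `(1 - h2) * var_p`.
#'
#' @param genotypes Integer dosage matrix (individuals x markers).
#' @param pedigree The pedigree (for generations and batch assignment).
#' @param trait_plan data.frame(name, h2, var_p, mean, n_qtl).
#' @param batches_per_generation Number of batches per generation.
#' @param batch_var_frac Fraction of the phenotypic variance contributed
#'   by batch effects (default 0.05; 0 gives a purely additive-plus-noise
#'   phenotype).
#' @param seed Integer seed.
#' @return List with `phenotypes` (data.frame: `id`, `trait`, `value`,
#'   `batch`, `generation`) and `tbv` (matrix individuals x traits).
#' @export
simulate_traits <- function(genotypes, pedigree, trait_plan,
                            batches_per_generation = 3,
                            batch_var_frac = 0.05, seed = 1) {
  stopifnot(all(trait_plan$h2 > 0 & trait_plan$h2 < 1))
  if (is.null(trait_plan$mean)) trait_plan$mean <- 0
  if (is.null(trait_plan$n_qtl)) trait_plan$n_qtl <- 300
  n_ind <- nrow(genotypes)
  batch <- integer(n_ind)
  for (g in unique(pedigree$generation)) {
    sel <- which(pedigree$generation == g)
    batch[sel] <- rep_len(seq_len(batches_per_generation), length(sel)) +
      g * batches_per_generation
  }
  with_seed(seed, {
    tbv <- matrix(0, n_ind, nrow(trait_plan),
                  dimnames = list(rownames(genotypes), trait_plan$name))
    phen <- vector("list", nrow(trait_plan))
    for (t in seq_len(nrow(trait_plan))) {
      h2 <- trait_plan$h2[t]; vp <- trait_plan$var_p[t]
      nq <- min(trait_plan$n_qtl[t], ncol(genotypes))
      qtl <- sample.int(ncol(genotypes), nq)
      eff <- stats::rnorm(nq)
      raw <- as.numeric(genotypes[, qtl, drop = FALSE] %*% eff)
      v <- stats::var(raw)
      if (v <= 0) stop("all-identical genotypes: cannot scale TBV")
      tbv[, t] <- (raw - mean(raw)) * sqrt(h2 * vp / v)
      batch_eff <- stats::rnorm(max(batch), 0, sqrt(batch_var_frac * vp))
      resid <- stats::rnorm(n_ind, 0, sqrt((1 - h2) * vp))
      phen[[t]] <- data.frame(
        id = rownames(genotypes), trait = trait_plan$name[t],
        value = trait_plan$mean[t] + batch_eff[batch] + tbv[, t] + resid,
        batch = batch, generation = pedigree$generation,
        stringsAsFactors = FALSE)
    }
    list(phenotypes = do.call(rbind, phen), tbv = tbv)
  })
}

#' Sample a high-density chip panel from the marker set
#'
#' Designates a deterministic-given-seed random subset of markers as the
#' "HD chip": the reference panel all candidates are imputed up to. The
#' remaining markers play the role of sequence-only variants.
#'
#' @param markers Marker data.frame with a `marker_id` column.
#' @param panel_fraction Fraction of markers in the panel, in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of panel marker ids (in marker order).
#' @export
sample_hd_panel <- function(markers, panel_fraction, seed = 1) {
  stopifnot(panel_fraction > 0, panel_fraction <= 1)
  n <- max(1L, round(panel_fraction * nrow(markers)))
  if (nrow(markers) == 0) stop("empty marker set: cannot build a panel")
  with_seed(seed, {
    sel <- sort(sample.int(nrow(markers), n))
    markers$marker_id[sel]
  })
}

#' Simulate a complete study population
#'
#' Orchestrates the full generator: genome, pedigree, founder haplotypes,
#' gene drop, genotypes, HD panel and phenotypes, all driven by named
#' substreams of the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A `radseq_sim` object: list with `config`, `genome`,
#'   `pedigree`, `markers`, `hap1`, `hap2`, `genotypes` (dosage matrix =
#'   hap1 + hap2), `hd_panel`, `phenotypes`, `tbv`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome(config)
  pedigree <- simulate_pedigree(config)
  founders <- simulate_founder_haplotypes(genome, config)
  haps <- gene_drop(pedigree, founders, genome,
                    recombination_rate = config$recombination_rate,
                    seed = substream_seed(config$seed, "genedrop"))
  genotypes <- haps$hap1 + haps$hap2
  storage.mode(genotypes) <- "integer"
  panel <- sample_hd_panel(founders$markers, config$panel_fraction,
                           seed = substream_seed(config$seed, "panel"))
  traits <- simulate_traits(genotypes, pedigree, config$trait_plan,
                            config$batches_per_generation,
                            seed = substream_seed(config$seed, "traits"))
  structure(list(config = config, genome = genome, pedigree = pedigree,
                 markers = founders$markers, hap1 = haps$hap1,
                 hap2 = haps$hap2, genotypes = genotypes,
                 hd_panel = panel, phenotypes = traits$phenotypes,
                 tbv = traits$tbv),
            class = "radseq_sim")
}

#' @export
print.radseq_sim <- function(x, ...) {
  cat("<radseq_sim> ", nrow(x$pedigree), " individuals in ",
      length(unique(x$pedigree$generation)), " generations; ",
      nrow(x$markers), " markers (", length(x$hd_panel),
      " on HD panel); ", ncol(x$tbv), " trait(s)\n", sep = "")
  invisible(x)
}
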