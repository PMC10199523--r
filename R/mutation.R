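#' Restriction sites destroyed and created by variants
#'
#' All alternate alleles are substituted into the genome jointly (so
#' several variants falling inside one recognition window are evaluated
#' together), the mutated sequence is rescanned, and the reference and
#' mutated site lists are differenced: a reference site absent from the
#' mutated scan is destroyed, a mutated-scan site absent from the
#' reference is created. Variants are applied under a homozygous-alternate
#' model; with `het_mode = "keep"`, variants flagged heterozygous (column
#' `is_het`) are left unapplied, i.e. a heterozygous polymorphism is
#' assumed not to abolish the site on both chromosomes.
#'
#' @param genome A [genome_assembly()].
#' @param variants Marker data.frame with `chrom`, `pos` (1-based), `ref`,
#'   `alt` single-base alleles; optional logical `is_het`.
#' @param enz An [enzyme()].
#' @param het_mode `"destroy"` (default: every variant applied) or
#'   `"keep"` (heterozygous variants not applied).
#' @return A `site_delta`: list with `enzyme`, `destroyed` and `created`
#'   (data.frames `chrom`, `start` 0-based), `n_destroyed`, `n_created`.
#' @export
site_deltas <- function(genome, variants, enz,
                        het_mode = c("destroy", "keep")) {
  het_mode <- match.arg(het_mode)
  stopifnot(inherits(genome, "genome_assembly"),
            inherits(enz, "enzyme_spec"),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  if (any(!snv)) {
    warning(sum(!snv), " non-SNV variant(s) rejected")
    variants <- variants[snv, , drop = FALSE]
  }
  if (het_mode == "keep" && !is.null(variants$is_het)) {
    variants <- variants[!variants$is_het, , drop = FALSE]
  }
  lens <- chrom_lengths(genome)
  if (any(!(variants$chrom %in% names(lens)))) {
    stop("variant on chromosome absent from genome")
  }
  if (any(variants$pos < 1 | variants$pos > lens[variants$chrom])) {
    stop("variant position out of genome bounds")
  }
  mut_seqs <- genome$seqs
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    mut_seqs[[ch]] <- Biostrings::replaceLetterAt(
      mut_seqs[[ch]], v$pos, paste0(v$alt, collapse = ""))
  }
  ref_sites <- scan_sites(genome, enz)
  mut_sites <- scan_sites(genome_assembly(mut_seqs, genome$chrom_types), enz)
  rk <- paste(ref_sites$chrom, ref_sites$start)
  mk <- paste(mut_sites$chrom, mut_sites$start)
  destroyed <- ref_sites[!(rk %in% mk), c("chrom", "start"), drop = FALSE]
  created <- mut_sites[!(mk %in% rk), c("chrom", "start"), drop = FALSE]
  rownames(destroyed) <- rownames(created) <- NULL
  structure(list(enzyme = enz$name, destroyed = destroyed,
                 created = created,
                 n_destroyed = nrow(destroyed), n_created = nrow(created)),
            class = "site_delta")
}

#' @export
print.site_delta <- function(x, ...) {
  cat("<site_delta> ", x$enzyme, ": ", x$n_destroyed, " destroyed, ",
      x$n_created, " created\n", sep = "")
  invisible(x)
}

#' Apply site deltas to a site list
#' @keywords internal
apply_delta <- function(sites, delta) {
  stopifnot(inherits(delta, "site_delta"))
  enz_name <- unique(sites$enzyme)
  stopifnot(length(enz_name) <= 1)
  k <- paste(sites$chrom, sites$start)
  dk <- paste(delta$destroyed$chrom, delta$destroyed$start)
  kept <- sites[!(k %in% dk), , drop = FALSE]
  if (nrow(delta$created) > 0) {
    add <- data.frame(chrom = delta$created$chrom,
                      start = delta$created$start,
                      enzyme = delta$enzyme, stringsAsFactors = FALSE)
    kept <- rbind(as.data.frame(kept), add)
  }
  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("site_list", "data.frame")
  kept
}

#' Rebuild fragments after applying site deltas
#'
#' For each enzyme, the mutated site list is the reference sites minus the
#' destroyed positions plus the created positions; fragments are then
#' rebuilt under the same single-digest or ddRADseq rule and size filter
#' as the reference prediction. Empty deltas reproduce the reference
#' fragment table exactly.
#'
#' @param reference_sites Named list of `site_list`s (one per enzyme; one
#'   entry for a single digest, two for a double digest).
#' @param deltas Named list of `site_delta`s, names matching
#'   `reference_sites`. Enzymes without a delta are left unchanged.
#' @param size_min,size_max Inclusive size bounds applied to the rebuilt
#'   fragments.
#' @return A size-selected `fragment_table`.
#' @export
rebuild_fragments_with_mutations <- function(reference_sites, deltas,
                                             size_min = 200,
                                             size_max = 500) {
  stopifnot(is.list(reference_sites), length(reference_sites) %in% 1:2)
  if (!all(names(deltas) %in% names(reference_sites))) {
    stop("deltas refer to enzymes absent from reference_sites")
  }
  new_sites <- lapply(names(reference_sites), function(nm) {
    if (nm %in% names(deltas)) apply_delta(reference_sites[[nm]],
                                           deltas[[nm]])
    else reference_sites[[nm]]
  })
  fragments <- if (length(new_sites) == 1) {
    build_fragments_single(new_sites[[1]])
  } else {
    build_fragments_double(new_sites[[1]], new_sites[[2]])
  }
  size_select(fragments, size_min, size_max)
}

#' Compare reference and mutated fragment predictions
#'
#' Fragments are matched on exact `(chrom, start, end, left_enzyme,
#' right_enzyme)` identity. When `markers` are supplied the read windows
#' of each table are intersected with the marker set and the shared SNP
#' count (and, with `panel`, the shared-with-panel count) is reported too.
#'
#' @param reference,mutated `fragment_table`s on the same genome.
#' @param markers Optional marker data.frame (`chrom`, `pos`).
#' @param panel Optional panel marker data.frame or id vector (see
#'   [overlap_with_panel()]).
#' @param read_length Read length used to derive windows for the SNP
#'   comparison.
#' @return List with `n_shared`, `n_only_reference`, `n_only_mutated` and,
#'   when markers are given, `n_snps_reference`, `n_snps_mutated`,
#'   `n_shared_snps`, `n_shared_snps_with_panel` (the latter `NA` without
#'   a panel).
#' @export
compare_fragment_tables <- function(reference, mutated, markers = NULL,
                                    panel = NULL, read_length = 150) {
  key <- function(fr) paste(fr$chrom, fr$start, fr$end, fr$left_enzyme,
                            fr$right_enzyme)
  rk <- key(reference); mk <- key(mutated)
  out <- list(n_shared = sum(rk %in% mk),
              n_only_reference = sum(!(rk %in% mk)),
              n_only_mutated = sum(!(mk %in% rk)))
  if (!is.null(markers)) {
    snp_key <- function(fr) {
      w <- make_windows(fr, read_length)
      s <- extract_snps_in_windows(markers, w)
      paste(s$chrom, s$pos)
    }
    sr <- snp_key(reference); sm <- snp_key(mutated)
    shared <- intersect(sr, sm)
    out$n_snps_reference <- length(sr)
    out$n_snps_mutated <- length(sm)
    out$n_shared_snps <- length(shared)
    out$n_shared_snps_with_panel <- NA_integer_
    if (!is.null(panel)) {
      if (is.character(panel)) {
        panel <- markers[markers$marker_id %in% panel, , drop = FALSE]
      }
      pk <- paste(panel$chrom, panel$pos)
      out$n_shared_snps_with_panel <- length(intersect(shared, pk))
    }
  }
  out
}

#' Invert a site delta
#'
#' Swapping destroyed and created positions yields the delta that undoes
#' the original one: applying a delta and then its inverse restores the
#' original site list.
#'
#' @param delta A `site_delta`.
#' @return The inverse `site_delta`.
#' @export
invert_delta <- function(delta) {
  stopifnot(inherits(delta, "site_delta"))
  structure(list(enzyme = delta$enzyme, destroyed = delta$created,
                 created = delta$destroyed,
                 n_destroyed = nrow(delta$created),
                 n_created = nrow(delta$destroyed)),
            class = "site_delta")
}
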