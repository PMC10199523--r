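#' Restriction enzyme specification
#'
#' An enzyme is described by its name and IUPAC recognition sequence.
#' Only the forward strand of a genome is scanned during digestion, which is
#' valid only when the recognition sequence set is closed under reverse
#' complementation (true for palindromic sites such as GAATTC, and for
#' degenerate sites such as GGWCC whose expansion {GGACC, GGTCC} maps onto
#' itself). Construction fails for non-closed patterns so a user can never
#' silently miss half of the sites.
#'
#' @param name Enzyme name, e.g. `"EcoRI"`.
#' @param recognition IUPAC recognition sequence, e.g. `"GAATTC"` or
#'   `"GGWCC"` (`W` = A or T).
#' @param methylation Free-text note on methylation sensitivity (metadata
#'   only; methylation is not simulated).
#' @return An object of class `enzyme_spec` with elements `name`,
#'   `recognition`, `site_length` and `methylation`.
#' @export
#' @examples
#' enzyme("EcoRI", "GAATTC")
#' enzyme("AvaII", "GGWCC")
enzyme <- function(name, recognition, methylation = NA_character_) {
  stopifnot(is.character(name), nzchar(name),
            is.character(recognition), nzchar(recognition))
  recognition <- toupper(recognition)
  bad <- setdiff(strsplit(recognition, "")[[1]], names(iupac_map()))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in recognition sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  if (!is_revcomp_closed(recognition)) {
    stop("recognition sequence '", recognition, "' is not closed under ",
         "reverse complementation; forward-strand scanning would miss ",
         "sites. Supply both strand patterns as separate enzymes.")
  }
  structure(
    list(name = name, recognition = recognition,
         site_length = nchar(recognition), methylation = methylation),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat("<enzyme_spec> ", x$name, ": ", x$recognition,
      " (", x$site_length, " bp)\n", sep = "")
  invisible(x)
}

#' IUPAC nucleotide code expansion
#' @return Named list mapping each IUPAC code to its base set.
#' @keywords internal
iupac_map <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

#' Expand an IUPAC pattern to all concrete DNA words
#' @param pattern IUPAC string.
#' @return Character vector of concrete sequences over {A,C,G,T}.
#' @keywords internal
expand_iupac <- function(pattern) {
  sets <- iupac_map()[strsplit(toupper(pattern), "")[[1]]]
  out <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(out[, rev(seq_along(sets)), drop = FALSE], 1, paste0, collapse = "")
}

#' Is a recognition set reverse-complement closed?
#' @keywords internal
is_revcomp_closed <- function(pattern) {
  words <- expand_iupac(pattern)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  setequal(words, rc)
}

#' Built-in restriction enzymes
#'
#' The four enzymes evaluated for chicken genome reduction: AvaII (GGWCC),
#' EcoRI (GAATTC), PstI (CTGCAG) and TaqI (TCGA). Their recognition sets are
#' all reverse-complement closed, so forward-strand scanning finds every
#' site.
#'
#' @return Named list of [enzyme()] objects.
#' @export
#' @examples
#' names(radseq_enzymes())
radseq_enzymes <- function() {
  list(
    AvaII = enzyme("AvaII", "GGWCC", "CpG and dcm methylation"),
    EcoRI = enzyme("EcoRI", "GAATTC", "CpG methylation"),
    PstI  = enzyme("PstI",  "CTGCAG", "Not sensitive"),
    TaqI  = enzyme("TaqI",  "TCGA", "dam methylation")
  )
}
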