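#' Derive a reproducible substream seed
#'
#' All stochastic stages of the simulator draw from their own substream so
#' that changing one stage (e.g. the trait model) never perturbs another
#' (e.g. the genome sequence). Substream seeds are derived deterministically
#' from a master seed and a stage name.
#'
#' @param seed Master integer seed.
#' @param name Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435.0)
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so package functions never disturb the
#' caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' Summary tables report proportions as percentages at two decimals with
#' conventional half-up rounding (0.005 rounds to 0.01), matching how such
#' tables are usually printed.
#'
#' @param part Numerator count.
#' @param total Denominator count.
#' @return Numeric percentage with two decimals.
#' @export
#' @examples
#' percent_of(21267, 270629)
percent_of <- function(part, total) {
  stopifnot(total > 0, part >= 0)
  round_half_up(100 * part / total, 2)
}

#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Sample standard deviation that is 0 for singletons
#' @keywords internal
sd0 <- function(x) {
  if (length(x) < 2) return(0)
  stats::sd(x)
}
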