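#' Kinetic parameterization of one mRNA
#'
#' Bundles everything the traffic simulator needs for one transcript: the
#' per-codon elongation-rate profile omega_i (1/s), the initiation rate
#' alpha, the termination rate beta (by default the elongation rate of the
#' last sense codon), the drop-off rate gamma, and the ribosomal footprint
#' d in codons (the minimum spacing between A-sites).
#'
#' @param rates Numeric vector of per-codon elongation rates (1/s), one per
#'   sense codon; or a list as returned by [sequence_profiles()].
#' @param init_rate Initiation rate alpha (1/s), >= 0 (0 disables initiation
#'   for pre-loaded-ribosome runs).
#' @param term_rate Termination rate beta (1/s); default: rate of the last
#'   codon.
#' @param dropoff_rate Drop-off rate gamma (1/s), >= 0; active at every
#'   codon except the last, where termination applies instead.
#' @param footprint Ribosomal footprint d in codons (default 10).
#' @return Object of class `translation_system`.
#' @export
translation_system <- function(rates, init_rate, term_rate = NULL,
                               dropoff_rate = 0, footprint = 10) {
  if (is.list(rates)) rates <- rates$rates
  rates <- as.numeric(rates)
  n <- length(rates)
  if (n < 1L || any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be a positive finite numeric vector")
  if (is.null(term_rate)) term_rate <- rates[n]
  footprint <- as.integer(footprint)
  stopifnot(is.finite(init_rate), init_rate >= 0,
            is.finite(term_rate), term_rate > 0,
            is.finite(dropoff_rate), dropoff_rate >= 0,
            footprint >= 1L)
  if (n < footprint)
    stop("sequence of ", n, " codons is shorter than the footprint (",
         footprint, ")")
  structure(list(rates = rates, init_rate = init_rate,
                 term_rate = term_rate, dropoff_rate = dropoff_rate,
                 footprint = footprint, n = n),
            class = "translation_system")
}

#' @export
print.translation_system <- function(x, ...) {
  m <- mean_rates(x$rates)
  cat(sprintf(
    "Translation system: %d codons, footprint %d\n  alpha = %.4g /s, beta = %.4g /s, gamma = %.4g /s\n  omega: mean %.4g /s (harmonic %.4g /s)\n",
    x$n, x$footprint, x$init_rate, x$term_rate, x$dropoff_rate,
    m["arithmetic"], m["harmonic"]))
  invisible(x)
}

#' Arithmetic and harmonic mean elongation rates
#'
#' @param rates Numeric rate profile (1/s).
#' @return Named vector `c(arithmetic=, harmonic=)`; the harmonic mean
#'   n / sum(1/omega_i) never exceeds the arithmetic mean.
#' @export
mean_rates <- function(rates) {
  if (is.list(rates)) rates <- rates$rates
  if (length(rates) == 0L) stop("empty rate profile")
  c(arithmetic = mean(rates), harmonic = length(rates) / sum(1 / rates))
}

#' Critical corner of the maximal-current regime
#'
#' For an exclusion process with extended particles of footprint `d`, the
#' maximal-current regime opens where the reduced initiation and
#' termination rates both exceed `1 / (sqrt(d) + 1)`.
#'
#' @param d Footprint length in codons, >= 1.
#' @return Dimensionless reduced rate.
#' @export
critical_corner <- function(d) {
  stopifnot(all(d >= 1))
  1 / (sqrt(d) + 1)
}

#' Analytic synthesis-time estimate
#'
#' The single-ribosome (traffic-free) expectation of the time to make one
#' protein: initiation wait 1/alpha, the sum of codon dwell times
#' sum(1/omega_i), and the termination wait 1/beta. Valid in the
#' initiation-limited low-density regime; ribosome interactions only
#' lengthen the true time.
#'
#' @param sys A [translation_system()].
#' @return Estimated synthesis time in seconds.
#' @export
estimate_synthesis_time <- function(sys) {
  stopifnot(inherits(sys, "translation_system"))
  1 / sys$init_rate + sum(1 / sys$rates) + 1 / sys$term_rate
}
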