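default_burn_in <- function(sys) {
  10 * sys$n / mean_rates(sys$rates)["harmonic"]
}

default_measure <- function(sys) {
  # long enough for ~500 expected completions at the initiation-limited
  # current p ~ alpha
  500 / sys$init_rate
}

as_sim_result <- function(raw, sys, burn_in, measure, method) {
  res <- list(current = raw$current,
              density = raw$density,
              avg_density = mean(raw$density),
              completions = raw$completions,
              dropoffs = raw$dropoffs,
              initiations = raw$initiations,
              completions_total = raw$completions_total,
              dropoffs_total = raw$dropoffs_total,
              initiations_total = raw$initiations_total,
              final_positions = raw$final_positions,
              mean_transit = raw$mean_transit,
              n_transit = raw$n_transit,
              absorbed = raw$absorbed,
              burn_in = burn_in, measure = measure,
              n = sys$n, method = method)
  class(res) <- "cosem_sim"
  res
}

#' Simulate ribosome traffic on one mRNA
#'
#' Continuous-time (Gillespie) integration of the codon-specific elongation
#' model: ribosomes initiate at rate alpha when the first `d` codons are
#' clear, advance codon by codon at the local elongation rate under mutual
#' exclusion (A-sites at least `d` codons apart), drop off at rate gamma
#' from any codon but the last, and terminate from the last codon at rate
#' beta. Statistics (current, time-averaged A-site density per codon,
#' event counts, transit times of completed proteins) are accumulated only
#' after `burn_in`.
#'
#' @param object A [translation_system()].
#' @param nsim Number of independent replicate runs.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param burn_in Equilibration time (s); default `10 n / <omega>_h`.
#' @param measure Measurement time (s); default long enough for about 500
#'   completions at the initiation-limited current.
#' @param init_positions Integer A-site positions pre-loaded at time 0
#'   (ascending, spaced >= d).
#' @param move_rule `"exclusion"` (default): the event set contains
#'   realizable transitions only. `"paired"`: blocked forward/initiation
#'   attempts stay in the event set, set a flag, and the flagged follower
#'   advances together with its blocker; kept for comparison, see the
#'   methods vignette.
#' @param max_events Safety cap on the number of events per run.
#' @param ... Unused.
#' @return For `nsim = 1` a `cosem_sim` object; otherwise a list of them.
#'   The current is completions per second per mRNA during `measure`.
#' @export
simulate.translation_system <- function(object, nsim = 1, seed = NULL,
                                        burn_in = NULL, measure = NULL,
                                        init_positions = integer(),
                                        move_rule = c("exclusion", "paired"),
                                        max_events = 5e8, ...) {
  sys <- object
  move_rule <- match.arg(move_rule)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- default_burn_in(sys)
  if (is.null(measure)) measure <- default_measure(sys)
  stopifnot(burn_in >= 0, measure > 0)
  init_positions <- as.integer(init_positions)
  if (length(init_positions)) {
    if (is.unsorted(init_positions, strictly = TRUE) ||
        any(diff(init_positions) < sys$footprint) ||
        min(init_positions) < 1L || max(init_positions) > sys$n)
      stop("init_positions must be ascending, in [1, n], spaced >= footprint")
  }
  runs <- lapply(seq_len(nsim), function(i) {
    raw <- cpp_gillespie(sys$rates, sys$init_rate, sys$term_rate,
                         sys$dropoff_rate, sys$footprint, burn_in, measure,
                         init_positions,
                         if (move_rule == "paired") 1L else 0L, max_events)
    if (raw$completions == 0)
      warning("no completions during the measurement window; current = 0",
              call. = FALSE)
    as_sim_result(raw, sys, burn_in, measure, "gillespie")
  })
  if (nsim == 1L) runs[[1L]] else runs
}

#' Fixed-increment traffic simulation
#'
#' The same dynamics as [simulate.translation_system()] integrated by
#' advancing time in small steps `dt`, each event firing with probability
#' rate * dt. Used to cross-validate the event-driven integrator.
#'
#' @param sys A [translation_system()].
#' @param dt Time increment (s); `dt * max(rate)` must be <= 0.1 and a
#'   warning is issued above 0.01.
#' @param total Measurement time (s).
#' @param seed Integer seed.
#' @param burn_in Equilibration time (s); default as in `simulate()`.
#' @param init_positions Pre-loaded A-site positions.
#' @return A `cosem_sim` object.
#' @export
simulate_fixed_timestep <- function(sys, dt, total, seed = NULL,
                                    burn_in = NULL,
                                    init_positions = integer()) {
  stopifnot(inherits(sys, "translation_system"), dt > 0, total > 0)
  maxrate <- max(sys$rates, sys$init_rate, sys$term_rate, sys$dropoff_rate)
  if (dt * maxrate > 0.1)
    stop("dt too large: dt * max(rate) = ", signif(dt * maxrate, 3),
         " exceeds 0.1")
  if (dt * maxrate > 0.01)
    warning("dt * max(rate) = ", signif(dt * maxrate, 3),
            " > 0.01; results may be biased", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- default_burn_in(sys)
  raw <- cpp_fixed_step(sys$rates, sys$init_rate, sys$term_rate,
                        sys$dropoff_rate, sys$footprint, dt, burn_in, total,
                        as.integer(init_positions))
  as_sim_result(raw, sys, burn_in, total, "fixed_timestep")
}

#' @export
print.cosem_sim <- function(x, ...) {
  cat(sprintf(
    "Ribosome traffic simulation (%s): %d codons\n  current p = %.5g proteins/(s*mRNA)  [%d completions / %.4g s]\n  average A-site density %.5g, drop-offs %d\n",
    x$method, x$n, x$current, as.integer(x$completions), x$measure,
    x$avg_density, as.integer(x$dropoffs)))
  if (is.finite(x$mean_transit))
    cat(sprintf("  mean transit of completed proteins: %.5g s (n = %d)\n",
                x$mean_transit, as.integer(x$n_transit)))
  invisible(x)
}

#' Elementary transition rates of a ribosome configuration
#'
#' Enumerates the Gillespie event set for a given configuration: forward
#' steps (zero rate when blocked under the exclusion rule), drop-off,
#' termination, and initiation, together with their normalized selection
#' probabilities q_m / Q.
#'
#' @param positions Ascending A-site codon positions (possibly empty).
#' @param sys A [translation_system()].
#' @param move_rule As in [simulate.translation_system()]; under
#'   `"paired"` blocked attempts keep their rate.
#' @return data.frame with columns `event`, `ribosome` (NA for initiation),
#'   `rate`, `prob`, and attribute `total_rate` (Q).
#' @export
transition_rates <- function(positions, sys,
                             move_rule = c("exclusion", "paired")) {
  stopifnot(inherits(sys, "translation_system"))
  move_rule <- match.arg(move_rule)
  positions <- as.integer(positions)
  n <- sys$n; d <- sys$footprint
  ev <- list()
  N <- length(positions)
  for (k in seq_len(N)) {
    p <- positions[k]
    if (p == n) {
      ev[[length(ev) + 1L]] <- data.frame(event = "terminate", ribosome = k,
                                          rate = sys$term_rate)
    } else {
      blocked <- k < N && positions[k + 1L] - p <= d
      rate <- if (blocked && move_rule == "exclusion") 0 else sys$rates[p]
      if (rate > 0)
        ev[[length(ev) + 1L]] <- data.frame(event = "move", ribosome = k,
                                            rate = rate)
      if (sys$dropoff_rate > 0)
        ev[[length(ev) + 1L]] <- data.frame(event = "dropoff", ribosome = k,
                                            rate = sys$dropoff_rate)
    }
  }
  init_ok <- N == 0L || positions[1L] > d
  if (sys$init_rate > 0 && (init_ok || move_rule == "paired"))
    ev[[length(ev) + 1L]] <- data.frame(event = "initiate", ribosome = NA_integer_,
                                        rate = sys$init_rate)
  if (length(ev) == 0L)
    stop("absorbing state: empty event set")
  out <- do.call(rbind, ev)
  out$prob <- out$rate / sum(out$rate)
  attr(out, "total_rate") <- sum(out$rate)
  out
}

#' Phase diagram of the uniform-rate traffic model
#'
#' Scans a grid of reduced initiation rates (alpha/omega) and reduced
#' termination rates (beta/omega) for a uniform elongation-rate transcript,
#' recording the steady-state average A-site density and current at each
#' grid point, and labels each point with its expected dynamic regime:
#' low density (LD, initiation-limited), high density (HD, jammed), or
#' maximal current (MC) when both reduced rates exceed the critical corner
#' [critical_corner()].
#'
#' @param alpha_bar,beta_bar Numeric grid values in (0, 1).
#' @param gamma_bar Reduced drop-off rate gamma/omega.
#' @param length Transcript length in codons.
#' @param footprint Ribosomal footprint d.
#' @param seed Integer seed.
#' @param burn_in,measure Simulation windows (s, with omega = 1).
#' @return data.frame of class `cosem_phase` with one row per grid point:
#'   `alpha_bar`, `beta_bar`, `density`, `current`, `regime`; the corner
#'   value is stored in attribute `corner`.
#' @export
phase_diagram <- function(alpha_bar, beta_bar, gamma_bar = 0, length = 300,
                          footprint = 10, seed = NULL, burn_in = 3000,
                          measure = 20000) {
  stopifnot(all(alpha_bar > 0), all(alpha_bar < 1),
            all(beta_bar > 0), all(beta_bar < 1))
  if (!is.null(seed)) set.seed(seed)
  corner <- critical_corner(footprint)
  grid <- expand.grid(alpha_bar = alpha_bar, beta_bar = beta_bar,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ab <- grid$alpha_bar[i]; bb <- grid$beta_bar[i]
    sys <- translation_system(rep(1, length), init_rate = ab,
                              term_rate = bb, dropoff_rate = gamma_bar,
                              footprint = footprint)
    sim <- suppressWarnings(
      simulate(sys, burn_in = burn_in, measure = measure))
    c(density = sim$avg_density, current = sim$current)
  })
  res <- do.call(rbind, res)
  grid$density <- res[, "density"]
  grid$current <- res[, "current"]
  grid$regime <- ifelse(grid$alpha_bar > corner & grid$beta_bar > corner,
                        "MC", ifelse(grid$alpha_bar <= grid$beta_bar,
                                     "LD", "HD"))
  attr(grid, "corner") <- corner
  attr(grid, "footprint") <- footprint
  class(grid) <- c("cosem_phase", "data.frame")
  grid
}

#' @export
print.cosem_phase <- function(x, ...) {
  cat(sprintf(
    "Phase-diagram scan: %d grid points, footprint %d, MC corner at %.4f\n",
    nrow(x), attr(x, "footprint"), attr(x, "corner")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @importFrom graphics image axis points
#' @export
plot.cosem_phase <- function(x, ...) {
  a <- sort(unique(x$alpha_bar)); b <- sort(unique(x$beta_bar))
  z <- matrix(NA_real_, length(a), length(b))
  for (i in seq_len(nrow(x)))
    z[match(x$alpha_bar[i], a), match(x$beta_bar[i], b)] <- x$density[i]
  image(a, b, z, xlab = "reduced initiation rate",
        ylab = "reduced termination rate",
        main = "Average ribosome density", ...)
  points(attr(x, "corner"), attr(x, "corner"), pch = 8)
  invisible(x)
}
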