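#' Simplified (linear + quadratic GC3) expression score
#'
#' A light-weight stand-in for the full boosted score: every feature
#' enters linearly except GC3 content, which gets an additional quadratic
#' term so that a balanced GC3 can be optimal.
#'
#' @param features data.frame (or one-row list) of feature values.
#' @param coefficients List with elements `intercept` (scalar), `linear`
#'   (named numeric vector of slopes) and `gc3_quadratic` (scalar
#'   coefficient on gc3^2).
#' @return Numeric score vector.
#' @export
simplified_score <- function(features, coefficients) {
  stopifnot(is.list(coefficients))
  intercept <- coefficients$intercept %||% 0
  lin <- coefficients$linear %||% numeric()
  q <- coefficients$gc3_quadratic %||% 0
  out <- rep(intercept, NROW(features))
  for (nm in names(lin)) {
    xv <- features[[nm]]
    if (is.null(xv)) stop("feature '", nm, "' missing from features")
    out <- out + lin[[nm]] * xv
  }
  if (q != 0) {
    if (is.null(features[["gc3"]])) stop("feature 'gc3' missing from features")
    out <- out + q * features[["gc3"]]^2
  }
  out
}

#' Linear/quadratic approximation of a fitted score
#'
#' Regresses each fitted partial function onto a linear term (quadratic
#' for GC3) over the training data, yielding coefficients usable with
#' [simplified_score()].
#'
#' @param object A fitted [expression_score()].
#' @return Coefficient list for [simplified_score()].
#' @export
fit_simplified <- function(object) {
  stopifnot(inherits(object, "expression_score"))
  lin <- c()
  intercept <- object$offset
  q <- 0
  for (nm in selected_features(object)) {
    xv <- object$train$x[[nm]]
    fv <- partial_function(object, nm, xv)
    if (nm == "gc3") {
      fit <- lm.fit(cbind(1, xv, xv^2), fv)
      intercept <- intercept + fit$coefficients[1L]
      lin[nm] <- fit$coefficients[2L]
      q <- unname(fit$coefficients[3L])
    } else {
      fit <- lm.fit(cbind(1, xv), fv)
      intercept <- intercept + fit$coefficients[1L]
      lin[nm] <- fit$coefficients[2L]
    }
  }
  list(intercept = unname(intercept), linear = lin, gc3_quadratic = q)
}

#' Calibrate the initiation rate against protein levels
#'
#' Scans a grid of initiation rates, simulates the ribosome current of
#' every sequence at each candidate rate, and returns the rate maximizing
#' the correlation between simulated currents and observed protein levels
#' (ties broken toward the smallest rate). A near-flat correlation profile
#' triggers a warning: the data then do not constrain the initiation rate.
#'
#' @param seqs Named character vector of coding sequences (>= 10).
#' @param table A [codon_rate_table()].
#' @param protein Numeric protein levels, one per sequence.
#' @param alpha_grid Candidate initiation rates (1/s).
#' @param method Correlation type, `"pearson"` or `"spearman"`.
#' @param seed Integer seed.
#' @param flat_tol Correlation range below which the profile is flagged
#'   flat.
#' @param ... Simulation settings passed to
#'   [simulate.translation_system()] (e.g. `measure`).
#' @param dropoff_rate,footprint Traffic-model parameters.
#' @return List of class `alpha_calibration`: `alpha` (the selected rate),
#'   `profile` (data.frame of alpha vs correlation), `currents` (matrix,
#'   sequences x grid).
#' @export
calibrate_initiation_rate <- function(seqs, table, protein, alpha_grid,
                                      method = c("pearson", "spearman"),
                                      seed = NULL, flat_tol = 0.05,
                                      dropoff_rate = 0, footprint = 10,
                                      ...) {
  method <- match.arg(method)
  stopifnot(length(seqs) == length(protein), length(alpha_grid) >= 1)
  if (length(seqs) < 10L) stop("need at least 10 sequences")
  if (!is.null(seed)) set.seed(seed)
  profs <- lapply(seqs, sequence_profiles, table = table)
  currents <- sapply(sort(alpha_grid), function(a) {
    vapply(profs, function(p) {
      sys <- translation_system(p$rates, init_rate = a,
                                dropoff_rate = dropoff_rate,
                                footprint = footprint)
      suppressWarnings(simulate(sys, ...)$current)
    }, numeric(1L))
  })
  currents <- matrix(currents, nrow = length(seqs))
  cors <- apply(currents, 2L, function(cc) {
    suppressWarnings(cor(cc, protein, method = method))
  })
  grid <- sort(alpha_grid)
  if (all(is.na(cors))) stop("correlation undefined for every grid point")
  # uninformative profile: all correlations alike, or none separable from
  # zero at ~2 Fisher-z standard errors
  z_se <- 1 / sqrt(max(length(seqs) - 3, 1))
  z <- atanh(pmin(pmax(cors, -0.999), 0.999))
  if (diff(range(cors, na.rm = TRUE)) < flat_tol ||
      all(abs(z) < 1.96 * z_se, na.rm = TRUE))
    warning("flat or insignificant correlation profile: the protein ",
            "levels do not constrain the initiation rate", call. = FALSE)
  best <- grid[which.max(replace(cors, is.na(cors), -Inf))]
  structure(list(alpha = best,
                 profile = data.frame(alpha = grid, correlation = cors),
                 currents = currents),
            class = "alpha_calibration")
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat(sprintf("Initiation-rate calibration: alpha* = %.4g /s\n", x$alpha))
  print(x$profile, row.names = FALSE, digits = 3)
  invisible(x)
}
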