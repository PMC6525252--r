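#' Boosting configuration
#'
#' Tuning constants of the component-wise P-spline boosting fit behind
#' [expression_score()].
#'
#' @param step Learning rate nu in (0, 1] applied to each selected
#'   base-learner update (default 0.1).
#' @param knots Number of interior knots of each cubic B-spline basis
#'   (default 20).
#' @param penalty_order Order of the difference penalty on spline
#'   coefficients (default 2).
#' @param df Effective degrees of freedom of each smooth base-learner; the
#'   ridge penalty weight is solved from this (default 4).
#' @param mstop_max Upper bound on boosting iterations (default 300).
#' @param bootstrap Number of bootstrap replicates used to pick the
#'   stopping iteration by out-of-sample squared error (default 25).
#' @param mstop_rule `"1se"` (default): smallest iteration whose mean
#'   out-of-bag error is within one standard error of the minimum — the
#'   usual parsimony rule, which suppresses spurious late selections of
#'   noise features on the flat part of the error curve; `"min"`: the
#'   exact minimizer.
#' @param train_frac Fraction of observations used for fitting; the rest
#'   is held out for [explained_variance()] (default 0.7).
#' @param monotone Features constrained to monotonically increasing
#'   partial functions.
#' @param linear Features modeled as plain linear effects.
#' @return List of class `boosting_config`.
#' @export
boosting_config <- function(step = 0.1, knots = 20, penalty_order = 2,
                            df = 4, mstop_max = 300, bootstrap = 25,
                            train_frac = 0.7,
                            monotone = c("current", "avg_rate", "log_mrna"),
                            linear = "hairpins",
                            mstop_rule = c("1se", "min")) {
  stopifnot(step > 0, step <= 1, knots >= 4, penalty_order >= 1,
            df > 1, mstop_max >= 1, bootstrap >= 2,
            train_frac > 0, train_frac <= 1)
  mstop_rule <- match.arg(mstop_rule)
  structure(list(step = step, knots = knots,
                 penalty_order = penalty_order, df = df,
                 mstop_max = mstop_max, bootstrap = bootstrap,
                 train_frac = train_frac, monotone = monotone,
                 linear = linear, mstop_rule = mstop_rule),
            class = "boosting_config")
}

# ---- base learners ---------------------------------------------------------

spline_knots <- function(range, n_interior, degree = 3L) {
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) hi <- lo + max(1e-8, abs(lo) * 1e-8)
  interior <- seq(lo, hi, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  c(rep(lo, degree + 1L), interior, rep(hi, degree + 1L))
}

spline_basis <- function(x, knots, degree = 3L) {
  lo <- knots[1L]; hi <- knots[length(knots)]
  x <- pmin(pmax(x, lo), hi)
  splines::splineDesign(knots, x, ord = degree + 1L)
}

diff_penalty <- function(p, order) {
  D <- diff(diag(p), differences = order)
  crossprod(D)
}

# Solve the ridge weight so that the smoother has the requested effective df.
lambda_for_df <- function(BtB, K, df) {
  tr_df <- function(loglam) {
    sum(diag(solve(BtB + 10^loglam * K, BtB))) - df
  }
  lo <- -8; hi <- 12
  if (tr_df(lo) < 0) return(10^lo)
  if (tr_df(hi) > 0) return(10^hi)
  10^stats::uniroot(tr_df, c(lo, hi), tol = 1e-4)$root
}

# Construct the base-learner descriptions from training data.
build_learners <- function(x, config) {
  lapply(names(x), function(nm) {
    xv <- x[[nm]]
    rng <- range(xv)
    type <- if (nm %in% config$linear) "linear" else "spline"
    monotone <- nm %in% config$monotone
    if (diff(rng) == 0) type <- "constant"   # degenerate feature
    l <- list(name = nm, type = type, monotone = monotone, range = rng)
    if (type == "spline") {
      l$knots <- spline_knots(rng, config$knots)
      B <- spline_basis(xv, l$knots)
      K <- diff_penalty(ncol(B), config$penalty_order)
      l$lambda <- lambda_for_df(crossprod(B), K, config$df)
      l$K <- K
    }
    l
  })
}

learner_design <- function(l, xv) {
  switch(l$type,
         spline = spline_basis(xv, l$knots),
         linear = cbind(1, pmin(pmax(xv, l$range[1]), l$range[2])),
         constant = matrix(1, length(xv), 1L))
}

learner_solver <- function(l, B) {
  pen <- switch(l$type,
                spline = l$lambda * l$K,
                linear = diag(1e-10, ncol(B)),
                constant = matrix(1e-10, 1L, 1L))
  solve(crossprod(B) + pen, t(B))
}

iso_project <- function(b) {
  as.numeric(isoreg(seq_along(b), b)$yf)
}

# Component-wise least-squares boosting path. Each iteration fits every
# base-learner to the current residuals, forms the nu-scaled candidate
# update (with isotone projection of the coefficients for monotone
# learners), and commits the one with the lowest post-update loss; the
# training loss is therefore non-increasing by construction, and the path
# stops early if no candidate improves it.
fit_path <- function(learners, B, M, y, nu, mstop, oob = NULL) {
  n <- length(y)
  Kf <- length(learners)
  offset <- mean(y)
  beta <- lapply(B, function(b) numeric(ncol(b)))
  contrib <- matrix(0, n, Kf)
  fit <- rep(offset, n)
  trace <- integer(0)
  loss <- numeric(0)
  oob_err <- NULL
  if (!is.null(oob)) {
    oob_contrib <- matrix(0, length(oob$y), Kf)
    oob_fit <- rep(offset, length(oob$y))
    oob_err <- numeric(mstop)
  }
  for (m in seq_len(mstop)) {
    r <- y - fit
    cur <- sum(r^2)
    best_k <- 0L; best_loss <- cur; best_beta <- NULL; best_fit <- NULL
    for (k in seq_len(Kf)) {
      if (learners[[k]]$type == "constant") next
      g <- drop(M[[k]] %*% r)
      cand <- beta[[k]] + nu * g
      if (learners[[k]]$monotone) cand <- iso_project(cand)
      fk <- drop(B[[k]] %*% cand)
      lk <- sum((r + contrib[, k] - fk)^2)
      if (lk < best_loss - 1e-12) {
        best_loss <- lk; best_k <- k; best_beta <- cand; best_fit <- fk
      }
    }
    if (best_k == 0L) break
    fit <- fit - contrib[, best_k] + best_fit
    contrib[, best_k] <- best_fit
    beta[[best_k]] <- best_beta
    trace <- c(trace, best_k)
    loss <- c(loss, best_loss / n)
    if (!is.null(oob)) {
      oob_contrib[, best_k] <- drop(oob$B[[best_k]] %*% best_beta)
      oob_fit <- offset + rowSums(oob_contrib)
      oob_err[m] <- mean((oob$y - oob_fit)^2)
    }
  }
  if (!is.null(oob) && length(trace) < mstop) {
    done <- length(trace)
    fillv <- if (done == 0) mean((oob$y - offset)^2) else oob_err[done]
    if (done < mstop) oob_err[(done + 1L):mstop] <- fillv
  }
  list(beta = beta, trace = trace, loss = loss, offset = offset,
       fitted = fit, oob_err = oob_err)
}

select_mstop <- function(learners, x, y, config, seed_offset = 0L) {
  n <- length(y)
  mmax <- config$mstop_max
  err <- matrix(NA_real_, config$bootstrap, mmax)
  for (b in seq_len(config$bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob_idx <- setdiff(seq_len(n), unique(idx))
    if (length(oob_idx) < 2L) next
    Bb <- lapply(learners, function(l) learner_design(l, x[[l$name]][idx]))
    Mb <- lapply(seq_along(learners),
                 function(k) learner_solver(learners[[k]], Bb[[k]]))
    Bo <- lapply(learners, function(l) learner_design(l, x[[l$name]][oob_idx]))
    p <- fit_path(learners, Bb, Mb, y[idx], config$step, mmax,
                  oob = list(B = Bo, y = y[oob_idx]))
    err[b, ] <- p$oob_err
  }
  mean_err <- colMeans(err, na.rm = TRUE)
  n_ok <- colSums(!is.na(err))
  se_err <- apply(err, 2L, sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1L))
  m_min <- which.min(mean_err)
  m_1se <- which(mean_err <= mean_err[m_min] + se_err[m_min])[1L]
  list(mstop = if (identical(config$mstop_rule, "min")) m_min else m_1se,
       mstop_min = m_min, oob_error = mean_err, oob_se = se_err)
}

# ---- the fitting front-end -------------------------------------------------

#' Fit the additive protein expression score
#'
#' Fits an additive model `y = offset + sum_k f_k(x_k) + e` for log protein
#' abundance by component-wise least-squares boosting. Each candidate
#' feature gets one base-learner: a penalized cubic B-spline (P-spline)
#' smooth by default, constrained to be monotonically increasing for the
#' features in `config$monotone`, or a plain linear effect for those in
#' `config$linear`. At every iteration the base-learner that most reduces
#' the squared-error loss is updated by a fraction `config$step` of its
#' fit to the current residuals; features never selected contribute
#' exactly zero. The stopping iteration is chosen by minimizing the mean
#' out-of-bag squared error over `config$bootstrap` bootstrap replicates,
#' and the explained variance R^2 is evaluated on a held-out fraction
#' `1 - config$train_frac` of the data.
#'
#' @param formula Model formula, e.g. `y ~ .` or
#'   `y ~ current + gc3 + log_mrna`.
#' @param data data.frame containing the outcome and numeric features.
#' @param config A [boosting_config()].
#' @param seed Integer seed governing the train/test split and the
#'   bootstrap; recorded in the fitted object.
#' @param mstop Optional fixed number of boosting iterations (skips the
#'   bootstrap selection).
#' @return Object of class `expression_score` with methods `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @seealso [explained_variance()], [simplified_score()]
#' @export
expression_score <- function(formula, data, config = boosting_config(),
                             seed = NULL, mstop = NULL) {
  stopifnot(inherits(config, "boosting_config"))
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  x <- mf[, -1L, drop = FALSE]
  x <- x[, vapply(x, is.numeric, logical(1L)), drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 candidate features")
  if (anyNA(y)) stop("missing values in the outcome")
  if (anyNA(x))
    stop("missing values in feature(s): ",
         paste(names(x)[vapply(x, anyNA, logical(1L))], collapse = ", "))
  n <- nrow(x)
  if (n < 20L) stop("need at least 20 observations")
  if (!is.null(seed)) set.seed(seed)

  n_train <- max(2L, round(config$train_frac * n))
  train_idx <- if (n_train >= n) seq_len(n) else sort(sample.int(n, n_train))
  test_idx <- setdiff(seq_len(n), train_idx)
  xt <- x[train_idx, , drop = FALSE]
  yt <- y[train_idx]

  learners <- build_learners(xt, config)
  names(learners) <- names(xt)
  Bt <- lapply(learners, function(l) learner_design(l, xt[[l$name]]))
  Mt <- lapply(seq_along(learners),
               function(k) learner_solver(learners[[k]], Bt[[k]]))

  oob_error <- NULL
  if (is.null(mstop)) {
    if (var(yt) == 0) {
      mstop <- 0L
    } else {
      sel <- select_mstop(learners, xt, yt, config)
      mstop <- sel$mstop
      oob_error <- sel$oob_error
    }
  }
  path <- fit_path(learners, Bt, Mt, yt, config$step, mstop)

  model <- structure(list(
    call = match.call(),
    feature_names = names(xt),
    learners = learners,
    beta = setNames(path$beta, names(xt)),
    offset = path$offset,
    trace = names(xt)[path$trace],
    loss = path$loss,
    mstop = length(path$trace),
    mstop_requested = mstop,
    oob_error = oob_error,
    config = config,
    split = list(train = train_idx, test = test_idx, seed = seed),
    train = list(x = xt, y = yt),
    test = list(x = x[test_idx, , drop = FALSE], y = y[test_idx]),
    fitted_values = path$fitted), class = "expression_score")
  model$r_squared <- if (length(test_idx) >= 3L && var(y[test_idx]) > 0)
    explained_variance(model) else NA_real_
  model
}

#' Features selected by the boosting path
#'
#' @param object A fitted [expression_score()].
#' @return Character vector of features with nonzero partial functions, in
#'   order of first selection.
#' @export
selected_features <- function(object) {
  unique(object$trace)
}

#' @export
print.expression_score <- function(x, ...) {
  cat("Additive protein expression score (component-wise P-spline boosting)\n")
  cat(sprintf("  %d candidate features, %d boosting iterations (step %.2g)\n",
              length(x$feature_names), x$mstop, x$config$step))
  sel <- selected_features(x)
  cat("  selected: ", if (length(sel)) paste(sel, collapse = ", ")
                      else "(none; offset-only model)", "\n", sep = "")
  if (is.finite(x$r_squared))
    cat(sprintf("  held-out R^2 = %.3f (on %d observations)\n",
                x$r_squared, length(x$test$y)))
  invisible(x)
}

#' @export
summary.expression_score <- function(object, ...) {
  sel_tab <- table(factor(object$trace, levels = object$feature_names))
  contrib_sd <- vapply(seq_along(object$feature_names), function(k) {
    B <- learner_design(object$learners[[k]],
                        object$train$x[[object$feature_names[k]]])
    sd(drop(B %*% object$beta[[k]]))
  }, numeric(1L))
  out <- data.frame(feature = object$feature_names,
                    constraint = vapply(object$learners, function(l) {
                      if (l$type == "linear") "linear"
                      else if (isTRUE(l$monotone)) "monotone" else "smooth"
                    }, character(1L)),
                    selections = as.integer(sel_tab),
                    contribution_sd = contrib_sd)
  res <- list(table = out, mstop = object$mstop,
              r_squared = object$r_squared, offset = object$offset)
  class(res) <- "summary.expression_score"
  res
}

#' @export
print.summary.expression_score <- function(x, ...) {
  cat(sprintf("Boosted additive score: offset %.4g, mstop %d, held-out R^2 %.3f\n",
              x$offset, x$mstop, x$r_squared))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.expression_score <- function(object, ...) {
  c(list(offset = object$offset), object$beta)
}

#' @export
fitted.expression_score <- function(object, ...) object$fitted_values

#' @export
residuals.expression_score <- function(object, ...) {
  object$train$y - object$fitted_values
}

#' Evaluate one partial function
#'
#' @param object A fitted [expression_score()].
#' @param feature Feature name.
#' @param x Values at which to evaluate (clamped to the training range).
#' @return Numeric vector f_k(x).
#' @export
partial_function <- function(object, feature, x) {
  stopifnot(inherits(object, "expression_score"))
  k <- match(feature, object$feature_names)
  if (is.na(k)) stop("unknown feature: ", feature)
  B <- learner_design(object$learners[[k]], x)
  drop(B %*% object$beta[[k]])
}

#' Predict the (weighted) expression score
#'
#' Evaluates `offset + sum_k v_k f_k(x_k)`. With all weights 1 (the
#' default) this is the plain additive score; setting a weight to zero
#' removes that feature, which also makes scoring legal when the feature is
#' undetermined (e.g. transcript abundance for a not-yet-expressed
#' construct). Feature values outside the training range are clamped to it
#' and the number of clamped values is attached as attribute `clamped`.
#'
#' @param object A fitted [expression_score()].
#' @param newdata data.frame with the feature columns.
#' @param weights Named nonnegative vector of per-feature weights v_k;
#'   missing names default to 1.
#' @param ... Unused.
#' @return Numeric score vector with attribute `clamped`.
#' @export
predict.expression_score <- function(object, newdata, weights = NULL, ...) {
  v <- setNames(rep(1, length(object$feature_names)), object$feature_names)
  if (!is.null(weights)) {
    if (is.null(names(weights))) stop("weights must be named")
    unknown <- setdiff(names(weights), object$feature_names)
    if (length(unknown)) stop("unknown feature(s) in weights: ",
                              paste(unknown, collapse = ", "))
    if (any(weights < 0)) stop("weights must be nonnegative")
    v[names(weights)] <- weights
  }
  nr <- nrow(newdata)
  out <- rep(object$offset, nr)
  clamped <- 0L
  sel <- selected_features(object)
  for (k in seq_along(object$feature_names)) {
    nm <- object$feature_names[k]
    if (v[nm] == 0) next
    xv <- newdata[[nm]]
    absent <- is.null(xv) || anyNA(xv)
    if (absent) {
      if (nm %in% sel)
        stop("feature '", nm, "' is absent but has weight ", v[nm],
             " and a nonzero partial function")
      next
    }
    clamped <- clamped + sum(xv < object$learners[[k]]$range[1] |
                               xv > object$learners[[k]]$range[2])
    out <- out + v[nm] * partial_function(object, nm, xv)
  }
  attr(out, "clamped") <- clamped
  out
}

#' Explained variance on held-out data
#'
#' `R^2 = 1 - SS_res / SS_tot` of the score against observed outcomes on
#' data disjoint from the training set (by default the internal 30%
#' hold-out recorded at fitting time).
#'
#' @param object A fitted [expression_score()].
#' @param newdata,y Optional explicit held-out features and outcomes.
#' @return R^2.
#' @export
explained_variance <- function(object, newdata = NULL, y = NULL) {
  stopifnot(inherits(object, "expression_score"))
  if (is.null(newdata)) {
    newdata <- object$test$x
    y <- object$test$y
  }
  if (length(y) < 2L) stop("need at least 2 held-out observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("degenerate held-out outcome: zero variance")
  pred <- predict(object, newdata)
  1 - sum((y - pred)^2) / ss_tot
}

#' @importFrom graphics par plot lines rug
#' @export
plot.expression_score <- function(x, features = selected_features(x), ...) {
  if (length(features) == 0L) {
    message("offset-only model; nothing to plot")
    return(invisible(x))
  }
  old <- par(mfrow = c(ceiling(length(features) / 2), min(2, length(features))))
  on.exit(par(old))
  for (nm in features) {
    k <- match(nm, x$feature_names)
    g <- seq(x$learners[[k]]$range[1], x$learners[[k]]$range[2],
             length.out = 200)
    plot(g, partial_function(x, nm, g), type = "l", xlab = nm,
         ylab = sprintf("f(%s)", nm), ...)
    rug(x$train$x[[nm]])
  }
  invisible(x)
}
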