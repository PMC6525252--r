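# Synonymous-codon sequence design driven by the expression score.

# transcript abundance is undetermined for a designed construct: weight it 0
default_opt_weights <- function(model) {
  if ("log_mrna" %in% model$feature_names) c(log_mrna = 0)
  else setNames(numeric(0), character(0))
}

norm01 <- function(x) {
  r <- max(x) - min(x)
  if (r == 0) rep(0, length(x)) else (x - min(x)) / r
}

#' Synonymous-codon proposal distribution
#'
#' For one codon position, the probability of proposing each synonymous
#' codon l is proportional to
#' `s1 * norm(omega_l) + s2 * norm(a_l) + eps`, where `norm` rescales the
#' family's elongation rates / accuracies to the unit interval. The regularization
#' `eps` is the relative weight of the slowest, least accurate synonym; a
#' family whose synonyms are kinetically indistinguishable gets the
#' uniform distribution (both normalized terms vanish by the 0/0 = 0
#' convention).
#'
#' @param codon A sense codon (the synonym family is derived from it) or a
#'   one-letter amino-acid code.
#' @param table A [codon_rate_table()].
#' @param s1,s2 Nonnegative weights of rate and accuracy (defaults 1).
#' @param eps Regularization (default 0.05).
#' @return Named probability vector over the family's codons (sums to 1).
#' @export
proposal_probabilities <- function(codon, table, s1 = 1, s2 = 1,
                                   eps = 0.05) {
  stopifnot(s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0 && eps <= 0)
    stop("s1, s2 and eps may not all vanish")
  syn <- synonymous_codons(codon)
  idx <- match(syn, table$codon)
  w <- s1 * norm01(table$elongation_rate[idx]) +
       s2 * norm01(table$accuracy[idx]) + eps
  if (sum(w) <= 0) w <- rep(1, length(w))
  setNames(w / sum(w), syn)
}

#' Locally optimal seed sequence
#'
#' Chooses at each position the synonym maximizing the combined normalized
#' rate and accuracy `s1 * norm(omega) + s2 * norm(a)`; ties are broken
#' toward the alphabetically smallest codon for reproducibility.
#'
#' @param x A coding DNA sequence or a one-letter amino-acid string.
#' @param table A [codon_rate_table()].
#' @param s1,s2 Criterion weights as in [proposal_probabilities()].
#' @return Coding DNA sequence (no stop codon).
#' @export
initial_sequence <- function(x, table, s1 = 1, s2 = 1) {
  aa <- if (grepl("^[ACGTUacgtu]+$", x) && nchar(x) %% 3L == 0L)
    translate_cds(x) else toupper(x)
  aas <- strsplit(aa, "")[[1L]]
  codons <- vapply(aas, function(a) {
    syn <- synonymous_codons(a)
    idx <- match(syn, table$codon)
    crit <- s1 * norm01(table$elongation_rate[idx]) +
            s2 * norm01(table$accuracy[idx])
    syn[which.max(crit)]    # syn is alphabetical; which.max takes first
  }, character(1L))
  paste(codons, collapse = "")
}

sample_proposal <- function(wt_codons, pi_list, frozen) {
  out <- wt_codons
  for (i in seq_along(out)) {
    if (frozen[i]) next
    p <- pi_list[[i]]
    if (length(p) > 1L)
      out[i] <- sample(names(p), 1L, prob = p)
  }
  out
}

#' Score-driven synonymous sequence optimization
#'
#' Searches synonymous variants of a wildtype coding sequence for extreme
#' protein expression scores. Candidate sequences are drawn position-wise
#' from the proposal distribution of [proposal_probabilities()] (frozen
#' positions keep the wildtype codon), features are recomputed for every
#' candidate, and the weighted score is evaluated; a candidate is retained
#' when it beats the best score so far. The wildtype and the locally
#' optimal seed of [initial_sequence()] are always evaluated first, so the
#' best score is never worse than the wildtype's under maximization. The
#' search stops when the coefficient of variation of the running top-`m`
#' scores falls below `cv_threshold`, or after `max_proposals` candidates.
#'
#' @param wildtype Wildtype coding sequence (terminal stop allowed).
#' @param table A [codon_rate_table()].
#' @param model A fitted [expression_score()].
#' @param objective `"maximize"` or `"minimize"` (deoptimization).
#' @param weights Score weights v_k; default: transcript abundance
#'   (`log_mrna`) weighted 0 and everything else 1, the configuration for
#'   designing constructs whose transcript levels are undetermined.
#' @param s1,s2,eps Proposal-distribution parameters.
#' @param frozen Integer codon positions copied from the wildtype (e.g.
#'   `1:50` to preserve a slow-codon ramp).
#' @param m Length of the score buffer for the stopping rule (default
#'   100).
#' @param cv_threshold Coefficient-of-variation threshold (default 0.05).
#' @param max_proposals Proposal budget.
#' @param buffer `"top"` (default): the m best scores seen so far;
#'   `"records"`: the m most recent record-breaking scores.
#' @param seed Integer seed.
#' @param ... Feature/simulation settings passed to [compute_features()]
#'   (e.g. `init_rate`, `measure`, `engine`).
#' @return Object of class `codon_opt`: best sequence and score, wildtype
#'   score, relative score, score trajectory, proposal count, convergence
#'   flag.
#' @export
optimize_codons <- function(wildtype, table, model,
                            objective = c("maximize", "minimize"),
                            weights = NULL, s1 = 1, s2 = 1, eps = 0.05,
                            frozen = integer(), m = 100,
                            cv_threshold = 0.05, max_proposals = 1000,
                            buffer = c("top", "records"), seed = NULL,
                            ...) {
  objective <- match.arg(objective)
  buffer <- match.arg(buffer)
  stopifnot(m >= 2, cv_threshold > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- default_opt_weights(model)
  sgn <- if (objective == "maximize") 1 else -1

  wt_prof <- sequence_profiles(wildtype, table)
  wt_codons <- wt_prof$codons
  n <- length(wt_codons)
  wt_protein <- translate_cds(wildtype)
  frozen_mask <- rep(FALSE, n)
  if (length(frozen)) {
    stopifnot(all(frozen >= 1), all(frozen <= n))
    frozen_mask[frozen] <- TRUE
  }
  pi_list <- lapply(wt_codons, proposal_probabilities, table = table,
                    s1 = s1, s2 = s2, eps = eps)

  score_of <- function(codons) {
    seqs <- paste(codons, collapse = "")
    stopifnot(translate_cds(seqs) == wt_protein)
    feats <- compute_features(seqs, table, ...)
    list(seq = seqs,
         score = unname(predict(model, feats, weights = weights)[1L]))
  }

  wt_eval <- score_of(wt_codons)
  seed_codons <- split_codons(initial_sequence(wt_protein, table, s1, s2))
  seed_codons[frozen_mask] <- wt_codons[frozen_mask]
  seed_eval <- score_of(seed_codons)

  best <- wt_eval
  buf <- numeric(0)
  trajectory <- numeric(0)
  push <- function(buf, s) {
    if (buffer == "top") {
      buf <- sort(c(buf, s), decreasing = (objective == "maximize"))
      head(buf, m)
    } else {
      tail(c(buf, s), m)   # caller pushes records only
    }
  }
  consider <- function(ev) {
    if (sgn * ev$score > sgn * best$score) {
      best <<- ev
      if (buffer == "records") buf <<- push(buf, ev$score)
    }
    if (buffer == "top") buf <<- push(buf, ev$score)
    trajectory <<- c(trajectory, best$score)
  }
  converged_now <- function() {
    if (length(buf) < m) return(FALSE)
    mu <- mean(buf)
    if (sd(buf) == 0) return(TRUE)
    if (mu == 0) return(FALSE)
    sd(buf) / abs(mu) < cv_threshold
  }

  consider(wt_eval)
  consider(seed_eval)
  n_prop <- 2L
  converged <- converged_now()
  while (!converged && n_prop < max_proposals) {
    cand <- sample_proposal(wt_codons, pi_list, frozen_mask)
    consider(score_of(cand))
    n_prop <- n_prop + 1L
    converged <- converged_now()
  }

  shift <- if (wt_eval$score <= 0) 1 - wt_eval$score else 0
  structure(list(
    best_seq = best$seq, best_score = best$score,
    wildtype_score = wt_eval$score,
    relative_score = (best$score + shift) / (wt_eval$score + shift),
    score_shift = shift, objective = objective,
    trajectory = trajectory, proposals = n_prop,
    converged = converged, buffer = buf,
    frozen = which(frozen_mask)), class = "codon_opt")
}

#' @export
print.codon_opt <- function(x, ...) {
  cat(sprintf(
    "Synonymous sequence optimization (%s): %d proposals%s\n  wildtype score %.5g -> best %.5g (relative %.4g%s)\n",
    x$objective, x$proposals,
    if (x$converged) ", converged" else ", proposal budget reached",
    x$wildtype_score, x$best_score, x$relative_score,
    if (x$score_shift != 0)
      sprintf(", scores shifted by %+.3g", x$score_shift) else ""))
  invisible(x)
}

#' Expression score of a variant relative to wildtype
#'
#' @param variant,wildtype Synonymous coding sequences (same protein).
#' @param table A [codon_rate_table()].
#' @param model A fitted [expression_score()].
#' @param weights Score weights; default drops transcript abundance.
#' @param ... Feature settings passed to [compute_features()].
#' @return List with `ratio`, `variant_score`, `wildtype_score`, `shift`
#'   (a positive constant added to both scores before forming the ratio
#'   when the wildtype score is nonpositive).
#' @export
relative_score <- function(variant, wildtype, table, model, weights = NULL,
                           ...) {
  if (translate_cds(variant) != translate_cds(wildtype))
    stop("variant and wildtype encode different proteins")
  if (is.null(weights)) weights <- default_opt_weights(model)
  sv <- unname(predict(model, compute_features(variant, table, ...),
                       weights = weights)[1L])
  sw <- unname(predict(model, compute_features(wildtype, table, ...),
                       weights = weights)[1L])
  shift <- if (sw <= 0) 1 - sw else 0
  list(ratio = (sv + shift) / (sw + shift), variant_score = sv,
       wildtype_score = sw, shift = shift)
}

#' Codon adaptation index
#'
#' Auxiliary comparison metric: the geometric mean over codons of the
#' relative adaptiveness w = f(codon) / max f(synonym) under a reference
#' codon-usage table. Single-codon families (Met, Trp) are excluded, as is
#' conventional.
#'
#' @param seq Coding sequence (terminal stop allowed).
#' @param usage Named numeric vector of reference codon frequencies (or
#'   counts) over the 61 sense codons.
#' @return CAI in (0, 1].
#' @export
cai <- function(seq, usage) {
  codons <- split_codons(seq)
  gc <- genetic_code()
  n <- length(codons)
  if (n > 0L && gc[codons[n]] == "*") codons <- codons[-n]
  if (any(gc[codons] == "*")) stop("internal stop codon")
  missing <- setdiff(sense_codons(), names(usage))
  if (length(missing)) stop("usage table missing codon(s): ",
                            paste(missing, collapse = ", "))
  w <- vapply(codons, function(cdn) {
    syn <- synonymous_codons(cdn)
    if (length(syn) == 1L) return(NA_real_)
    usage[cdn] / max(usage[syn])
  }, numeric(1L))
  w <- w[!is.na(w)]
  if (length(w) == 0L) stop("no multi-synonym codons in sequence")
  if (any(w <= 0)) stop("usage frequencies must be positive")
  exp(mean(log(w)))
}
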