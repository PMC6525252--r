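#' GC content at third codon positions
#'
#' @param seq Coding sequence (length divisible by 3).
#' @return Fraction of codons whose third nucleotide is G or C.
#' @export
gc3 <- function(seq) {
  codons <- split_codons(seq)
  third <- substr(codons, 3L, 3L)
  mean(third %in% c("G", "C"))
}

#' Bottleneck index of an elongation-rate profile
#'
#' The minimum over all contiguous windows of `window` codons of the
#' within-window mean elongation rate; low values flag clusters of slow
#' codons that throttle ribosome flow.
#'
#' @param rates Numeric rate profile (1/s) or a [sequence_profiles()] list.
#' @param window Window width in codons (default 10).
#' @return Minimum sliding-window mean rate (codons/s).
#' @export
bottleneck_index <- function(rates, window = 10) {
  if (is.list(rates)) rates <- rates$rates
  n <- length(rates)
  if (n < window)
    stop("profile of length ", n, " is shorter than the window (", window, ")")
  cs <- c(0, cumsum(rates))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  min(means)
}

#' Ramp index of an elongation-rate profile
#'
#' Mean elongation rate over the first `window` codons (default 30), the
#' region where slow "ramp" codons are thought to space out ribosomes.
#'
#' @param rates Numeric rate profile (1/s) or a [sequence_profiles()] list.
#' @param window Number of leading codons (default 30).
#' @return Mean rate over the leading window (codons/s).
#' @export
ramp_index <- function(rates, window = 30) {
  if (is.list(rates)) rates <- rates$rates
  if (length(rates) < window)
    stop("profile of length ", length(rates),
         " is shorter than the ramp window (", window, ")")
  mean(rates[seq_len(window)])
}

#' Sequence-wide translational accuracy
#'
#' The product of per-codon accuracies, computed in log space so that it
#' neither under- nor overflows for long sequences.
#'
#' @param accuracies Numeric vector in (0, 1], or a [sequence_profiles()]
#'   list.
#' @param log Return log(a) instead of a.
#' @return Probability that every codon is decoded by a cognate tRNA.
#' @export
accuracy_product <- function(accuracies, log = FALSE) {
  if (is.list(accuracies)) accuracies <- accuracies$accuracies
  stopifnot(all(accuracies > 0), all(accuracies <= 1))
  la <- sum(base::log(accuracies))
  if (log) la else exp(la)
}

#' Compute the candidate predictors of protein expression
#'
#' Computes the ten sequence features entering the protein expression
#' score: the simulated ribosome current (x1), arithmetic mean elongation
#' rate (x2), bottleneck index (x3), sequence accuracy (x4), 5' folding
#' energy over the first 30 codons (x5), log10 transcript abundance (x6,
#' `NA` when undetermined), GC3 content (x7), ramp index (x8), hairpin
#' count in the 5' structure (x9) and length in codons (x10). The harmonic
#' mean rate is carried along as auxiliary information.
#'
#' @param seq Coding sequence.
#' @param table A [codon_rate_table()].
#' @param init_rate,term_rate,dropoff_rate,footprint Kinetic parameters of
#'   the traffic model (see [translation_system()]).
#' @param transcript_abundance Transcript abundance (linear scale) or
#'   `NULL` when undetermined.
#' @param seed Integer seed for the current simulation.
#' @param burn_in,measure Simulation windows; `NULL` for defaults.
#' @param engine Folding engine, see [fold_5prime()].
#' @return One-row data.frame with columns `current`, `avg_rate`,
#'   `bottleneck`, `accuracy`, `folding_energy`, `log_mrna`, `gc3`, `ramp`,
#'   `hairpins`, `length`, `harmonic_rate`.
#' @export
compute_features <- function(seq, table, init_rate = 0.1, term_rate = NULL,
                             dropoff_rate = 0.003, footprint = 10,
                             transcript_abundance = NULL, seed = NULL,
                             burn_in = NULL, measure = NULL,
                             engine = c("internal", "vienna")) {
  engine <- match.arg(engine)
  prof <- sequence_profiles(seq, table)
  sys <- translation_system(prof$rates, init_rate = init_rate,
                            term_rate = term_rate,
                            dropoff_rate = dropoff_rate,
                            footprint = footprint)
  sim <- suppressWarnings(simulate(sys, seed = seed, burn_in = burn_in,
                                   measure = measure))
  fold <- fold_5prime(seq, engine = engine)
  m <- mean_rates(prof$rates)
  data.frame(
    current = sim$current,
    avg_rate = unname(m["arithmetic"]),
    bottleneck = bottleneck_index(prof$rates),
    accuracy = accuracy_product(prof$accuracies),
    folding_energy = fold$energy,
    log_mrna = if (is.null(transcript_abundance)) NA_real_
               else log10(transcript_abundance),
    gc3 = gc3(seq),
    ramp = ramp_index(prof$rates),
    hairpins = fold$hairpins,
    length = length(prof$rates),
    harmonic_rate = unname(m["harmonic"]))
}

#' Feature table for a set of sequences
#'
#' @param seqs Named character vector of coding sequences.
#' @param table A [codon_rate_table()].
#' @param transcript_abundance Optional named numeric vector (linear
#'   scale), matched to `names(seqs)`.
#' @param seed Integer seed; per-sequence simulation seeds are derived from
#'   it deterministically.
#' @param ... Passed to [compute_features()].
#' @return data.frame with an `id` column followed by the feature columns.
#' @export
feature_table <- function(seqs, table, transcript_abundance = NULL,
                          seed = NULL, ...) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- if (is.null(seed)) rep(list(NULL), length(seqs))
               else as.list(sample.int(.Machine$integer.max, length(seqs)))
  rows <- lapply(seq_along(seqs), function(i) {
    ta <- if (!is.null(transcript_abundance))
      unname(transcript_abundance[names(seqs)[i]]) else NULL
    compute_features(seqs[[i]], table, transcript_abundance = ta,
                     seed = sub_seeds[[i]], ...)
  })
  cbind(data.frame(id = names(seqs), stringsAsFactors = FALSE),
        do.call(rbind, rows))
}
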