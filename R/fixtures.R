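# Deterministic synthetic-fixture generators: every input the simulator,
# score and optimizer need, regenerable bit-identically from a seed.

#' Synthetic codon rate table
#'
#' Draws an independent elongation rate and accuracy for every sense
#' codon, so every synonym family has rate and accuracy spread. The
#' default rate range brackets organism-scale mean elongation rates of a
#' few to a few tens of codons per second.
#'
#' @param seed Integer seed.
#' @param rate_range Elongation-rate range (1/s), default `c(2, 45)`.
#' @param accuracy_range Accuracy range within (0, 1].
#' @param organism Label.
#' @return A [codon_rate_table()].
#' @export
make_rate_table <- function(seed, rate_range = c(2, 45),
                            accuracy_range = c(0.95, 0.9999),
                            organism = "synthetic") {
  stopifnot(all(rate_range > 0), diff(rate_range) >= 0,
            accuracy_range[1] > 0, accuracy_range[2] <= 1)
  set.seed(seed)
  codons <- sense_codons()
  rates <- runif(length(codons), rate_range[1], rate_range[2])
  acc <- runif(length(codons), accuracy_range[1], accuracy_range[2])
  codon_rate_table(setNames(rates, codons), setNames(acc, codons),
                   organism = organism)
}

#' Synthetic tRNA pool
#'
#' One tRNA species per sense codon with log-normal concentration; the
#' species of single-mismatch sense codons are assigned as near-cognates
#' and a fixed-size random draw of the remainder as non-cognates.
#'
#' @param seed Integer seed.
#' @param n_non Number of non-cognate species listed per codon.
#' @param conc_meanlog,conc_sdlog Log-normal concentration parameters.
#' @return A [trna_pool()].
#' @export
make_trna_pool <- function(seed, n_non = 5, conc_meanlog = 0,
                           conc_sdlog = 0.5) {
  set.seed(seed)
  codons <- sense_codons()
  species <- paste0("tRNA_", codons)
  conc <- setNames(stats::rlnorm(length(species), conc_meanlog, conc_sdlog),
                   species)
  one_off <- function(cdn) {
    nt <- c("A", "C", "G", "T")
    out <- character(0)
    for (p in 1:3) for (b in setdiff(nt, substr(cdn, p, p))) {
      v <- cdn
      substr(v, p, p) <- b
      out <- c(out, v)
    }
    intersect(out, codons)
  }
  assignment <- lapply(codons, function(cdn) {
    near <- setdiff(one_off(cdn), cdn)
    rest <- setdiff(codons, c(cdn, near))
    non <- sample(rest, min(n_non, length(rest)))
    list(cognate = paste0("tRNA_", cdn), near = paste0("tRNA_", near),
         non = paste0("tRNA_", non))
  })
  names(assignment) <- codons
  trna_pool(conc, assignment)
}

#' Random translatable coding sequences
#'
#' @param seed Integer seed.
#' @param n Number of genes.
#' @param length_range Length range in sense codons (>= 30).
#' @param terminal_stop Append a TAA stop codon.
#' @return Named character vector of CDSs starting with ATG and free of
#'   internal stops.
#' @export
make_genes <- function(seed, n, length_range = c(60, 200),
                       terminal_stop = TRUE) {
  stopifnot(length_range[1] >= 30)
  set.seed(seed)
  codons <- sense_codons()
  pool <- length_range[1]:length_range[2]
  lens <- pool[sample.int(length(pool), n, replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    body <- sample(codons, L - 1L, replace = TRUE)
    paste(c("ATG", body, if (terminal_stop) "TAA"), collapse = "")
  }, character(1L))
  setNames(seqs, sprintf("gene%04d", seq_len(n)))
}

#' Generative specification for benchmark datasets
#'
#' Describes the additive ground truth of a [make_benchmark()] dataset:
#' which features carry signal, the shape of each partial effect, and the
#' noise level. Effects act on internally standardized features
#' z = (x - mean) / sd: `linear` is `coef * z`, `monotone` is
#' `coef * tanh(z)` (increasing, saturating), `quadratic` is
#' `coef * (z^2 - 1) / sqrt(2)`.
#'
#' @param partials Named list (names are feature names) of
#'   `list(type = "linear"|"monotone"|"quadratic", coef = <numeric>)`.
#' @param sigma Gaussian noise standard deviation; `NULL` derives it from
#'   `target_r2` and the realized signal variance.
#' @param target_r2 Intended fraction of outcome variance carried by the
#'   signal (used only when `sigma` is `NULL`).
#' @param offset Outcome offset (log10 protein abundance scale).
#' @return List of class `benchmark_spec`.
#' @export
benchmark_spec <- function(partials = list(
                             current = list(type = "monotone", coef = 1),
                             gc3 = list(type = "quadratic", coef = 0.6)),
                           sigma = NULL, target_r2 = 0.5, offset = 1.5) {
  stopifnot(is.list(partials), length(partials) >= 1,
            is.null(sigma) || sigma >= 0,
            target_r2 > 0, target_r2 < 1)
  structure(list(partials = partials, sigma = sigma,
                 target_r2 = target_r2, offset = offset),
            class = "benchmark_spec")
}

eval_partial <- function(type, coef, z) {
  switch(type,
         linear = coef * z,
         monotone = coef * tanh(z),
         quadratic = coef * (z^2 - 1) / sqrt(2),
         stop("unknown partial type: ", type))
}

#' Synthetic expression benchmark with known additive truth
#'
#' Generates genes and a rate table, runs the real feature pipeline
#' (traffic simulation, folding, GC3, ...), and then simulates log10
#' protein abundances from a known additive model on those features plus
#' Gaussian noise. Because the generative partials and noise SD are
#' recorded, the explainable variance fraction is known exactly and
#' fitted models can be validated against it.
#'
#' @param seed Integer seed; everything (genes, table, abundances, noise)
#'   regenerates bit-identically from it.
#' @param n Number of genes.
#' @param spec A [benchmark_spec()].
#' @param table Optional [codon_rate_table()]; generated from `seed` if
#'   omitted.
#' @param length_range Gene length range (codons).
#' @param init_rate,dropoff_rate,footprint Traffic parameters for the
#'   feature pipeline.
#' @param measure Per-gene measurement window (s); the default targets a
#'   few hundred completions per gene.
#' @param engine Folding engine.
#' @return Object of class `cosem_benchmark` with elements `genes`,
#'   `table`, `transcript`, `features`, `data` (features plus outcome
#'   `y`), `signal`, `sigma`, `generative_r2`, `spec`, `seed`.
#' @export
make_benchmark <- function(seed, n = 200, spec = benchmark_spec(),
                           table = NULL, length_range = c(60, 150),
                           init_rate = 0.1, dropoff_rate = 0.003,
                           footprint = 10, measure = 3000,
                           engine = "internal") {
  stopifnot(inherits(spec, "benchmark_spec"))
  if (is.null(table)) table <- make_rate_table(seed)
  genes <- make_genes(seed + 1L, n, length_range)
  set.seed(seed + 2L)
  transcript <- setNames(10^rnorm(n, 1.5, 0.6), names(genes))
  features <- feature_table(genes, table, transcript_abundance = transcript,
                            seed = seed + 3L, init_rate = init_rate,
                            dropoff_rate = dropoff_rate,
                            footprint = footprint, measure = measure,
                            engine = engine)
  signal <- rep(0, n)
  realized <- list()
  for (nm in names(spec$partials)) {
    p <- spec$partials[[nm]]
    xv <- features[[nm]]
    if (is.null(xv)) stop("spec names unknown feature: ", nm)
    mu <- mean(xv); s <- sd(xv)
    if (s == 0) stop("feature ", nm, " is constant; cannot carry signal")
    g <- eval_partial(p$type, p$coef, (xv - mu) / s)
    realized[[nm]] <- list(type = p$type, coef = p$coef, center = mu,
                           scale = s)
    signal <- signal + g
  }
  sigma <- spec$sigma
  if (is.null(sigma))
    sigma <- sd(signal) * sqrt((1 - spec$target_r2) / spec$target_r2)
  set.seed(seed + 4L)
  y <- spec$offset + signal + rnorm(n, 0, sigma)
  var_s <- var(signal)
  data <- cbind(features, y = y)
  structure(list(genes = genes, table = table, transcript = transcript,
                 features = features, data = data, y = y, signal = signal,
                 sigma = sigma, offset = spec$offset,
                 realized_partials = realized,
                 generative_r2 = var_s / (var_s + sigma^2),
                 spec = spec, seed = seed), class = "cosem_benchmark")
}

#' Redraw benchmark outcomes with fresh noise
#'
#' Keeps the genes, features and generative signal of a benchmark fixed
#' and draws a new Gaussian noise realization; used for replicated
#' refitting experiments.
#'
#' @param bench A [make_benchmark()] object.
#' @param seed Integer seed for the new noise draw.
#' @return Numeric outcome vector.
#' @export
benchmark_outcomes <- function(bench, seed) {
  stopifnot(inherits(bench, "cosem_benchmark"))
  set.seed(seed)
  bench$offset + bench$signal + rnorm(length(bench$signal), 0, bench$sigma)
}

#' @export
print.cosem_benchmark <- function(x, ...) {
  cat(sprintf(
    "Synthetic expression benchmark: %d genes, generative R^2 = %.3f (sigma %.3g)\n  signal features: %s\n",
    length(x$genes), x$generative_r2, x$sigma,
    paste(names(x$spec$partials), collapse = ", ")))
  invisible(x)
}
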