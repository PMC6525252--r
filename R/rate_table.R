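#' Codon rate tables
#'
#' A codon rate table stores, for one organism or translation context, the
#' elongation rate omega (1/s) and decoding accuracy a (probability of
#' incorporating a cognate tRNA) of each of the 61 sense codons.
#'
#' @param rates Named numeric vector of elongation rates (1/s), names are
#'   sense codons.
#' @param accuracies Named numeric vector of accuracies in (0, 1], same
#'   names.
#' @param organism Free-text label.
#' @return An object of class `codon_rate_table`: a data.frame with columns
#'   `codon`, `elongation_rate`, `accuracy`, rows ordered alphabetically by
#'   codon, plus an `organism` attribute.
#' @export
codon_rate_table <- function(rates, accuracies, organism = "unspecified") {
  codons <- names(rates)
  if (is.null(codons) || is.null(names(accuracies)))
    stop("rates and accuracies must be named by codon")
  codons <- normalize_seq(codons)
  names(rates) <- codons
  names(accuracies) <- normalize_seq(names(accuracies))
  bad <- codons[!grepl("^[ACGT]{3}$", codons)]
  if (length(bad)) stop("malformed codon entries: ", paste(bad, collapse = ", "))
  stops <- intersect(codons, stop_codons())
  if (length(stops))
    stop("stop codons are not valid rate-table entries: ",
         paste(stops, collapse = ", "))
  missing <- setdiff(sense_codons(), codons)
  if (length(missing))
    stop("missing sense codon(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(codons, sense_codons())
  if (length(extra)) stop("unknown codon(s): ", paste(extra, collapse = ", "))
  if (!all(names(accuracies) %in% codons) || length(accuracies) != 61L)
    stop("accuracies must cover exactly the 61 sense codons")
  ord <- sense_codons()
  rates <- rates[ord]; accuracies <- accuracies[ord]
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("elongation rates must be positive and finite; offending codon(s): ",
         paste(ord[!is.finite(rates) | rates <= 0], collapse = ", "))
  if (any(!is.finite(accuracies)) || any(accuracies <= 0) ||
      any(accuracies > 1))
    stop("accuracies must lie in (0, 1]; offending codon(s): ",
         paste(ord[!is.finite(accuracies) | accuracies <= 0 |
                     accuracies > 1], collapse = ", "))
  out <- data.frame(codon = ord, elongation_rate = unname(rates),
                    accuracy = unname(accuracies),
                    stringsAsFactors = FALSE)
  attr(out, "organism") <- organism
  class(out) <- c("codon_rate_table", "data.frame")
  out
}

#' @export
print.codon_rate_table <- function(x, ...) {
  cat("Codon rate table (", attr(x, "organism"), "): 61 sense codons\n",
      sep = "")
  cat(sprintf("  elongation rate [1/s]: %.3g-%.3g (mean %.3g)\n",
              min(x$elongation_rate), max(x$elongation_rate),
              mean(x$elongation_rate)))
  cat(sprintf("  accuracy: %.4g-%.4g\n", min(x$accuracy), max(x$accuracy)))
  invisible(x)
}

#' Read a codon rate table from TSV
#'
#' Expects tab-separated columns `codon`, `elongation_rate`, `accuracy`;
#' `#` comment lines are allowed. Codons may use U instead of T.
#'
#' @param path File path.
#' @param organism Label; defaults to the file name.
#' @return A [codon_rate_table()].
#' @export
load_rate_table <- function(path, organism = basename(path)) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("codon", "elongation_rate", "accuracy")
  if (!all(need %in% names(d)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  codon_rate_table(setNames(d$elongation_rate, d$codon),
                   setNames(d$accuracy, d$codon), organism = organism)
}

#' Write a codon rate table to TSV
#'
#' Numeric values are written with full double precision so that
#' `load_rate_table(write_rate_table(x, p))` reproduces `x` exactly.
#'
#' @param table A [codon_rate_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "codon_rate_table"))
  lines <- c("codon\telongation_rate\taccuracy",
             sprintf("%s\t%.17g\t%.17g", table$codon,
                     table$elongation_rate, table$accuracy))
  writeLines(lines, path)
  invisible(path)
}

#' tRNA pools for the competition-based rate generator
#'
#' A minimal description of the tRNA supply: a concentration per tRNA
#' species and, for every sense codon, a partition of species into cognate,
#' near-cognate and non-cognate sets.
#'
#' @param concentrations Named nonnegative numeric vector, one entry per
#'   tRNA species (arbitrary units; only ratios matter).
#' @param assignment Named list over the 61 sense codons; each element is a
#'   list with character vectors `cognate`, `near`, `non` of species names.
#'   `near`/`non` may be omitted (empty).
#' @return An object of class `trna_pool`.
#' @export
trna_pool <- function(concentrations, assignment) {
  if (is.null(names(concentrations)) || any(concentrations < 0) ||
      any(!is.finite(concentrations)))
    stop("concentrations must be a named nonnegative numeric vector")
  missing <- setdiff(sense_codons(), names(assignment))
  if (length(missing))
    stop("assignment missing codon(s): ", paste(missing, collapse = ", "))
  for (cdn in sense_codons()) {
    a <- assignment[[cdn]]
    a$near <- a$near %||% character()
    a$non <- a$non %||% character()
    if (length(a$cognate %||% character()) == 0L)
      stop("codon ", cdn, " has no cognate tRNA species")
    all_sp <- c(a$cognate, a$near, a$non)
    if (anyDuplicated(all_sp))
      stop("codon ", cdn, ": cognate/near/non sets must be disjoint")
    unknown <- setdiff(all_sp, names(concentrations))
    if (length(unknown))
      stop("codon ", cdn, ": unknown species ", paste(unknown, collapse = ", "))
    assignment[[cdn]] <- a
  }
  structure(list(concentrations = concentrations, assignment = assignment),
            class = "trna_pool")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a rate table from ternary-complex competition
#'
#' A simplified competition scheme: the elongation rate of codon c is the
#' base rate scaled by the probability that a cognate ternary complex binds
#' first, `[cog] / ([cog] + w_near [near] + w_non [non])`, and the accuracy
#' is the cognate share of productive (cognate or near-cognate) binding,
#' `[cog] / ([cog] + w_near [near])`. The discrimination weights `w_near`
#' and `w_non` model the reduced acceptance of near- and non-cognate
#' complexes. The map is deterministic; `seed` is accepted for interface
#' symmetry with the other generators and ignored.
#'
#' @param pool A [trna_pool()].
#' @param base_rate Codon-independent maximal elongation rate (1/s).
#' @param w_near,w_non Discrimination weights between 0 and 1.
#' @param seed Ignored (the map is deterministic).
#' @param organism Label for the resulting table.
#' @return A [codon_rate_table()].
#' @export
synthesize_rate_table <- function(pool, base_rate = 22, w_near = 0.1,
                                  w_non = 0.01, seed = NULL,
                                  organism = "competition-synthetic") {
  stopifnot(inherits(pool, "trna_pool"), base_rate > 0)
  conc <- pool$concentrations
  codons <- sense_codons()
  rates <- acc <- setNames(numeric(length(codons)), codons)
  for (cdn in codons) {
    a <- pool$assignment[[cdn]]
    cog <- sum(conc[a$cognate])
    near <- sum(conc[a$near])
    non <- sum(conc[a$non])
    if (cog <= 0) stop("codon ", cdn, " has zero cognate concentration")
    rates[cdn] <- base_rate * cog / (cog + w_near * near + w_non * non)
    acc[cdn] <- cog / (cog + w_near * near)
  }
  codon_rate_table(rates, acc, organism = organism)
}

#' Map a coding sequence to rate and accuracy profiles
#'
#' @param seq Coding DNA (or RNA) sequence; a terminal stop codon is
#'   stripped silently, internal stop codons are an error.
#' @param table A [codon_rate_table()].
#' @return A list with `codons`, `rates` (1/s) and `accuracies`, one entry
#'   per sense codon.
#' @export
sequence_profiles <- function(seq, table) {
  stopifnot(inherits(table, "codon_rate_table"))
  codons <- split_codons(seq)
  n <- length(codons)
  gc <- genetic_code()
  aa <- gc[codons]
  if (anyNA(aa)) stop("untranslatable codon in sequence")
  if (n > 0L && aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n] }
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1L])
  if (length(codons) == 0L) stop("sequence has no sense codons")
  idx <- match(codons, table$codon)
  list(codons = codons,
       rates = table$elongation_rate[idx],
       accuracies = table$accuracy[idx])
}
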