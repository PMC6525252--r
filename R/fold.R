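# 5' secondary-structure features.
#
# The internal engine is a deterministic minimum-energy dynamic program
# over canonical pairs with a stacking bonus:
#   GC/CG -3.0, AU/UA -2.0, GU/UG -1.0 kcal/mol per pair,
#   -1.0 kcal/mol per directly stacked pair, hairpin loops >= 3 nt.
# It is a coarse thermodynamic caricature intended for ranking and for
# dependency-free tests; the "vienna" engine shells out to RNAfold when
# that binary is on the PATH.

.fold_const <- list(e_gc = -3.0, e_au = -2.0, e_gu = -1.0,
                    e_stack = -1.0, min_loop = 3L)

#' Fold the 5' end of a coding sequence
#'
#' Predicts the secondary structure of the first `window_nt` nucleotides
#' (default 90 nt = 30 codons) and reports its minimum free energy and the
#' number of hairpin loops. Shorter sequences are folded whole and flagged.
#'
#' @param seq Nucleotide sequence (DNA or RNA alphabet).
#' @param engine `"internal"` (default; deterministic base-pair
#'   energy-minimization with stacking bonus) or `"vienna"` (the RNAfold
#'   binary, if installed).
#' @param window_nt 5' window length in nucleotides.
#' @param min_stem Minimum stem length (stacked pairs) for a stem-loop to
#'   count as a hairpin.
#' @return List with `energy` (kcal/mol, <= 0), `hairpins` (count),
#'   `structure` (dot-bracket), `partial` (TRUE if the sequence was shorter
#'   than the window).
#' @export
fold_5prime <- function(seq, engine = c("internal", "vienna"),
                        window_nt = 90, min_stem = 3) {
  engine <- match.arg(engine)
  seq <- normalize_seq(seq)
  if (grepl("[^ACGT]", seq)) stop("non-ACGT character in sequence")
  partial <- nchar(seq) < window_nt
  sub <- substr(seq, 1L, min(nchar(seq), window_nt))
  if (engine == "internal") {
    code <- match(strsplit(sub, "")[[1L]], c("A", "C", "G", "T")) - 1L
    f <- cpp_fold(code, .fold_const$e_gc, .fold_const$e_au,
                  .fold_const$e_gu, .fold_const$e_stack,
                  .fold_const$min_loop)
    energy <- f$energy
    structure <- f$structure
  } else {
    if (Sys.which("RNAfold") == "")
      stop("folding engine 'vienna' unavailable: RNAfold not on PATH")
    out <- tryCatch(
      system2("RNAfold", c("--noPS"), input = sub, stdout = TRUE),
      error = function(e) stop("folding engine 'vienna' failed: ",
                               conditionMessage(e)))
    line <- out[length(out)]
    structure <- sub("^([.()]+).*$", "\\1", line)
    energy <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
    if (is.na(energy)) stop("folding engine 'vienna': unparseable output")
  }
  list(energy = energy, hairpins = count_hairpins(structure, min_stem),
       structure = structure, partial = partial)
}

#' Count hairpin loops in a dot-bracket structure
#'
#' A hairpin is a base pair enclosing no further pairs, supported by a stem
#' of at least `min_stem` directly stacked pairs.
#'
#' @param structure Dot-bracket string.
#' @param min_stem Minimum number of consecutive stacked pairs.
#' @return Nonnegative integer count.
#' @export
count_hairpins <- function(structure, min_stem = 3) {
  ch <- strsplit(structure, "")[[1L]]
  open <- integer()
  pair <- rep(NA_integer_, length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      j <- open[length(open)]
      open <- open[-length(open)]
      pair[i] <- j; pair[j] <- i
    }
  }
  count <- 0L
  for (i in seq_along(ch)) {
    j <- pair[i]
    if (is.na(j) || j < i) next
    inner <- if (j - i > 1L) pair[(i + 1L):(j - 1L)] else integer()
    if (any(!is.na(inner))) next   # not innermost
    # stem length: chain of directly stacked pairs (i-k, j+k)
    stem <- 1L
    while (i - stem >= 1L && j + stem <= length(ch) &&
           !is.na(pair[i - stem]) && pair[i - stem] == j + stem)
      stem <- stem + 1L
    if (stem >= min_stem) count <- count + 1L
  }
  count
}
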