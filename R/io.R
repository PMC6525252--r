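# FASTA and artifact I/O, plus the end-to-end pipeline.

#' Read sequences from FASTA
#'
#' Sequences are uppercased and RNA U is normalized to DNA T; record ids
#' (first whitespace-delimited token) are preserved as names.
#'
#' @param path FASTA file.
#' @return Named character vector (possibly empty).
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) return(setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  setNames(normalize_seq(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a two-column abundance TSV
#'
#' @param path TSV with header columns `id` and `abundance`.
#' @return Named numeric vector.
#' @export
read_abundance <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  if (!all(c("id", "abundance") %in% names(d)))
    stop("abundance table must have columns 'id' and 'abundance'")
  setNames(d$abundance, d$id)
}

# full-precision JSON round trip for doubles
to_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Serialize a fitted expression score to JSON
#'
#' Stores everything needed to re-score sequences to the identical value:
#' basis knots, coefficients, constraints, ranges, the boosting trace and
#' the split seed. The training/test data themselves are not stored.
#'
#' @param model A fitted [expression_score()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "expression_score"))
  learners <- lapply(model$learners, function(l)
    list(name = l$name, type = l$type, monotone = l$monotone,
         range = l$range, knots = l$knots, lambda = l$lambda))
  payload <- list(
    class = "expression_score", package = "cosem",
    version = as.character(utils::packageVersion("cosem")),
    feature_names = model$feature_names,
    offset = model$offset,
    learners = learners,
    beta = model$beta,
    trace = model$trace,
    mstop = model$mstop,
    split_seed = model$split$seed,
    r_squared = model$r_squared,
    config = unclass(model$config))
  writeLines(as.character(to_json(payload)), path)
  invisible(path)
}

#' Load a fitted expression score from JSON
#'
#' @param path JSON file written by [write_model()].
#' @return An `expression_score` object (without training data; `predict`
#'   and [partial_function()] work, refitting diagnostics do not).
#' @export
read_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  if (!identical(p$class, "expression_score"))
    stop("not a serialized expression_score: ", path)
  learners <- lapply(p$learners, function(l) {
    l$range <- as.numeric(l$range)
    if (!is.null(l$knots)) l$knots <- as.numeric(l$knots)
    l
  })
  names(learners) <- vapply(learners, `[[`, character(1L), "name")
  cfg <- p$config
  config <- boosting_config(step = cfg$step, knots = cfg$knots,
                            penalty_order = cfg$penalty_order, df = cfg$df,
                            mstop_max = cfg$mstop_max,
                            bootstrap = cfg$bootstrap,
                            train_frac = cfg$train_frac,
                            monotone = cfg$monotone, linear = cfg$linear,
                            mstop_rule = cfg$mstop_rule %||% "1se")
  structure(list(call = NULL, feature_names = p$feature_names,
                 learners = learners,
                 beta = setNames(lapply(p$beta, as.numeric),
                                 p$feature_names),
                 offset = p$offset,
                 trace = as.character(p$trace),
                 loss = numeric(0), mstop = p$mstop,
                 oob_error = NULL, config = config,
                 split = list(seed = p$split_seed),
                 train = NULL, test = NULL,
                 fitted_values = NULL, r_squared = p$r_squared),
            class = "expression_score")
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(to_json(obj)), f)
  unname(tools::md5sum(f))
}

#' Run the feature -> fit -> optimize pipeline
#'
#' Drives the full workflow from a single configuration list: compute the
#' feature table for a set of sequences (generated fixtures or a FASTA
#' file), optionally fit the expression score against protein abundances,
#' optionally optimize a sequence, and write all artifacts plus a
#' machine-readable run manifest into `out_dir`. Reruns with the same
#' configuration produce an identical manifest hash.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `out_dir`; `seed`; either `fasta` (path) or `fixtures`
#'   (`list(n =, length_range =)`); optional `rates` (path; a synthetic
#'   table is generated otherwise); optional `transcript` and `abundance`
#'   (paths to id/abundance TSVs); optional `sim`
#'   (`list(init_rate =, dropoff_rate =, footprint =, measure =)`);
#'   `fit = TRUE` to fit the score (requires `abundance`); optional
#'   `optimize` (`list(id =, objective =, frozen =, m =, max_proposals =)`,
#'   requires a fitted or supplied `model` path).
#' @return Invisibly, a list of artifact paths and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$seed))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  sim <- config$sim %||% list()
  sim_args <- list(init_rate = sim$init_rate %||% 0.1,
                   dropoff_rate = sim$dropoff_rate %||% 0.003,
                   footprint = sim$footprint %||% 10,
                   measure = sim$measure %||% 3000)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  seqs <- stage("sequences", {
    if (!is.null(config$fasta)) read_fasta(config$fasta)
    else if (!is.null(config$fixtures))
      make_genes(seed, config$fixtures$n %||% 50,
                 unlist(config$fixtures$length_range %||% c(60, 150)))
    else stop("config needs 'fasta' or 'fixtures'")
  })
  table <- stage("rates", {
    if (!is.null(config$rates)) load_rate_table(config$rates)
    else make_rate_table(seed + 1L)
  })
  transcript <- if (!is.null(config$transcript))
    stage("transcript", read_abundance(config$transcript)) else NULL

  paths <- list()
  feats <- stage("features", do.call(feature_table, c(
    list(seqs = seqs, table = table, transcript_abundance = transcript,
         seed = seed + 2L), sim_args)))
  paths$features <- file.path(config$out_dir, "features.tsv")
  write.table(feats, paths$features, sep = "\t", quote = FALSE,
              row.names = FALSE)

  model <- NULL
  if (isTRUE(config$fit)) {
    model <- stage("fit", {
      if (is.null(config$abundance))
        stop("fitting requires 'abundance'")
      ab <- read_abundance(config$abundance)
      d <- feats[feats$id %in% names(ab), , drop = FALSE]
      d$y <- log10(ab[d$id])
      drop_cols <- c("id", "harmonic_rate",
                     if (all(is.na(d$log_mrna))) "log_mrna")
      expression_score(y ~ ., d[, setdiff(names(d), drop_cols)],
                       seed = seed + 3L)
    })
    paths$model <- file.path(config$out_dir, "model.json")
    write_model(model, paths$model)
  } else if (!is.null(config$model)) {
    model <- stage("model", read_model(config$model))
  }

  if (!is.null(config$optimize)) {
    opt_cfg <- config$optimize
    if (is.null(model))
      stop("pipeline stage 'optimize' failed: no fitted or supplied model")
    res <- stage("optimize", {
      id <- opt_cfg$id %||% names(seqs)[1L]
      do.call(optimize_codons, c(
        list(wildtype = seqs[[id]], table = table, model = model,
             objective = opt_cfg$objective %||% "maximize",
             frozen = opt_cfg$frozen %||% integer(),
             m = opt_cfg$m %||% 100,
             max_proposals = opt_cfg$max_proposals %||% 500,
             seed = seed + 4L), sim_args))
    })
    paths$result <- file.path(config$out_dir, "result.json")
    writeLines(as.character(to_json(list(
      best_score = res$best_score, wildtype_score = res$wildtype_score,
      relative_score = res$relative_score, proposals = res$proposals,
      converged = res$converged))), paths$result)
    paths$optimized_fasta <- file.path(config$out_dir, "optimized.fasta")
    write_fasta(setNames(res$best_seq, "optimized"), paths$optimized_fasta)
  }

  manifest <- list(package = "cosem",
                   version = as.character(utils::packageVersion("cosem")),
                   seed = seed,
                   config_md5 = md5_of(config),
                   artifacts = lapply(paths, function(p)
                     unname(tools::md5sum(p))))
  manifest$hash <- md5_of(manifest)
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  writeLines(as.character(to_json(manifest)), paths$manifest)
  invisible(list(paths = paths, manifest = manifest, model = model))
}
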