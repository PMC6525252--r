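# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

uniform_table <- function(rate = 22, accuracy = 0.99) {
  codons <- sense_codons()
  codon_rate_table(setNames(rep(rate, 61), codons),
                   setNames(rep(accuracy, 61), codons),
                   organism = "uniform")
}

fix_table <- function() memo("table", make_rate_table(101))

fix_genes <- function() memo("genes", make_genes(102, 6, c(60, 120)))

# small benchmark + fitted score shared by feature/optimizer/io tests
fix_bench_small <- function() {
  memo("bench_small", make_benchmark(103, n = 60, measure = 800))
}

fix_model_small <- function() {
  memo("model_small", {
    b <- fix_bench_small()
    d <- b$data[, setdiff(names(b$data), c("id", "harmonic_rate"))]
    expression_score(y ~ ., d,
                     config = boosting_config(mstop_max = 100, bootstrap = 5),
                     seed = 104)
  })
}

# an offset-only model (constant outcome): flat score landscape
fix_model_flat <- function() {
  memo("model_flat", {
    b <- fix_bench_small()
    d <- b$data[, setdiff(names(b$data), c("id", "harmonic_rate"))]
    d$y <- 2
    expression_score(y ~ ., d,
                     config = boosting_config(mstop_max = 20, bootstrap = 3),
                     seed = 105)
  })
}

# Exact stationary current of the open d=1 exclusion process on a short
# lattice, via the master equation: independent oracle for the simulator.
tasep_master_current <- function(L, alpha, beta, omega = 1) {
  n_states <- 2^L
  occ <- function(s) as.integer(intToBits(s)[1:L])
  Q <- matrix(0, n_states, n_states)
  for (s in 0:(n_states - 1L)) {
    o <- occ(s)
    if (o[1] == 0L) {                       # entry
      t <- s + 1L
      Q[s + 1L, t + 1L] <- Q[s + 1L, t + 1L] + alpha
    }
    if (L > 1L) for (i in 1:(L - 1L)) {     # bulk hops
      if (o[i] == 1L && o[i + 1L] == 0L) {
        t <- s - 2^(i - 1L) + 2^i
        Q[s + 1L, t + 1L] <- Q[s + 1L, t + 1L] + omega
      }
    }
    if (o[L] == 1L) {                       # exit
      t <- s - 2^(L - 1L)
      Q[s + 1L, t + 1L] <- Q[s + 1L, t + 1L] + beta
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, n_states))
  pi <- qr.solve(A, c(rep(0, n_states), 1))
  p_lastocc <- sum(pi[sapply(0:(n_states - 1L),
                             function(s) occ(s)[L] == 1L)])
  beta * p_lastocc
}

# mean and standard error of replicate simulated currents
rep_current <- function(sys, seeds, ...) {
  cur <- vapply(seeds, function(s)
    suppressWarnings(simulate(sys, seed = s, ...)$current), numeric(1))
  c(mean = mean(cur), se = sd(cur) / sqrt(length(cur)))
}
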