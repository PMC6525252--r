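test_that("event probabilities follow the normalized-rate rule", {
  sys <- translation_system(rep(1, 30), init_rate = 2, term_rate = 1,
                            dropoff_rate = 1, footprint = 10)
  tr <- transition_rates(15L, sys)
  expect_setequal(tr$event, c("move", "dropoff", "initiate"))
  expect_equal(tr$prob[tr$event == "move"], 0.25)
  expect_equal(tr$prob[tr$event == "dropoff"], 0.25)
  expect_equal(tr$prob[tr$event == "initiate"], 0.5)
  expect_equal(sum(tr$prob), 1)
  expect_equal(attr(tr, "total_rate"), 4)

  # ribosome at the last codon terminates at beta, no drop-off there
  tr2 <- transition_rates(30L, sys)
  expect_setequal(tr2$event, c("terminate", "initiate"))

  # blocked follower: zero rate under exclusion, full rate under paired
  tr3 <- transition_rates(c(5L, 15L), sys)
  expect_false(any(tr3$event == "move" & tr3$ribosome == 1))
  tr4 <- transition_rates(c(5L, 15L), sys, move_rule = "paired")
  expect_true(any(tr4$event == "move" & tr4$ribosome == 1))

  # empty event set signals the absorbing state
  sys0 <- translation_system(rep(1, 30), init_rate = 0, dropoff_rate = 0)
  expect_error(transition_rates(integer(), sys0), "absorbing")
})

test_that("simulation is seed-reproducible and respects exclusion", {
  sys <- translation_system(rep(1, 60), init_rate = 0.3, dropoff_rate = 0.01)
  a <- simulate(sys, seed = 1, burn_in = 100, measure = 2000)
  b <- simulate(sys, seed = 1, burn_in = 100, measure = 2000)
  expect_identical(a$current, b$current)
  expect_identical(a$density, b$density)
  for (s in 1:5) {
    r <- simulate(sys, seed = s, burn_in = 50, measure = 500)
    if (length(r$final_positions) > 1)
      expect_true(all(diff(r$final_positions) >= sys$footprint))
    expect_true(all(r$density >= 0 & r$density <= 1 + 1e-12))
  }
})

test_that("count conservation holds exactly over any run", {
  sys <- translation_system(rep(1.5, 80), init_rate = 0.5,
                            dropoff_rate = 0.02)
  for (s in 1:4) {
    r <- simulate(sys, seed = s, burn_in = 200, measure = 3000)
    expect_identical(r$initiations_total,
                     r$completions_total + r$dropoffs_total +
                       length(r$final_positions))
  }
})

test_that("short-lattice current matches the exact master equation", {
  alpha <- 0.4; beta <- 0.6; L <- 6
  exact <- tasep_master_current(L, alpha, beta)
  sys <- translation_system(rep(1, L), init_rate = alpha, term_rate = beta,
                            dropoff_rate = 0, footprint = 1)
  r <- rep_current(sys, 1:6, burn_in = 500, measure = 20000)
  expect_lt(abs(r["mean"] - exact), 3 * r["se"] + 1e-4)
})

test_that("a pre-loaded ribosome with no initiation completes exactly once", {
  sys <- translation_system(rep(2, 60), init_rate = 0, dropoff_rate = 0)
  r <- suppressWarnings(simulate(sys, seed = 3, burn_in = 0, measure = 500,
                                 init_positions = 5L))
  expect_identical(r$completions_total, 1)
  expect_identical(r$dropoffs_total, 0)
  # same contract for the fixed-increment integrator
  rf <- suppressWarnings(simulate_fixed_timestep(
    sys, dt = 0.004, total = 500, seed = 4, burn_in = 0,
    init_positions = 5L))
  expect_identical(rf$completions_total, 1)
  # with no ribosomes at all the state is absorbing
  expect_error(simulate(sys, seed = 1, burn_in = 0, measure = 10),
               "absorbing")
})

test_that("very fast drop-off kills the current", {
  sys <- translation_system(rep(10, 60), init_rate = 0.5,
                            dropoff_rate = 1000)
  r <- suppressWarnings(simulate(sys, seed = 2, burn_in = 50, measure = 500))
  expect_identical(r$completions, 0)
  expect_identical(r$current, 0)
})

test_that("current is monotone non-increasing in the drop-off rate", {
  rates <- sequence_profiles(fix_genes()[[1]], fix_table())$rates
  cur <- vapply(c(0, 0.02, 0.1, 0.5), function(g) {
    sys <- translation_system(rates, init_rate = 0.2, dropoff_rate = g)
    suppressWarnings(simulate(sys, seed = 11, burn_in = 200,
                              measure = 8000)$current)
  }, numeric(1))
  expect_true(all(diff(cur) <= 0))
})

test_that("single-ribosome completion odds match the survival product", {
  rates <- sequence_profiles(fix_genes()[[2]], fix_table())$rates
  gam <- 0.5
  sys <- translation_system(rates, init_rate = 0.02, dropoff_rate = gam)
  theo <- prod(head(rates, -1) / (head(rates, -1) + gam))
  r <- simulate(sys, seed = 7, burn_in = 500, measure = 4e5)
  n <- r$completions + r$dropoffs
  p_hat <- r$completions / n
  se <- sqrt(theo * (1 - theo) / n)
  expect_lt(abs(p_hat - theo), 4 * se)
})

test_that("synthesis-time estimate matches its closed form and the
           initiation-limited simulation", {
  sys <- translation_system(c(2, 4), init_rate = 1e6, term_rate = 1e6,
                            footprint = 1)
  expect_equal(estimate_synthesis_time(sys), 0.75, tolerance = 1e-5)
  sys2 <- translation_system(rep(1, 30), init_rate = 1e6, term_rate = 1e6,
                             footprint = 1)
  expect_equal(estimate_synthesis_time(sys2), 30, tolerance = 1e-4)

  rates <- sequence_profiles(fix_genes()[[3]], fix_table())$rates
  sys3 <- translation_system(rates, init_rate = 0.05, dropoff_rate = 0)
  est <- estimate_synthesis_time(sys3)
  sim <- simulate(sys3, seed = 5, burn_in = 500, measure = 60000)
  measured <- sim$mean_transit + 1 / sys3$init_rate
  # transit SE ~ sd of a sum of exponentials / sqrt(n)
  se <- sqrt(sum(1 / rates^2)) / sqrt(sim$n_transit) + 2 / sqrt(sim$n_transit)
  expect_lt(abs(measured - est), 4 * se + 0.05 * est)
})

test_that("mean rates obey the arithmetic/harmonic relations", {
  expect_equal(unname(mean_rates(c(2, 2))), c(2, 2))
  expect_equal(unname(mean_rates(c(1, 3))), c(2, 1.5))
  set.seed(9)
  for (i in 1:20) {
    x <- runif(sample(2:50, 1), 0.1, 50)
    m <- mean_rates(x)
    expect_lte(m["harmonic"], m["arithmetic"] + 1e-12)
  }
  m <- mean_rates(rep(3.7, 8))
  expect_equal(unname(m["harmonic"]), unname(m["arithmetic"]))
  expect_error(mean_rates(numeric()), "empty")
})

test_that("critical corner follows 1/(sqrt(d)+1)", {
  expect_equal(critical_corner(1), 0.5)
  expect_equal(critical_corner(4), 1 / 3)
  expect_equal(critical_corner(10), 1 / (sqrt(10) + 1))
  expect_equal(round(critical_corner(10), 2), 0.24)
})

test_that("phase-diagram regime labels partition the grid as expected", {
  pd <- phase_diagram(c(0.05, 0.5), c(0.1, 0.6), gamma_bar = 0,
                      length = 30, footprint = 10, seed = 1,
                      burn_in = 50, measure = 200)
  expect_identical(
    pd$regime[pd$alpha_bar == 0.05 & pd$beta_bar == 0.1], "LD")
  expect_identical(
    pd$regime[pd$alpha_bar == 0.5 & pd$beta_bar == 0.1], "HD")
  expect_identical(
    pd$regime[pd$alpha_bar == 0.5 & pd$beta_bar == 0.6], "MC")
  expect_equal(attr(pd, "corner"), critical_corner(10))
})

test_that("fixed-timestep integrator validates dt", {
  sys <- translation_system(rep(10, 40), init_rate = 0.1)
  expect_error(simulate_fixed_timestep(sys, dt = 0.02, total = 10, seed = 1),
               "dt too large")
  expect_warning(simulate_fixed_timestep(sys, dt = 0.002, total = 10,
                                         seed = 1, burn_in = 1),
                 "biased")
})

test_that("the paired-move rule mechanically advances flagged followers", {
  # deterministic-ish check: under the paired rule a jammed pair resolves
  # and the simulation conserves counts just like the default rule
  sys <- translation_system(rep(1, 40), init_rate = 0.8, dropoff_rate = 0,
                            footprint = 5)
  r <- simulate(sys, seed = 21, burn_in = 100, measure = 2000,
                move_rule = "paired")
  expect_identical(r$initiations_total,
                   r$completions_total + r$dropoffs_total +
                     length(r$final_positions))
  if (length(r$final_positions) > 1)
    expect_true(all(diff(r$final_positions) >= sys$footprint))
  # and it yields a strictly larger current than strict exclusion in a
  # jammed regime (banked attempts push the queue forward)
  r0 <- simulate(sys, seed = 21, burn_in = 100, measure = 2000)
  expect_gt(r$current, r0$current)
})
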