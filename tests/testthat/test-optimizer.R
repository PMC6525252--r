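test_that("proposal probabilities match hand evaluation of the rule", {
  rates <- setNames(fix_table()$elongation_rate, fix_table()$codon)
  acc <- setNames(fix_table()$accuracy, fix_table()$codon)
  rates["AAA"] <- 10; rates["AAG"] <- 5
  acc["AAA"] <- 0.99; acc["AAG"] <- 0.95
  tb <- codon_rate_table(rates, acc)
  # one synonym dominates both criteria: (1+1+.05)/2.1 and .05/2.1
  p <- proposal_probabilities("AAA", tb, s1 = 1, s2 = 1, eps = 0.05)
  expect_equal(unname(p["AAA"]), 2.05 / 2.10, tolerance = 1e-12)
  expect_equal(unname(p["AAG"]), 0.05 / 2.10, tolerance = 1e-12)

  # single-codon family
  expect_equal(unname(proposal_probabilities("ATG", tb)), 1)

  # s1 = s2 = 0: uniform from the regularizer alone
  expect_equal(unname(proposal_probabilities("CTG", tb, s1 = 0, s2 = 0)),
               rep(1 / 6, 6))

  # degenerate family (identical rates and accuracies): uniform
  u <- uniform_table()
  expect_equal(unname(proposal_probabilities("GCT", u)), rep(0.25, 4))

  expect_error(proposal_probabilities("AAA", tb, s1 = 0, s2 = 0, eps = 0),
               "vanish")
})

test_that("proposal vectors sum to one for every family and random table", {
  for (s in 1:3) {
    tb <- make_rate_table(200 + s)
    tot <- vapply(sense_codons(), function(cdn)
      sum(proposal_probabilities(cdn, tb)), numeric(1))
    expect_true(all(abs(tot - 1) < 1e-12))
  }
})

test_that("sampling frequencies follow the proposal distribution", {
  rates <- setNames(fix_table()$elongation_rate, fix_table()$codon)
  acc <- setNames(fix_table()$accuracy, fix_table()$codon)
  rates["AAA"] <- 10; rates["AAG"] <- 5
  acc["AAA"] <- 0.99; acc["AAG"] <- 0.95
  tb <- codon_rate_table(rates, acc)
  p <- proposal_probabilities("AAA", tb)
  set.seed(12)
  draws <- sample(names(p), 1e4, replace = TRUE, prob = p)
  p_hat <- mean(draws == "AAA")
  se <- sqrt(p["AAA"] * (1 - p["AAA"]) / 1e4)
  expect_lt(abs(p_hat - p["AAA"]), 4 * se)
  # large regularization flattens the proposal
  p_flat <- proposal_probabilities("AAA", tb, eps = 1e6)
  expect_equal(unname(p_flat), c(0.5, 0.5), tolerance = 1e-5)
})

test_that("the seed sequence is the positionwise combined argmax", {
  tb <- fix_table()
  s <- initial_sequence("MKVLW", tb)
  expect_identical(translate_cds(s), "MKVLW")
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  # brute-force check of the argmax at every position
  for (i in seq_along(codons)) {
    syn <- synonymous_codons(codons[i])
    idx <- match(syn, tb$codon)
    r <- tb$elongation_rate[idx]; a <- tb$accuracy[idx]
    nr <- if (diff(range(r)) == 0) rep(0, length(r))
          else (r - min(r)) / diff(range(r))
    na <- if (diff(range(a)) == 0) rep(0, length(a))
          else (a - min(a)) / diff(range(a))
    expect_identical(codons[i], syn[which.max(nr + na)])
  }
  # accepts a CDS as input too
  expect_identical(initial_sequence("ATGAAATAA", tb),
                   initial_sequence("MK", tb))
  expect_error(initial_sequence("MX?", tb))
})

test_that("optimization respects its selection and constraint contracts", {
  b <- fix_bench_small()
  m <- fix_model_small()
  wt <- b$genes[[1]]
  opt <- optimize_codons(wt, b$table, m, m = 12, max_proposals = 40,
                         seed = 1, measure = 300)
  expect_identical(translate_cds(opt$best_seq), translate_cds(wt))
  expect_gte(opt$best_score, opt$wildtype_score)
  expect_true(all(diff(opt$trajectory) >= 0))
  expect_gt(opt$relative_score, 0)

  dopt <- optimize_codons(wt, b$table, m, objective = "minimize",
                          m = 12, max_proposals = 30, seed = 2,
                          measure = 300)
  expect_lte(dopt$best_score, dopt$wildtype_score)
  expect_true(all(diff(dopt$trajectory) <= 0))

  fr <- optimize_codons(wt, b$table, m, frozen = 1:30, m = 8,
                        max_proposals = 20, seed = 3, measure = 300)
  expect_identical(substr(fr$best_seq, 1, 90), substr(wt, 1, 90))

  expect_error(optimize_codons("ATGTAAATG", b$table, m), "stop")
})

test_that("a flat score landscape terminates within the buffer length", {
  b <- fix_bench_small()
  flat <- fix_model_flat()
  wt <- b$genes[[2]]
  opt <- optimize_codons(wt, b$table, flat, m = 8, max_proposals = 100,
                         seed = 4, measure = 200)
  expect_true(opt$converged)
  expect_lte(opt$proposals, 9)
})

test_that("relative scores preserve ordering and protein identity", {
  b <- fix_bench_small()
  m <- fix_model_small()
  wt <- b$genes[[3]]
  # variant = wildtype with a shared simulation seed: ratio is exactly 1
  rs <- relative_score(wt, wt, b$table, m, measure = 300, seed = 5)
  expect_equal(rs$ratio, 1)
  expect_error(relative_score("ATGAAA", "ATGCCC", b$table, m),
               "different proteins")
})

test_that("codon adaptation index follows the usage-ratio definition", {
  usage <- setNames(rep(1, 61), sense_codons())
  usage["AAA"] <- 4; usage["AAG"] <- 1
  expect_equal(cai("AAAAAA", usage), 1)
  expect_equal(cai("AAGAAG", usage), 0.25)
  expect_equal(cai("AAAAAG", usage), sqrt(0.25))
  # single-codon families are excluded
  expect_equal(cai("ATGAAA", usage), 1)
  expect_error(cai("ATGATG", usage), "no multi-synonym")
  expect_error(cai("AAA", usage[-1]), "missing codon")
})
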