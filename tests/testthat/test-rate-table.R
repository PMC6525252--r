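test_that("rate-table validation enforces the 61-sense-codon contract", {
  tb <- uniform_table()
  expect_s3_class(tb, "codon_rate_table")
  expect_identical(nrow(tb), 61L)
  expect_true(all(tb$elongation_rate == 22))

  rates <- setNames(rep(22, 61), sense_codons())
  acc <- setNames(rep(0.99, 61), sense_codons())
  # missing codon named in the error
  expect_error(codon_rate_table(rates[-match("TGG", names(rates))],
                                acc[-match("TGG", names(acc))]),
               "TGG")
  # stop codons rejected
  r2 <- c(rates, TAA = 5); a2 <- c(acc, TAA = 0.9)
  expect_error(codon_rate_table(r2, a2), "stop codon")
  # nonpositive rate / accuracy out of (0, 1]
  r3 <- rates; r3["AAA"] <- 0
  expect_error(codon_rate_table(r3, acc), "AAA")
  a3 <- acc; a3["TTT"] <- 1.2
  expect_error(codon_rate_table(rates, a3), "TTT")
  # U accepted on input and mapped to T
  names(r2) <- names(rates); names(a2) <- names(acc)
  names(rates)[match("TTT", names(rates))] <- "UUU"
  names(acc)[match("TTT", names(acc))] <- "UUU"
  tb2 <- codon_rate_table(rates, acc)
  expect_true("TTT" %in% tb2$codon)
})

test_that("TSV round trip reproduces numeric content exactly", {
  tb <- fix_table()
  f <- withr::local_tempfile()
  write_rate_table(tb, f)
  tb2 <- load_rate_table(f)
  expect_identical(tb2$codon, tb$codon)
  expect_identical(tb2$elongation_rate, tb$elongation_rate)
  expect_identical(tb2$accuracy, tb$accuracy)
  # second round trip is a fixed point
  f2 <- withr::local_tempfile()
  write_rate_table(tb2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("load_rate_table validates files", {
  f <- withr::local_tempfile()
  writeLines(c("codon\telongation_rate\taccuracy",
               "# comment", "AAA\t22\t0.99"), f)
  expect_error(load_rate_table(f), "missing sense codon")
  f2 <- withr::local_tempfile()
  writeLines("foo\tbar", f2)
  expect_error(load_rate_table(f2))
})

test_that("competition generator follows the binding-ratio formulas", {
  codons <- sense_codons()
  conc <- setNames(rep(1, 61), paste0("tRNA_", codons))
  no_comp <- lapply(codons, function(cdn)
    list(cognate = paste0("tRNA_", cdn)))
  names(no_comp) <- codons
  pool <- trna_pool(conc, no_comp)
  tb <- synthesize_rate_table(pool, base_rate = 22)
  expect_true(all(tb$elongation_rate == 22))
  expect_true(all(tb$accuracy == 1))

  # one near-cognate with equal concentration: a = 1 / 1.1
  with_near <- no_comp
  with_near[["AAA"]]$near <- "tRNA_AAC"
  pool2 <- trna_pool(conc, with_near)
  tb2 <- synthesize_rate_table(pool2, base_rate = 22, w_near = 0.1)
  expect_equal(tb2$accuracy[tb2$codon == "AAA"], 1 / 1.1, tolerance = 1e-12)
  expect_equal(tb2$elongation_rate[tb2$codon == "AAA"], 22 / 1.1,
               tolerance = 1e-12)

  # scale invariance: doubling all concentrations changes nothing
  pool3 <- trna_pool(conc * 2, with_near)
  tb3 <- synthesize_rate_table(pool3, base_rate = 22, w_near = 0.1)
  expect_identical(tb3$elongation_rate, tb2$elongation_rate)
  expect_identical(tb3$accuracy, tb2$accuracy)

  # zero cognate concentration is an error
  conc0 <- conc; conc0["tRNA_AAA"] <- 0
  expect_error(synthesize_rate_table(trna_pool(conc0, no_comp), 22), "AAA")

  # generated tables from random pools always satisfy the invariants
  for (s in 1:3) {
    tbs <- synthesize_rate_table(make_trna_pool(s), base_rate = 22)
    expect_s3_class(tbs, "codon_rate_table")
    expect_true(all(tbs$elongation_rate > 0))
    expect_true(all(tbs$accuracy > 0 & tbs$accuracy <= 1))
  }
})

test_that("sequence_profiles maps codons positionally and handles stops", {
  tb <- fix_table()
  p <- sequence_profiles("ATGATG", tb)
  expect_identical(p$codons, c("ATG", "ATG"))
  expect_equal(p$rates,
               rep(tb$elongation_rate[tb$codon == "ATG"], 2))
  # terminal stop stripped silently
  p2 <- sequence_profiles("ATGTAA", tb)
  expect_identical(p2$codons, "ATG")
  # internal stop reported with position
  expect_error(sequence_profiles("ATGTAAATG", tb), "codon 2")
  expect_error(sequence_profiles("ATGXAA", tb), "non-ACGT")
  expect_error(sequence_profiles("ATGA", tb), "divisible by 3")

  # position-wise: permuting synonymous codons permutes profile values
  s1 <- "ATGAAAAAGGGT"   # Lys AAA, Lys AAG
  s2 <- "ATGAAGAAAGGT"   # swapped synonyms
  q1 <- sequence_profiles(s1, tb)
  q2 <- sequence_profiles(s2, tb)
  expect_equal(q1$rates[c(1, 3, 2, 4)], q2$rates)
  expect_equal(q1$accuracies[c(1, 3, 2, 4)], q2$accuracies)
})

test_that("translate_cds and synonym families follow the genetic code", {
  expect_identical(translate_cds("ATGAAATAA"), "MK")
  expect_identical(length(sense_codons()), 61L)
  expect_identical(synonymous_codons("M"), "ATG")
  expect_identical(synonymous_codons("AAA"), c("AAA", "AAG"))
  expect_error(synonymous_codons("TAA"), "stop")
})
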