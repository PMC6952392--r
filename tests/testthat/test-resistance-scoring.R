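ref <- reference_state(-10.0, -7.7)

test_that("the resistance score matches hand arithmetic", {
  ev <- energy_evaluation(-8.0, -7.7, 1.0)
  # (−8 − (−10)) / (|−7.7 − (−8)| * 1.0 * 1) = 2.0 / 0.3
  expect_equal(resistance_score(ev, ref, 1), 2.0 / 0.3, tolerance = 1e-12)
  # normalisation by the mutation count: exactly half for a double mutant
  expect_equal(resistance_score(ev, ref, 2), 0.5 * 2.0 / 0.3)
  # zero numerator -> zero score whatever the denominator
  ev0 <- energy_evaluation(-10.0, -7.7, 2.3)
  expect_equal(resistance_score(ev0, ref, 1), 0)
  expect_error(resistance_score(ev, ref, 0), "wild type")
})

test_that("the epsilon floor keeps degenerate denominators finite", {
  cfg <- constraint_config(denominator_epsilon = 1e-6)
  ev_rmsd0 <- energy_evaluation(-8.0, -7.7, 0.0)
  s <- resistance_score(ev_rmsd0, ref, 1, cfg)
  expect_true(is.finite(s))
  expect_equal(s, 2.0 / (0.3 * 1e-6))
  ev_gap0 <- energy_evaluation(-7.7, -7.7, 1.0)
  expect_true(is.finite(resistance_score(ev_gap0, ref, 1, cfg)))
})

test_that("score and gate agree with a brute-force oracle", {
  cfg <- constraint_config()
  oracle_score <- function(dd, da, r, n) {
    (dd - ref$dE_wt_drug) /
      (max(abs(da - dd), cfg$denominator_epsilon) *
         max(r, cfg$denominator_epsilon) * n)
  }
  set.seed(41)
  for (i in 1:2000) {
    dd <- runif(1, -12, -6); da <- runif(1, -9, -6.5)
    r <- runif(1, 0, 6); n <- sample(1:3, 1)
    ev <- energy_evaluation(dd, da, r)
    gate <- atp_constraints_pass(ev, ref, cfg)
    expect_identical(gate$pass,
                     r <= cfg$rmsd_max &&
                       (da - ref$dE_wt_atp) <= cfg$atp_dE_increase_max)
    expect_equal(resistance_score(ev, ref, n, cfg), oracle_score(dd, da, r, n),
                 tolerance = 1e-9)
  }
})

test_that("ATP-preservation constraints gate mutants before scoring", {
  cfg <- constraint_config()
  big_rmsd <- energy_evaluation(-8.0, -7.7, 4.5)
  expect_equal(atp_constraints_pass(big_rmsd, ref, cfg)$reason, "atp_rmsd")
  weak_atp <- energy_evaluation(-8.0, -7.2, 1.0)  # ATP 0.5 kcal/mol worse
  expect_equal(atp_constraints_pass(weak_atp, ref, cfg)$reason, "atp_energy")
  like_wt <- energy_evaluation(-10.0, -7.7, 0.0)
  expect_true(atp_constraints_pass(like_wt, ref, cfg)$pass)
})

test_that("score is monotone in drug weakening, mutation count and RMSD", {
  cfg <- constraint_config()
  base <- resistance_score(energy_evaluation(-8.5, -7.7, 1.0), ref, 1, cfg)
  weaker_drug <- resistance_score(energy_evaluation(-8.0, -7.7, 1.0),
                                  ref, 1, cfg)
  expect_gt(weaker_drug, base)
  # for a positive numerator: more mutations or more ATP displacement
  # lowers the score (single mutations prioritised)
  expect_lt(resistance_score(energy_evaluation(-8.5, -7.7, 1.0), ref, 2, cfg),
            base)
  expect_lt(resistance_score(energy_evaluation(-8.5, -7.7, 2.0), ref, 1, cfg),
            base)
})

test_that("the optional inverted-RMSD variant reverses that direction", {
  cfg <- constraint_config(invert_rmsd = TRUE)
  lo <- resistance_score(energy_evaluation(-8.5, -7.7, 1.0), ref, 1, cfg)
  hi <- resistance_score(energy_evaluation(-8.5, -7.7, 2.0), ref, 1, cfg)
  expect_gt(hi, lo)
})

test_that("ranking is deterministic with the stated tie-breaks", {
  gene <- toy_gene()
  mk <- function(dna, dd, da = -7.7, r = 1.0) {
    g <- translate_and_classify(dna, gene)
    score_mutant(g, energy_evaluation(dd, da, r), ref)
  }
  s <- list(mk("AAAGCTAAA", -9.0), mk("TTGGCTAAA", -7.0),
            mk("ATGGCTAAG", -8.0))
  ranked <- rank_mutants(s)
  expect_equal(vapply(ranked, function(x) x$resistance_score, numeric(1)),
               sort(vapply(s, function(x) x$resistance_score, numeric(1)),
                    decreasing = TRUE))

  # equal scores: fewer amino-acid mutations first
  single <- mk("AAAGCTAAA", -8.0)                      # M1K
  double <- mk("AAAAAAAAA", -8.0)                      # M1K + A2K
  double$resistance_score <- single$resistance_score   # force the tie
  ranked2 <- rank_mutants(list(double, single))
  expect_equal(ranked2[[1]]$genotype$num_mut, 1)

  # rejected mutants are excluded
  bad <- mk("AAAGCTAAA", -8.0, r = 9)
  expect_length(rank_mutants(list(bad)), 0)

  # random pools agree with an independent sort oracle
  set.seed(51)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*" & gc != "M"]
  pool <- lapply(1:100, function(i) {
    dna <- paste0(sample(sense, 1), "GCTAAA")
    mk(dna, runif(1, -11, -7), r = runif(1, 0.2, 3))
  })
  ranked3 <- rank_mutants(pool)
  df <- data.frame(
    score = vapply(pool, function(x) x$resistance_score, numeric(1)),
    num_mut = vapply(pool, function(x) x$genotype$num_mut, numeric(1)),
    dna = vapply(pool, function(x) x$genotype$dna, character(1)))
  oracle <- df[order(-df$score, df$num_mut, df$dna, method = "radix"), ]
  expect_equal(vapply(ranked3, function(x) x$genotype$dna, character(1)),
               oracle$dna)
})

test_that("nonsense genotypes are rejected with a reason", {
  gene <- back_translate(1:2, "ATGTGG")
  g <- translate_and_classify("ATGTAG", gene)
  s <- score_mutant(g, energy_evaluation(-8, -7.7, 1), ref)
  expect_false(s$passed_constraints)
  expect_equal(s$rejection_reason, "nonsense")
  expect_true(is.na(s$resistance_score))
})

test_that("scored tables export the full bookkeeping", {
  gene <- toy_gene()
  g <- translate_and_classify("AAAGCTAAA", gene)
  s <- score_mutant(g, energy_evaluation(-8, -7.7, 1), ref)
  tab <- scored_mutant_table(list(s))
  expect_equal(tab$aa_mutations, "M1K")
  expect_equal(tab$rejection_reason, "none")
  path <- tempfile(fileext = ".tsv")
  scored_mutant_table(list(s), path)
  expect_equal(read.delim(path)$score, tab$score)
})
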