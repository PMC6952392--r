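planted_fixture <- function(seed = 42) {
  generate_fixture(seed, n_residues = 10,
                   planted = list(aa = "M", drug_offset = 2.5,
                                  atp_offset = 0))
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_parents = 100L, n_offspring_per_parent = 1000L,
         mutation_rate = 1e-2, population_cap = 100L, seeds = 1L),
    list(...))
  do.call(ga_config, args)
}

test_that("the initial population is all wild type", {
  fx <- planted_fixture()
  pop <- initialize_population(fx$gene, ga_config(n_parents = 1000L))
  expect_equal(sum(pop$count), 1000L)
  expect_equal(unique(pop$dna), fx$gene$dna)
  pop1 <- initialize_population(fx$gene, ga_config(n_parents = 1L))
  expect_equal(sum(pop1$count), 1L)
})

test_that("selection keeps the top cap or refills with originals", {
  cfg <- ga_config(population_cap = 1000L)
  mk_pool <- function(n, score_from = 10) {
    data.frame(dna = sprintf("G%05d", seq_len(n)),
               count = rep(1L, n),
               score = seq(score_from, score_from - 1, length.out = n),
               num_mut = rep(1, n))
  }
  originals <- data.frame(dna = "WT", count = 5000L, score = 0, num_mut = 0)

  # more eligible mutants than the cap: exactly the top 1000, no originals
  sel <- select_population(mk_pool(5000), originals, cfg)
  expect_equal(sum(sel$population$count), 1000L)
  expect_equal(sel$n_mutants, 1000L)
  expect_equal(sel$n_refill, 0L)
  kept <- sort(sel$population$dna)
  expect_true(all(kept %in% sprintf("G%05d", 1:1000)))

  # fewer eligible than the cap: all kept, originals fill the rest
  sel2 <- select_population(mk_pool(200), originals, cfg)
  expect_equal(sel2$n_mutants, 200L)
  expect_equal(sel2$n_refill, 800L)
  expect_equal(sum(sel2$population$count), 1000L)

  # no mutants at all: the population is originals only
  sel3 <- select_population(mk_pool(0), originals, cfg)
  expect_equal(sel3$n_mutants, 0L)
  expect_equal(sum(sel3$population$count), 1000L)
  expect_equal(sel3$population$dna, "WT")
})

test_that("the eligible pool is the top fraction of mutation-bearing offspring", {
  cfg <- ga_config(top_fraction = 0.05)
  pool <- data.frame(dna = sprintf("G%03d", 1:100), count = 10L,
                     score = 100:1, num_mut = 1)
  elig <- top_fraction_pool(pool, n_mutation_bearing = 1000L, cfg)
  expect_equal(sum(elig$count), 50L)  # floor(0.05 * 1000)
  expect_equal(elig$dna, sprintf("G%03d", 1:5))
})

test_that("zero mutation rate is a fixed point of the whole system", {
  fx <- planted_fixture()
  cfg <- small_config(mutation_rate = 0, max_generations = 3L)
  rep <- ga_run(fx$gene, surrogate_backend(fx$landscape), cfg)[[1]]
  expect_equal(rep$termination$reason, "max_generations")
  for (rec in rep$generations) {
    expect_equal(rec$n_mutation_bearing, 0L)
    expect_equal(rec$n_selected_mutants, 0L)
  }
  expect_equal(rep$final_population$dna, fx$gene$dna)
  expect_equal(nrow(rep$final_selected), 0L)
})

test_that("population size and offspring accounting are exact", {
  fx <- planted_fixture()
  cfg <- small_config(max_generations = 3L,
                      convergence_share = 2)  # disable early stops
  set.seed(1)
  memo <- new.env(parent = emptyenv())
  cache <- new_evaluation_cache()
  pop <- initialize_population(fx$gene, cfg)
  backend <- surrogate_backend(fx$landscape)
  for (g in 1:3) {
    step <- run_generation(pop, fx$gene, backend, fx$reference, cfg,
                           memo = memo, eval_cache = cache)
    rec <- step$record
    expect_equal(rec$n_offspring, 100L * 1000L)
    expect_equal(sum(step$population$count), cfg$population_cap)
    expect_lte(rec$n_unique_mutants, rec$n_mutation_bearing)
    expect_lte(rec$n_mutation_bearing, rec$n_offspring)
    expect_lte(rec$n_selected_mutants + rec$n_refill, cfg$population_cap)
    expect_true(all(rec$n_rejected >= 0))
    pop <- step$population
  }
  # cache: one backend call per unique genotype ever evaluated
  expect_equal(n_backend_calls(cache), length(ls(envir = cache)))
})

test_that("the planted resistance mutation is selected in generation one", {
  fx <- planted_fixture()
  cfg <- small_config()
  rep <- ga_run(fx$gene, surrogate_backend(fx$landscape), cfg)[[1]]
  planted_label <- paste0(
    fx$gene$residues$wt_aa[match(fx$planted$position, fx$gene$residues$resno)],
    fx$planted$position, fx$planted$aa)
  expect_equal(rep$final_selected$label[1], planted_label)
  expect_gt(rep$final_selected$score[1], 10)
})

test_that("termination fires when the drug binds more weakly than ATP", {
  # planted mutant: dE_drug = -7.5 > dE_atp = -7.7 once selected
  fx <- planted_fixture()
  rep <- ga_run(fx$gene, surrogate_backend(fx$landscape), small_config())[[1]]
  expect_equal(rep$termination$reason, "drug_weaker_than_atp")
  top <- rep$generations[[length(rep$generations)]]$top
  expect_gt(top$dE_drug, top$dE_atp)

  # synthetic record histories exercise the other branches directly
  mk_rec <- function(dd, da, share, label = "A1B") {
    list(top = list(dE_drug = dd, dE_atp = da),
         dominant_share = share,
         composition = stats::setNames(share, label))
  }
  cfg <- ga_config(max_generations = 10L, convergence_share = 0.9,
                   convergence_generations = 2L)
  expect_false(check_termination(list(mk_rec(-9, -7.7, 0.2)), cfg)$stop)
  expect_equal(check_termination(list(mk_rec(-7.0, -7.7, 0.2)), cfg)$reason,
               "drug_weaker_than_atp")
  hist2 <- list(mk_rec(-9, -7.7, 0.95), mk_rec(-9, -7.7, 0.97))
  expect_equal(check_termination(hist2, cfg)$reason, "converged")
  # one converged generation is not enough
  hist1 <- list(mk_rec(-9, -7.7, 0.2), mk_rec(-9, -7.7, 0.95))
  expect_false(check_termination(hist1, cfg)$stop)
  cfg1 <- ga_config(max_generations = 1L)
  expect_equal(check_termination(list(mk_rec(-9, -7.7, 0.2)), cfg1)$reason,
               "max_generations")
})

test_that("a whole-landscape dominance run converges by mutation share", {
  # strong planted offset, termination (a) disabled by a large ATP baseline
  fx <- generate_fixture(9, n_residues = 6,
                         planted = list(aa = "M", drug_offset = 2.5,
                                        atp_offset = 0),
                         dE_wt_atp = -3.0)
  cfg <- small_config(max_generations = 6L)
  rep <- ga_run(fx$gene, surrogate_backend(fx$landscape), cfg)[[1]]
  expect_equal(rep$termination$reason, "converged")
  last <- rep$generations[[length(rep$generations)]]
  expect_gte(last$dominant_share, 0.9)
})

test_that("runs are reproducible and replicates are independent", {
  fx <- planted_fixture()
  backend <- surrogate_backend(fx$landscape)
  cfg3 <- small_config(seeds = c(1L, 2L, 3L))
  reps <- ga_run(fx$gene, backend, cfg3)
  expect_length(reps, 3)
  expect_equal(vapply(reps, function(r) r$seed, integer(1)), 1:3)
  again <- ga_run(fx$gene, backend, small_config(seeds = 1L))[[1]]
  expect_identical(reps[[1]]$final_population, again$final_population)
  expect_identical(reps[[1]]$generations, again$generations)
})

test_that("run reports serialise to JSON and TSV", {
  fx <- planted_fixture()
  reps <- ga_run(fx$gene, surrogate_backend(fx$landscape), small_config())
  dir <- tempfile("reports")
  write_run_reports(reps, dir)
  expect_true(file.exists(file.path(dir, "run_seed1.json")))
  parsed <- jsonlite::read_json(file.path(dir, "run_seed1.json"))
  expect_equal(parsed$seed, 1L)
  tab <- read.delim(file.path(dir, "final_selected.tsv"))
  expect_true(all(c("seed", "label", "score") %in% names(tab)))
})
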