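test_that("back-translation returns the actual gene codons", {
  gene <- back_translate(1:3, "ATGGCTAAA")
  expect_equal(gene$residues$codon, c("ATG", "GCT", "AAA"))
  expect_equal(gene$residues$wt_aa, c("M", "A", "K"))
  expect_equal(gene$dna, "ATGGCTAAA")

  # subset selection with a residue-number offset
  gene2 <- back_translate(c(315, 317), "ACTGAATTC", offset = 315)
  expect_equal(gene2$residues$resno, c(315, 317))
  expect_equal(gene2$residues$codon, c("ACT", "TTC"))
  expect_equal(gene2$residues$wt_aa, c("T", "F"))

  # empty selection
  empty <- back_translate(integer(0), "ATGGCTAAA")
  expect_s3_class(empty, "binding_site_gene")
  expect_equal(nrow(empty$residues), 0)

  # RNA alphabet accepted, stored as DNA
  expect_equal(back_translate(1, "AUG")$residues$codon, "ATG")

  expect_error(back_translate(5, "ATGGCTAAA"), "not covered")
  expect_error(back_translate(1, "ATGG"), "multiple of 3")
  expect_error(back_translate(1:2, "ATGTAA"), "stop codon")
})

test_that("back-translation round-trips through translation on random CDSs", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    cds <- paste(sample(sense, n, replace = TRUE), collapse = "")
    sel <- sort(sample(n, sample(n, 1)))
    gene <- back_translate(sel, cds)
    expect_equal(unname(gc[gene$residues$codon]), gene$residues$wt_aa)
    expect_equal(translate_dna(gene$dna), gene$residues$wt_aa)
  }
})

test_that("mutant translation classifies silent, missense and nonsense", {
  gene <- back_translate(c(315, 316), "ACTTGG", offset = 315)

  # threonine ACT -> ATT isoleucine: the classic gatekeeper substitution
  g <- translate_and_classify("ATTTGG", gene)
  expect_equal(g$aa_mutations,
               data.frame(position = 315, wt_aa = "T", mut_aa = "I",
                          stringsAsFactors = FALSE))
  expect_equal(g$num_mut, 1)
  expect_false(g$is_nonsense)
  expect_false(g$is_silent)
  expect_equal(mutation_label(g), "T315I")

  # identical sequence: no change at all
  same <- translate_and_classify("ACTTGG", gene)
  expect_equal(same$num_mut, 0)
  expect_false(same$is_silent)

  # synonymous change only
  silent <- translate_and_classify("ACATGG", gene)
  expect_equal(silent$num_mut, 0)
  expect_true(silent$is_silent)
  expect_equal(mutation_label(silent), "")

  # TGG -> TAG introduces a stop codon
  stopm <- translate_and_classify("ACTTAG", gene)
  expect_true(stopm$is_nonsense)
  expect_equal(stopm$num_mut, 0)

  expect_error(translate_and_classify("ACT", gene), "length")
})

test_that("codon distance reproduces single-step accessibility arithmetic", {
  expect_identical(min_nt_substitutions("ACU", "AUG"), 2L)
  expect_identical(min_nt_substitutions("AUU", "AUG"), 1L)
  expect_identical(min_nt_substitutions("AAA", "AAA"), 0L)
  expect_error(min_nt_substitutions("AXU", "AUG"), "alphabet")

  # metric properties over random codon triples
  set.seed(7)
  codons <- names(Biostrings::GENETIC_CODE)
  for (i in 1:50) {
    abc <- sample(codons, 3, replace = TRUE)
    dab <- min_nt_substitutions(abc[1], abc[2])
    dba <- min_nt_substitutions(abc[2], abc[1])
    expect_identical(dab, dba)
    expect_identical(dab == 0L, abc[1] == abc[2])
    expect_lte(min_nt_substitutions(abc[1], abc[3]),
               dab + min_nt_substitutions(abc[2], abc[3]))
  }
})

test_that("single-step accessible substitutions match brute-force enumeration", {
  gc <- Biostrings::GENETIC_CODE

  acc <- accessible_substitutions("ACU")
  expect_setequal(acc$aa[acc$class == "missense"],
                  c("P", "A", "S", "N", "I"))
  expect_false("M" %in% acc$aa)          # Met needs two substitutions
  expect_true("M" %in% accessible_substitutions("AUU")$aa)

  sense <- names(gc)[gc != "*"]
  for (codon in sense) {
    acc <- accessible_substitutions(codon)
    expect_equal(sum(acc$n_routes), 9L)  # 3 positions x 3 bases
    oracle <- table(unname(gc[oracle_single_nt_variants(codon)]))
    expect_equal(acc$n_routes[match(names(oracle), acc$aa)],
                 as.integer(oracle))
    expect_setequal(acc$aa, names(oracle))
  }
})

test_that("per-offspring mutation has Bernoulli semantics", {
  gene <- toy_gene()
  off0 <- mutate_offspring(gene, 0, rng_seed = 1)
  expect_equal(off0$dna, gene$dna)
  expect_equal(off0$num_mut, 0)

  set.seed(2)
  for (i in 1:20) {
    off1 <- mutate_offspring(gene, 1)
    expect_equal(sum(strsplit(off1$dna, "")[[1]] !=
                       strsplit(gene$dna, "")[[1]]), 1)
  }

  # batch generator: empirical mutant count within 4 binomial sd
  set.seed(3)
  n <- 2e5; rate <- 1e-2
  batch <- generate_offspring(gene$dna, n, rate)
  expect_equal(batch$n_copies + length(batch$mutated_dna), n)
  expect_lt(abs(length(batch$mutated_dna) - n * rate),
            4 * sqrt(n * rate * (1 - rate)))
  # every mutated offspring differs from the parent at exactly one base
  some <- sample(batch$mutated_dna, 50)
  expect_true(all(vapply(some, function(d)
    sum(strsplit(d, "")[[1]] != strsplit(gene$dna, "")[[1]]) == 1,
    logical(1))))
})

test_that("per-base mutation mode can stack substitutions in one offspring", {
  gene <- toy_gene()
  set.seed(4)
  batch <- generate_offspring(gene$dna, 5000, 0.1, per_base = TRUE)
  ndiff <- vapply(batch$mutated_dna, function(d)
    sum(strsplit(d, "")[[1]] != strsplit(gene$dna, "")[[1]]), numeric(1))
  expect_true(any(ndiff >= 2))
  expect_equal(batch$n_copies + length(batch$mutated_dna), 5000)
})

test_that("mutation-route tables enumerate per-residue accessibility", {
  gene <- toy_gene()
  tab <- mutation_routes_table(gene)
  expect_equal(sum(tab$routes), 9L * 3L)
  path <- tempfile(fileext = ".tsv")
  mutation_routes_table(gene, path)
  expect_equal(read.delim(path)$routes, tab$routes)
})
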