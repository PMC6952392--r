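# The mutation-only genetic algorithm: offspring generation at the DNA
# level, per-unique-genotype evaluation, top-fraction selection with
# original-sequence refill, and termination over generations.

#' Configuration of the evolutionary simulation
#'
#' Defaults mirror the full-scale study conditions: 10^3 parent sequences,
#' 10^4 offspring each, a per-offspring mutation rate of 10^-4 (so about
#' 10^3 mutation-bearing offspring per generation), selection of the top 5%
#' of mutation-bearing offspring capped at 1000 individuals with
#' original-sequence refill, and three independent replicates. Tests and
#' examples run the same code at reduced scale purely through these knobs.
#'
#' @param n_parents number of first-generation parent sequences.
#' @param n_offspring_per_parent offspring per individual per generation.
#' @param mutation_rate per-offspring mutation probability (one uniformly
#'   placed substitution per mutating offspring); interpreted per base when
#'   `per_base = TRUE`.
#' @param per_base use per-base mutation semantics.
#' @param top_fraction share of mutation-bearing offspring eligible for
#'   selection.
#' @param population_cap population size after selection.
#' @param max_generations hard generation limit.
#' @param convergence_share dominant-mutation frequency treated as
#'   converged.
#' @param convergence_generations consecutive generations the dominant share
#'   must hold.
#' @param seeds integer seeds, one replicate run each.
#' @param constraint a [constraint_config()].
#' @param max_eval_failure_rate abort a generation when the fraction of
#'   failed backend evaluations among unique mutants exceeds this ceiling.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(n_parents = 1000L, n_offspring_per_parent = 10000L,
                      mutation_rate = 1e-4, per_base = FALSE,
                      top_fraction = 0.05, population_cap = 1000L,
                      max_generations = 10L, convergence_share = 0.9,
                      convergence_generations = 2L, seeds = c(1L, 2L, 3L),
                      constraint = constraint_config(),
                      max_eval_failure_rate = 0.5) {
  stopifnot(n_parents >= 1L, population_cap >= 1L,
            top_fraction > 0, top_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1, max_generations >= 1L)
  structure(list(n_parents = as.integer(n_parents),
                 n_offspring_per_parent = as.integer(n_offspring_per_parent),
                 mutation_rate = mutation_rate, per_base = per_base,
                 top_fraction = top_fraction,
                 population_cap = as.integer(population_cap),
                 max_generations = as.integer(max_generations),
                 convergence_share = convergence_share,
                 convergence_generations = as.integer(convergence_generations),
                 seeds = as.integer(seeds), constraint = constraint,
                 max_eval_failure_rate = max_eval_failure_rate),
            class = "ga_config")
}

#' Initialise the first-generation population
#'
#' All individuals carry the wild-type binding-site DNA; individuals are
#' tracked as (genotype, count) multisets.
#'
#' @param gene a [binding_site_gene()].
#' @param config a [ga_config()].
#' @return data.frame with columns `dna` and `count`.
#' @export
initialize_population <- function(gene, config = ga_config()) {
  stopifnot(inherits(gene, "binding_site_gene"), nzchar(gene$dna))
  data.frame(dna = gene$dna, count = config$n_parents,
             stringsAsFactors = FALSE)
}

# Memoised classify+evaluate+score for one genotype DNA. The memo
# environment persists across generations of a run so docking happens once
# per unique genotype.
score_genotype <- function(dna, gene, backend, reference, config, memo,
                           eval_cache) {
  if (exists(dna, envir = memo, inherits = FALSE)) {
    return(get(dna, envir = memo))
  }
  genotype <- translate_and_classify(dna, gene)
  scored <- if (genotype$is_nonsense) {
    score_mutant(genotype, energy_evaluation(NA_real_, NA_real_, NA_real_,
                                             success = FALSE),
                 reference, config$constraint)
  } else {
    score_mutant(genotype, evaluate_mutant(genotype, backend, eval_cache),
                 reference, config$constraint)
  }
  assign(dna, scored, envir = memo)
  scored
}

# pool: data.frame(dna, count, score, num_mut), sort deterministically
rank_pool <- function(pool) {
  if (nrow(pool) == 0L) return(pool)
  pool[order(-pool$score, pool$num_mut, pool$dna, method = "radix"), ,
       drop = FALSE]
}

# take the top k individuals (with multiplicity) from a ranked pool
take_top_individuals <- function(pool, k) {
  if (k <= 0L || nrow(pool) == 0L) return(pool[0L, , drop = FALSE])
  cum <- cumsum(pool$count)
  last <- which(cum >= k)[1L]
  if (is.na(last)) last <- nrow(pool)
  out <- pool[seq_len(last), , drop = FALSE]
  excess <- sum(out$count) - k
  if (excess > 0L) out$count[last] <- out$count[last] - excess
  out
}

#' Restrict ranked mutants to the eligible top fraction
#'
#' The eligible pool is the best `top_fraction` share of all
#' mutation-bearing offspring, ranked by resistance score.
#'
#' @param ranked_mutants ranked pool data.frame (`dna`, `count`, `score`,
#'   `num_mut`).
#' @param n_mutation_bearing total number of mutation-bearing offspring this
#'   generation (the denominator of the fraction).
#' @param config a [ga_config()].
#' @return the truncated ranked pool.
#' @export
top_fraction_pool <- function(ranked_mutants, n_mutation_bearing,
                              config = ga_config()) {
  take_top_individuals(rank_pool(ranked_mutants),
                       floor(config$top_fraction * n_mutation_bearing))
}

#' Selection: cap the eligible mutants, refill with originals
#'
#' If the eligible mutants exceed the population cap, the top-ranked cap is
#' kept; otherwise all eligible mutants are kept and the remaining slots are
#' filled with the highest-ranking original (previous-population)
#' individuals. The returned population always has exactly
#' `config$population_cap` individuals.
#'
#' @param eligible eligible mutant pool (data.frame `dna`, `count`, `score`,
#'   `num_mut`), e.g. from [top_fraction_pool()].
#' @param originals previous-population pool in the same format.
#' @param config a [ga_config()].
#' @return list with `population` (data.frame `dna`, `count`), `n_mutants`
#'   and `n_refill` selected.
#' @export
select_population <- function(eligible, originals, config = ga_config()) {
  eligible <- rank_pool(eligible)
  n_elig <- sum(eligible$count)
  if (n_elig >= config$population_cap) {
    kept <- take_top_individuals(eligible, config$population_cap)
    refill <- kept[0L, , drop = FALSE]
  } else {
    kept <- eligible
    refill <- take_top_individuals(rank_pool(originals),
                                   config$population_cap - n_elig)
  }
  pop <- rbind(kept[, c("dna", "count")], refill[, c("dna", "count")])
  pop <- stats::aggregate(count ~ dna, data = pop, FUN = sum)
  list(population = pop[, c("dna", "count")],
       n_mutants = sum(kept$count), n_refill = sum(refill$count))
}

#' Run one generation of the evolutionary simulation
#'
#' Every individual produces `n_offspring_per_parent` offspring; mutating
#' offspring acquire one uniformly placed nucleotide substitution. Unique
#' genotypes are translated, evaluated (cached), gated by the ATP
#' constraints and scored; nonsense mutants are discarded as catalytically
#' dead and silent DNA-level mutants rank with score 0. The top fraction of
#' mutation-bearing offspring is then selected with original-sequence
#' refill.
#'
#' @param population data.frame (`dna`, `count`).
#' @param gene wild-type [binding_site_gene()].
#' @param backend an `energy_backend`.
#' @param reference a [reference_state()].
#' @param config a [ga_config()].
#' @param memo,eval_cache persistent per-run caches (created when `NULL`).
#' @return list with `population` (next generation) and `record` (a
#'   per-generation bookkeeping list).
#' @export
run_generation <- function(population, gene, backend, reference,
                           config = ga_config(), memo = NULL,
                           eval_cache = NULL) {
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  if (is.null(eval_cache)) eval_cache <- new_evaluation_cache()
  wt_dna <- gene$dna

  # offspring, aggregated as genotype -> count
  copies <- population
  copies$count <- 0L
  mutated_all <- character(0)
  n_offspring <- 0L
  for (i in seq_len(nrow(population))) {
    batch <- generate_offspring(population$dna[i],
                                population$count[i] *
                                  config$n_offspring_per_parent,
                                config$mutation_rate,
                                per_base = config$per_base)
    n_offspring <- n_offspring + batch$n_offspring
    copies$count[i] <- batch$n_copies
    mutated_all <- c(mutated_all, batch$mutated_dna)
  }
  pool <- copies
  if (length(mutated_all)) {
    tab <- table(mutated_all)
    pool <- rbind(pool, data.frame(dna = names(tab),
                                   count = as.integer(tab),
                                   stringsAsFactors = FALSE))
    pool <- stats::aggregate(count ~ dna, data = pool, FUN = sum)
  }
  mb <- pool[pool$dna != wt_dna & pool$count > 0L, , drop = FALSE]
  n_mutation_bearing <- sum(mb$count)

  # score unique mutation-bearing genotypes
  scored <- lapply(mb$dna, score_genotype, gene = gene, backend = backend,
                   reference = reference, config = config, memo = memo,
                   eval_cache = eval_cache)
  reason <- vapply(scored, function(s) s$rejection_reason, character(1))
  passed <- vapply(scored, function(s) isTRUE(s$passed_constraints),
                   logical(1))
  n_failed <- sum(reason == "eval_failed")
  if (nrow(mb) > 0L &&
      n_failed / nrow(mb) > config$max_eval_failure_rate) {
    stop("backend failure rate ", signif(n_failed / nrow(mb), 3),
         " exceeds ceiling ", config$max_eval_failure_rate)
  }
  rejected_individuals <- vapply(
    c("nonsense", "atp_rmsd", "atp_energy", "eval_failed"),
    function(r) sum(mb$count[reason == r]), numeric(1))
  n_silent <- sum(mb$count[vapply(scored, function(s)
    isTRUE(s$genotype$is_silent), logical(1))])

  mut_pool <- data.frame(
    dna = mb$dna[passed], count = mb$count[passed],
    score = vapply(scored[passed], function(s) s$resistance_score,
                   numeric(1)),
    num_mut = vapply(scored[passed], function(s) s$genotype$num_mut,
                     numeric(1)),
    stringsAsFactors = FALSE)
  eligible <- top_fraction_pool(mut_pool, n_mutation_bearing, config)

  # originals: the previous population, ranked by its own scores
  orig_scored <- lapply(population$dna, score_genotype, gene = gene,
                        backend = backend, reference = reference,
                        config = config, memo = memo,
                        eval_cache = eval_cache)
  orig_ok <- vapply(orig_scored, function(s) isTRUE(s$passed_constraints),
                    logical(1))
  originals <- data.frame(
    dna = population$dna[orig_ok], count = population$count[orig_ok],
    score = vapply(orig_scored[orig_ok], function(s) s$resistance_score,
                   numeric(1)),
    num_mut = vapply(orig_scored[orig_ok], function(s) s$genotype$num_mut,
                     numeric(1)),
    stringsAsFactors = FALSE)

  sel <- select_population(eligible, originals, config)

  # composition of the selected population at the amino-acid level
  new_pop <- sel$population
  comp <- integer(0)
  top <- NULL
  if (nrow(eligible)) {
    missense <- eligible[eligible$num_mut >= 1L, , drop = FALSE]
    if (nrow(missense)) {
      top_s <- get(missense$dna[1L], envir = memo)
      top <- list(dna = missense$dna[1L],
                  label = mutation_label(top_s$genotype),
                  score = top_s$resistance_score,
                  dE_drug = top_s$evaluation$dE_drug,
                  dE_atp = top_s$evaluation$dE_atp,
                  rmsd_atp = top_s$evaluation$rmsd_atp)
    }
  }
  sel_mut <- new_pop[new_pop$dna != wt_dna, , drop = FALSE]
  if (nrow(sel_mut)) {
    labels <- vapply(sel_mut$dna, function(d)
      mutation_label(get(d, envir = memo)$genotype), character(1))
    keep <- nzchar(labels)
    if (any(keep)) {
      comp <- tapply(sel_mut$count[keep], labels[keep], sum)
      comp <- sort(comp / sum(comp), decreasing = TRUE)
    }
  }

  record <- list(
    n_offspring = n_offspring,
    n_mutation_bearing = n_mutation_bearing,
    n_unique_mutants = nrow(mb),
    n_rejected = rejected_individuals,
    n_silent = n_silent,
    n_selected_mutants = sel$n_mutants,
    n_refill = sel$n_refill,
    top = top,
    score_summary = if (nrow(eligible))
      stats::quantile(rep(eligible$score, eligible$count),
                      c(0, 0.5, 1), names = FALSE) else c(NA, NA, NA),
    composition = comp,
    dominant_share = if (length(comp)) unname(comp[1L]) else 0
  )
  list(population = new_pop, record = record)
}

#' Termination check
#'
#' Evolution stops when (a) the top-ranked mutant binds the drug more weakly
#' than ATP (`dE_drug > dE_atp`), (b) one amino-acid mutation dominates the
#' selected population (share >= `convergence_share`) for
#' `convergence_generations` consecutive generations, or (c) the generation
#' limit is reached.
#'
#' @param records list of generation records.
#' @param config a [ga_config()].
#' @return list with `stop` (logical) and `reason`
#'   (`"drug_weaker_than_atp"`, `"converged"`, `"max_generations"` or
#'   `"none"`).
#' @export
check_termination <- function(records, config = ga_config()) {
  stopifnot(length(records) >= 1L)
  last <- records[[length(records)]]
  if (!is.null(last$top) && last$top$dE_drug > last$top$dE_atp) {
    return(list(stop = TRUE, reason = "drug_weaker_than_atp"))
  }
  k <- config$convergence_generations
  if (length(records) >= k) {
    recent <- records[seq(length(records) - k + 1L, length(records))]
    shares <- vapply(recent, function(r) r$dominant_share, numeric(1))
    labels <- vapply(recent, function(r)
      if (length(r$composition)) names(r$composition)[1L] else "",
      character(1))
    if (all(shares >= config$convergence_share) &&
        length(unique(labels)) == 1L && nzchar(labels[1L])) {
      return(list(stop = TRUE, reason = "converged"))
    }
  }
  if (length(records) >= config$max_generations) {
    return(list(stop = TRUE, reason = "max_generations"))
  }
  list(stop = FALSE, reason = "none")
}

#' Run the full evolutionary simulation, one replicate per seed
#'
#' For each seed: initialise the population, iterate generations until a
#' termination condition fires, and emit a run report. Per-generation RNG
#' streams are derived from the run seed (a seed sequence drawn once up
#' front), so every replicate is exactly reproducible from (config, seed)
#' with the surrogate backend.
#'
#' @param gene wild-type [binding_site_gene()].
#' @param backend an `energy_backend`.
#' @param config a [ga_config()].
#' @param reference a [reference_state()]; derived from the landscape for
#'   surrogate backends when `NULL`.
#' @return list of `run_report` objects (one per seed), each with `seed`,
#'   `termination`, `generations` (records), `final_population` and
#'   `final_selected` (data.frame of mutation-bearing missense individuals:
#'   `label`, `dna`, `count`, `score`, `num_mut`).
#' @export
ga_run <- function(gene, backend, config = ga_config(), reference = NULL) {
  if (is.null(reference)) {
    if (backend$type == "surrogate") {
      reference <- surrogate_reference(backend$landscape)
    } else {
      stop("an explicit reference_state is required for this backend")
    }
  }
  lapply(config$seeds, function(seed) {
    set.seed(seed)
    gen_seeds <- sample.int(.Machine$integer.max - 1L,
                            config$max_generations)
    memo <- new.env(parent = emptyenv())
    eval_cache <- new_evaluation_cache()
    population <- initialize_population(gene, config)
    records <- list()
    term <- list(stop = FALSE, reason = "none")
    for (g in seq_len(config$max_generations)) {
      set.seed(gen_seeds[g])
      step <- run_generation(population, gene, backend, reference, config,
                             memo = memo, eval_cache = eval_cache)
      population <- step$population
      records[[g]] <- c(list(generation = g), step$record)
      term <- check_termination(records, config)
      if (term$stop) break
    }
    final_selected <- final_selected_mutants(population, gene, memo)
    structure(list(seed = seed, termination = term, generations = records,
                   final_population = population,
                   final_selected = final_selected,
                   n_backend_calls = n_backend_calls(eval_cache)),
              class = "run_report")
  })
}

# mutation-bearing missense individuals of a final population, labelled
final_selected_mutants <- function(population, gene, memo) {
  rows <- lapply(seq_len(nrow(population)), function(i) {
    dna <- population$dna[i]
    if (dna == gene$dna) return(NULL)
    s <- get(dna, envir = memo)
    lab <- mutation_label(s$genotype)
    if (!nzchar(lab)) return(NULL)
    data.frame(label = lab, dna = dna, count = population$count[i],
               score = s$resistance_score, num_mut = s$genotype$num_mut,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(label = character(), dna = character(),
                      count = integer(), score = numeric(),
                      num_mut = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$score, out$num_mut, out$dna, method = "radix"), ,
      drop = FALSE]
}

#' @export
print.run_report <- function(x, ...) {
  cat("Evolutionary run (seed ", x$seed, "): ", length(x$generations),
      " generation(s), stopped: ", x$termination$reason, "\n", sep = "")
  if (nrow(x$final_selected)) {
    top <- utils::head(x$final_selected, 5L)
    cat("  top mutants:",
        paste(sprintf("%s (n=%d, score=%.3g)", top$label, top$count,
                      top$score), collapse = ", "), "\n")
  } else {
    cat("  no mutants in the final population\n")
  }
  invisible(x)
}

#' Write run reports to disk
#'
#' One JSON per report (records and final selection) plus a combined TSV of
#' final selected mutants.
#'
#' @param reports list of `run_report` objects from [ga_run()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_run_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in reports) {
    jsonlite::write_json(
      list(seed = r$seed, termination = r$termination,
           generations = r$generations,
           final_selected = r$final_selected),
      file.path(dir, sprintf("run_seed%d.json", r$seed)),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$final_selected) == 0L) return(NULL)
    cbind(seed = r$seed, r$final_selected)
  }))
  if (!is.null(tab)) {
    utils::write.table(tab, file.path(dir, "final_selected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
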