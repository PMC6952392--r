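# The resistance score and the ATP-preservation constraints that gate it.
#
# A mutant is resistance-prone when it weakens drug binding while leaving
# ATP binding (energy and pose) essentially intact, so that the kinase stays
# catalytically competent. The score rewards the drug-energy increase over
# wild type, normalised by the ATP/drug energy gap, the ATP-pose
# displacement, and the number of amino-acid substitutions (so single
# mutations are prioritised).

#' Constraint and scoring configuration
#'
#' @param rmsd_max maximum tolerated ATP-pose RMSD, angstroms. Mutants whose
#'   docked ATP deviates more than this from the reference position are
#'   discarded (default 4.0).
#' @param atp_dE_increase_max maximum tolerated increase of the ATP binding
#'   energy over wild type, kcal/mol (default 0.3).
#' @param denominator_epsilon positive floor applied to both denominator
#'   factors of the score, which is otherwise singular at zero ATP
#'   displacement or equal drug/ATP energies (default 1e-6).
#' @param invert_rmsd if `TRUE`, the pose-RMSD factor multiplies the
#'   numerator instead of the denominator (sensitivity analysis only; the
#'   default `FALSE` is the literal scoring function).
#' @return object of class `constraint_config`.
#' @export
constraint_config <- function(rmsd_max = 4.0, atp_dE_increase_max = 0.3,
                              denominator_epsilon = 1e-6,
                              invert_rmsd = FALSE) {
  stopifnot(rmsd_max > 0, atp_dE_increase_max > 0, denominator_epsilon > 0)
  structure(list(rmsd_max = rmsd_max,
                 atp_dE_increase_max = atp_dE_increase_max,
                 denominator_epsilon = denominator_epsilon,
                 invert_rmsd = invert_rmsd),
            class = "constraint_config")
}

#' ATP-preservation constraint gate
#'
#' A mutant fails (and is discarded before scoring) when its docked ATP pose
#' deviates from the reference position by more than `rmsd_max`, or when its
#' ATP binding energy increases over wild type by more than
#' `atp_dE_increase_max`.
#'
#' @param evaluation a successful [energy_evaluation()].
#' @param reference a [reference_state()].
#' @param config a [constraint_config()].
#' @return list with `pass` (logical) and `reason`
#'   (`"none"`/`"atp_rmsd"`/`"atp_energy"`).
#' @export
atp_constraints_pass <- function(evaluation, reference,
                                 config = constraint_config()) {
  stopifnot(isTRUE(evaluation$success))
  if (evaluation$rmsd_atp > config$rmsd_max) {
    return(list(pass = FALSE, reason = "atp_rmsd"))
  }
  if ((evaluation$dE_atp - reference$dE_wt_atp) > config$atp_dE_increase_max) {
    return(list(pass = FALSE, reason = "atp_energy"))
  }
  list(pass = TRUE, reason = "none")
}

#' Resistance score of a mutant
#'
#' \deqn{score = \frac{\Delta E^{drug}_{mut} - \Delta E^{drug}_{wt}}
#'   {|\Delta E^{ATP}_{mut} - \Delta E^{drug}_{mut}| \cdot RMSD_{ATP}
#'    \cdot Num_{mut}}}
#'
#' Higher scores mean more resistance potential: the numerator grows as drug
#' binding weakens relative to wild type, and the denominator normalises by
#' the ATP/drug energy gap, the ATP-pose displacement, and the number of
#' amino-acid substitutions. Both denominator factors are floored at
#' `denominator_epsilon` to keep the score finite and order-preserving when
#' the ATP pose is essentially unmoved or the energies coincide.
#'
#' @param evaluation a successful [energy_evaluation()] that passed
#'   [atp_constraints_pass()].
#' @param reference a [reference_state()].
#' @param num_mut number of amino-acid mutations (>= 1; wild type is not
#'   scored).
#' @param config a [constraint_config()].
#' @return dimensionless score.
#' @examples
#' ev <- energy_evaluation(-8.0, -7.7, 1.0)
#' ref <- reference_state(-10.0, -7.7)
#' resistance_score(ev, ref, num_mut = 1)  # 2.0 / 0.3 = 6.667
#' @export
resistance_score <- function(evaluation, reference, num_mut,
                             config = constraint_config()) {
  if (num_mut < 1L) stop("num_mut must be >= 1: wild type is not scored")
  eps <- config$denominator_epsilon
  numer <- evaluation$dE_drug - reference$dE_wt_drug
  gap <- max(abs(evaluation$dE_atp - evaluation$dE_drug), eps)
  rmsd <- max(evaluation$rmsd_atp, eps)
  if (config$invert_rmsd) {
    numer * rmsd / (gap * num_mut)
  } else {
    numer / (gap * rmsd * num_mut)
  }
}

#' Score and gate one evaluated mutant
#'
#' @param genotype a `mutant_genotype`.
#' @param evaluation its [energy_evaluation()].
#' @param reference a [reference_state()].
#' @param config a [constraint_config()].
#' @return object of class `scored_mutant`: list with `genotype`,
#'   `evaluation`, `resistance_score` (`NA` unless passed),
#'   `passed_constraints` and `rejection_reason`
#'   (`none`/`atp_rmsd`/`atp_energy`/`nonsense`/`eval_failed`).
#' @export
score_mutant <- function(genotype, evaluation, reference,
                         config = constraint_config()) {
  make <- function(score, pass, reason) {
    structure(list(genotype = genotype, evaluation = evaluation,
                   resistance_score = score, passed_constraints = pass,
                   rejection_reason = reason),
              class = "scored_mutant")
  }
  if (isTRUE(genotype$is_nonsense)) {
    return(make(NA_real_, FALSE, "nonsense"))
  }
  if (!isTRUE(evaluation$success)) {
    return(make(NA_real_, FALSE, "eval_failed"))
  }
  gate <- atp_constraints_pass(evaluation, reference, config)
  if (!gate$pass) return(make(NA_real_, FALSE, gate$reason))
  score <- if (genotype$num_mut == 0L) 0 else {
    resistance_score(evaluation, reference, genotype$num_mut, config)
  }
  make(score, TRUE, "none")
}

#' Rank scored mutants
#'
#' Constraint-passing mutants sorted by score (descending) with a
#' deterministic tie-break: fewer amino-acid mutations first, then
#' lexicographic genotype DNA. Rejected mutants are excluded.
#'
#' @param scored list of `scored_mutant` objects.
#' @return the passing subset, ordered.
#' @export
rank_mutants <- function(scored) {
  passed <- Filter(function(s) isTRUE(s$passed_constraints), scored)
  if (length(passed) == 0L) return(passed)
  score <- vapply(passed, function(s) s$resistance_score, numeric(1))
  nmut <- vapply(passed, function(s) s$genotype$num_mut, numeric(1))
  dna <- vapply(passed, function(s) s$genotype$dna, character(1))
  passed[order(-score, nmut, dna, method = "radix")]
}

#' Tabulate scored mutants
#'
#' Flat table suitable for TSV export: genotype DNA, amino-acid mutation
#' label, energies, pose RMSD, mutation count, score and rejection reason.
#'
#' @param scored list of `scored_mutant` objects.
#' @param path optional TSV output path.
#' @return data.frame (invisibly when written).
#' @export
scored_mutant_table <- function(scored, path = NULL) {
  tab <- do.call(rbind, lapply(scored, function(s) {
    data.frame(genotype = s$genotype$dna,
               aa_mutations = mutation_label(s$genotype),
               dE_drug = s$evaluation$dE_drug,
               dE_atp = s$evaluation$dE_atp,
               rmsd_atp = s$evaluation$rmsd_atp,
               num_mut = s$genotype$num_mut,
               score = s$resistance_score,
               rejection_reason = s$rejection_reason,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
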