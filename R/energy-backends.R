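# One evaluation contract for mutant energetics: genotype in,
# (dE_drug, dE_atp, ATP-pose RMSD) out. Backends: deterministic surrogate
# landscape (testable at desk scale) and an external repack+dock adapter.

#' Construct an energy evaluation
#'
#' @param dE_drug drug binding free-energy estimate for the mutant, kcal/mol.
#' @param dE_atp ATP binding free-energy estimate for the mutant, kcal/mol.
#' @param rmsd_atp displacement of the docked ATP pose from its reference
#'   position, angstroms (>= 0).
#' @param backend backend tag.
#' @param success whether the evaluation succeeded.
#' @return object of class `energy_evaluation`.
#' @export
energy_evaluation <- function(dE_drug, dE_atp, rmsd_atp, backend = "manual",
                              success = TRUE) {
  if (success) {
    stopifnot(is.finite(dE_drug), is.finite(dE_atp), is.finite(rmsd_atp),
              rmsd_atp >= 0)
  }
  structure(list(dE_drug = dE_drug, dE_atp = dE_atp, rmsd_atp = rmsd_atp,
                 backend = backend, success = success),
            class = "energy_evaluation")
}

#' Wild-type reference state
#'
#' Evaluated once per run and fixed thereafter: wild-type drug and ATP
#' binding energies and the reference ATP pose.
#'
#' @param dE_wt_drug,dE_wt_atp kcal/mol.
#' @param atp_pose optional reference [ligand_pose()].
#' @return object of class `reference_state`.
#' @export
reference_state <- function(dE_wt_drug, dE_wt_atp, atp_pose = NULL) {
  stopifnot(is.finite(dE_wt_drug), is.finite(dE_wt_atp))
  structure(list(dE_wt_drug = dE_wt_drug, dE_wt_atp = dE_wt_atp,
                 atp_pose = atp_pose),
            class = "reference_state")
}

#' Deterministic surrogate energy landscape
#'
#' A per-(position, amino acid) table of additive drug/ATP binding-energy
#' offsets and ATP-pose displacements, standing in for side-chain repacking
#' plus docking so the evolutionary engine can be exercised and tested
#' deterministically. Wild-type amino acids carry zero offsets by
#' construction.
#'
#' @param offsets data.frame with columns `position`, `aa`, `drug_offset`,
#'   `atp_offset` (kcal/mol) and `atp_displacement` (angstroms).
#' @param dE_wt_drug,dE_wt_atp wild-type baselines, kcal/mol.
#' @return object of class `surrogate_landscape`.
#' @export
surrogate_landscape <- function(offsets, dE_wt_drug = -10.0,
                                dE_wt_atp = -7.7) {
  stopifnot(is.data.frame(offsets),
            all(c("position", "aa", "drug_offset", "atp_offset",
                  "atp_displacement") %in% names(offsets)))
  num <- as.matrix(offsets[, c("drug_offset", "atp_offset",
                               "atp_displacement")])
  if (!all(is.finite(num))) stop("non-finite landscape entries")
  lookup <- new.env(parent = emptyenv())
  key <- paste0(offsets$position, ":", offsets$aa)
  if (anyDuplicated(key)) stop("duplicate (position, aa) entries")
  for (i in seq_along(key)) {
    assign(key[i], c(drug = offsets$drug_offset[i],
                     atp = offsets$atp_offset[i],
                     disp = offsets$atp_displacement[i]), envir = lookup)
  }
  structure(list(offsets = offsets, lookup = lookup,
                 dE_wt_drug = dE_wt_drug, dE_wt_atp = dE_wt_atp),
            class = "surrogate_landscape")
}

#' Evaluate a mutant genotype on a surrogate landscape
#'
#' Additive model: the mutant drug (ATP) energy is the wild-type baseline
#' plus the sum of per-substitution offsets; the ATP-pose RMSD is the
#' root-sum-square of per-substitution displacements. Fully deterministic.
#'
#' @param mutant a `mutant_genotype`.
#' @param landscape a [surrogate_landscape()].
#' @return an [energy_evaluation()].
#' @export
surrogate_evaluate <- function(mutant, landscape) {
  stopifnot(inherits(landscape, "surrogate_landscape"))
  m <- mutant$aa_mutations
  drug <- landscape$dE_wt_drug
  atp <- landscape$dE_wt_atp
  disp2 <- 0
  if (nrow(m)) {
    for (i in seq_len(nrow(m))) {
      key <- paste0(m$position[i], ":", m$mut_aa[i])
      if (!exists(key, envir = landscape$lookup, inherits = FALSE)) {
        stop("no landscape entry for ", m$wt_aa[i], m$position[i],
             m$mut_aa[i])
      }
      v <- get(key, envir = landscape$lookup)
      drug <- drug + v[["drug"]]
      atp <- atp + v[["atp"]]
      disp2 <- disp2 + v[["disp"]]^2
    }
  }
  energy_evaluation(drug, atp, sqrt(disp2), backend = "surrogate")
}

#' Surrogate backend
#' @param landscape a [surrogate_landscape()].
#' @return an `energy_backend` usable by [evaluate_mutant()] and the engine.
#' @export
surrogate_backend <- function(landscape) {
  stopifnot(inherits(landscape, "surrogate_landscape"))
  structure(list(type = "surrogate", landscape = landscape),
            class = "energy_backend")
}

#' Create an evaluation cache
#'
#' Docking is per unique genotype, never per offspring: identical sequences
#' have identical evaluations, so results are cached by genotype DNA.
#'
#' @return an environment with a call counter (`n_backend_calls`).
#' @export
new_evaluation_cache <- function() {
  cache <- new.env(parent = emptyenv())
  assign(".n_backend_calls", 0L, envir = cache)
  cache
}

#' Number of backend calls made through a cache
#' @param cache a [new_evaluation_cache()].
#' @return integer count.
#' @export
n_backend_calls <- function(cache) get(".n_backend_calls", envir = cache)

#' Evaluate a mutant genotype through a backend, with caching
#'
#' @param mutant a `mutant_genotype` (missense-only; nonsense mutants are
#'   rejected upstream).
#' @param backend an `energy_backend` ([surrogate_backend()] or
#'   [dock_backend()]).
#' @param cache optional [new_evaluation_cache()]; identical genotypes are
#'   evaluated once.
#' @return an [energy_evaluation()].
#' @export
evaluate_mutant <- function(mutant, backend, cache = NULL) {
  stopifnot(inherits(backend, "energy_backend"))
  key <- mutant$dna
  if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE)) {
    return(get(key, envir = cache))
  }
  ev <- switch(backend$type,
    surrogate = surrogate_evaluate(mutant, backend$landscape),
    dock = dock_evaluate(mutant, backend),
    stop("unknown backend type ", backend$type))
  if (!is.null(cache)) {
    assign(key, ev, envir = cache)
    assign(".n_backend_calls", n_backend_calls(cache) + 1L, envir = cache)
  }
  ev
}

#' Reference state of a surrogate landscape
#' @param landscape a [surrogate_landscape()].
#' @return a [reference_state()] with the landscape baselines.
#' @export
surrogate_reference <- function(landscape) {
  reference_state(landscape$dE_wt_drug, landscape$dE_wt_atp)
}

#' Generate a reproducible toy binding site with a surrogate landscape
#'
#' Builds a synthetic test system: a binding-site gene of random sense
#' codons, a surrogate landscape of small random background offsets
#' (|drug| <= 0.3, |ATP| <= 0.1 kcal/mol), and optionally one planted
#' resistance substitution that is reachable by a single nucleotide change
#' from the planted position's codon (the generator chooses that codon
#' accordingly, so recovery experiments are fair).
#'
#' Baselines default to dE_wt_drug = -10.0 and dE_wt_atp = -7.7 kcal/mol,
#' the latter matching the stable ATP-binding level of the ABL reference
#' system.
#'
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param n_residues number of binding-site residues (>= 1).
#' @param planted optional list with `position` (structure residue number
#'   within the fixture; defaults to the middle residue when `NULL`),
#'   `aa` (one-letter target amino acid), `drug_offset`, `atp_offset`
#'   (kcal/mol) and optionally `atp_displacement` (angstroms, default 1.0).
#' @param first_resno residue number of the first fixture residue.
#' @param dE_wt_drug,dE_wt_atp wild-type baselines.
#' @return list with `gene` ([binding_site_gene()]), `landscape`
#'   ([surrogate_landscape()]), `reference` ([reference_state()]) and
#'   `planted` (the completed planted description, or `NULL`).
#' @export
generate_fixture <- function(seed, n_residues = 10L, planted = NULL,
                             first_resno = 301L, dE_wt_drug = -10.0,
                             dE_wt_atp = -7.7) {
  stopifnot(n_residues >= 1L)
  set.seed(seed)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  codons <- sample(sense, n_residues, replace = TRUE)
  resno <- seq.int(first_resno, length.out = n_residues)

  if (!is.null(planted)) {
    stopifnot(all(c("aa", "drug_offset", "atp_offset") %in% names(planted)))
    if (is.null(planted$position)) {
      planted$position <- resno[ceiling(n_residues / 2)]
    }
    if (is.null(planted$atp_displacement)) planted$atp_displacement <- 1.0
    idx <- match(planted$position, resno)
    if (is.na(idx)) stop("planted position not in the fixture gene")
    # pick a codon from which the planted amino acid is one substitution away
    donors <- sense[vapply(sense, function(cd) {
      gc[[cd]] != planted$aa &&
        planted$aa %in% accessible_substitutions(cd)$aa
    }, logical(1))]
    if (length(donors) == 0L) {
      stop("planted amino acid ", planted$aa,
           " is not single-nucleotide accessible from any sense codon")
    }
    codons[idx] <- sample(donors, 1L)
  }

  wt_aa <- unname(gc[codons])
  gene <- binding_site_gene(
    data.frame(resno = resno, wt_aa = wt_aa, codon = codons,
               stringsAsFactors = FALSE),
    source_id = sprintf("synthetic-fixture-seed%d", seed))

  aas <- sort(unique(unname(gc[gc != "*"])))
  grid <- expand.grid(position = resno, aa = aas, stringsAsFactors = FALSE)
  n <- nrow(grid)
  grid$drug_offset <- stats::runif(n, -0.3, 0.3)
  grid$atp_offset <- stats::runif(n, -0.1, 0.1)
  grid$atp_displacement <- stats::runif(n, 0.3, 2.0)
  # wild-type amino acids: zero offsets, zero displacement
  wt_rows <- grid$aa == wt_aa[match(grid$position, resno)]
  grid$drug_offset[wt_rows] <- 0
  grid$atp_offset[wt_rows] <- 0
  grid$atp_displacement[wt_rows] <- 0
  if (!is.null(planted)) {
    row <- grid$position == planted$position & grid$aa == planted$aa
    grid$drug_offset[row] <- planted$drug_offset
    grid$atp_offset[row] <- planted$atp_offset
    grid$atp_displacement[row] <- planted$atp_displacement
  }
  landscape <- surrogate_landscape(grid, dE_wt_drug = dE_wt_drug,
                                   dE_wt_atp = dE_wt_atp)
  list(gene = gene, landscape = landscape,
       reference = surrogate_reference(landscape), planted = planted)
}
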