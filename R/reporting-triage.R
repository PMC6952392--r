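# Replicate aggregation into mutation-frequency distributions, and the
# stepwise experimental-triage classifier that compares measured IC50
# values against the drug's clinical safety window.

#' Aggregate replicate runs into a mutation-frequency distribution
#'
#' Pools the final selected mutants of independent replicate runs and
#' normalises counts per amino-acid mutation label. Labels that occur only
#' once across all replicates are collapsed into an `"other"` bucket
#' (singletons carry no reproducible signal). Synonymous DNA routes to the
#' same amino-acid change are pooled, since predictions are reported at the
#' amino-acid level.
#'
#' @param reports list of `run_report` objects from [ga_run()] for the same
#'   target/drug.
#' @param pool `"counts"` pools individual counts across replicates
#'   (default); `"mean"` averages per-replicate frequencies instead.
#' @param singleton_to_other collapse labels with a pooled count of 1 into
#'   `"other"`.
#' @return object of class `mutation_distribution`: data.frame with columns
#'   `label` and `frequency` (sums to 1), with attributes `n_replicates`
#'   and `pool`.
#' @export
aggregate_runs <- function(reports, pool = c("counts", "mean"),
                           singleton_to_other = TRUE) {
  pool <- match.arg(pool)
  stopifnot(length(reports) >= 1L)
  sel <- lapply(reports, function(r) r$final_selected)
  if (all(vapply(sel, nrow, integer(1)) == 0L)) {
    stop("no selected mutants to aggregate")
  }
  counts <- lapply(sel, function(s) tapply(s$count, s$label, sum))
  all_labels <- sort(unique(unlist(lapply(counts, names))))
  total_count <- vapply(all_labels, function(l)
    sum(unlist(lapply(counts, function(cc) cc[l])), na.rm = TRUE),
    numeric(1))
  if (pool == "counts") {
    freq <- total_count / sum(total_count)
  } else {
    per_run <- vapply(counts, function(cc) {
      v <- cc[all_labels]
      v[is.na(v)] <- 0
      v / sum(v)
    }, numeric(length(all_labels)))
    per_run <- matrix(per_run, nrow = length(all_labels))
    freq <- rowMeans(per_run)
  }
  names(freq) <- all_labels
  if (singleton_to_other) {
    single <- all_labels[total_count == 1]
    if (length(single)) {
      other <- sum(freq[single])
      freq <- freq[setdiff(all_labels, single)]
      freq <- c(freq, other = other)
    }
  }
  freq <- sort(freq, decreasing = TRUE)
  structure(data.frame(label = names(freq), frequency = unname(freq),
                       stringsAsFactors = FALSE),
            class = c("mutation_distribution", "data.frame"),
            n_replicates = length(reports), pool = pool)
}

#' Convert a plasma concentration to molarity
#'
#' Clinical safe plasma concentrations are reported in ng/mL; inhibition
#' assays in molar units. This converts between them:
#' molarity = (ng/mL as g/L) / molecular weight.
#'
#' @param plasma_ng_ml plasma concentration, ng/mL (> 0).
#' @param molecular_weight drug molecular weight, g/mol (> 0).
#' @return concentration in mol/L.
#' @examples
#' convert_safety_window(3000, 493.6) * 1e6  # ~6.08 uM (imatinib upper bound)
#' @export
convert_safety_window <- function(plasma_ng_ml, molecular_weight) {
  if (any(plasma_ng_ml <= 0) || any(molecular_weight <= 0)) {
    stop("plasma concentration and molecular weight must be positive")
  }
  (plasma_ng_ml * 1e-6) / molecular_weight  # ng/mL -> g/L, then / (g/mol)
}

#' Triage record for one predicted mutant
#'
#' Holds the measurements used by the stepwise triage: binding and
#' inhibition fold-changes versus wild type, catalytic-efficiency
#' fold-change, the absolute IC50, and the drug's safety window.
#'
#' @param label amino-acid mutation label (e.g. `"T315I"`).
#' @param ic50_molar measured IC50 of the drug against the mutant, mol/L
#'   (`NA` if unmeasured).
#' @param kd_fold,ic50_fold,catalytic_fold fold-changes versus wild type
#'   (> 0; `NA` allowed).
#' @param window_max_ng_ml upper bound of the safe plasma window, ng/mL.
#' @param molecular_weight drug molecular weight, g/mol.
#' @return object of class `triage_record`.
#' @export
triage_record <- function(label, ic50_molar = NA_real_, kd_fold = NA_real_,
                          ic50_fold = NA_real_, catalytic_fold = NA_real_,
                          window_max_ng_ml, molecular_weight) {
  for (f in c(kd_fold, ic50_fold, catalytic_fold)) {
    if (!is.na(f) && f <= 0) stop("fold-changes must be positive")
  }
  structure(list(label = label, ic50_molar = ic50_molar, kd_fold = kd_fold,
                 ic50_fold = ic50_fold, catalytic_fold = catalytic_fold,
                 window_max_ng_ml = window_max_ng_ml,
                 molecular_weight = molecular_weight),
            class = "triage_record")
}

#' Classify a predicted mutant against the drug safety window
#'
#' Final triage step: a mutant whose measured IC50 exceeds the highest safe
#' plasma concentration (converted to molarity) cannot be inhibited by dose
#' escalation and is classified resistant; a mutant inhibitable within the
#' window is sensitive; a missing IC50 is inconclusive.
#'
#' Annotations flag fold-change patterns typical of the two outcome groups:
#' IC50 fold-change at or above `ic50_fold_resistant` (default 60) is the
#' regime of clinically observed resistance mutations, below
#' `ic50_fold_sensitive` (default 15) that of predicted-but-not-observed
#' ones; a catalytic-efficiency fold-change above `catalytic_fold_max`
#' (default 6) marks an enzyme change cells may not tolerate.
#'
#' @param record a [triage_record()].
#' @param thresholds named list overriding `ic50_fold_resistant`,
#'   `ic50_fold_sensitive`, `catalytic_fold_max`.
#' @return list with `verdict` (`"resistant"`/`"sensitive"`/
#'   `"inconclusive"`), `window_max_molar` and `annotations` (character
#'   vector).
#' @export
classify_mutant <- function(record, thresholds = list()) {
  th <- utils::modifyList(list(ic50_fold_resistant = 60,
                               ic50_fold_sensitive = 15,
                               catalytic_fold_max = 6), thresholds)
  window_max <- convert_safety_window(record$window_max_ng_ml,
                                      record$molecular_weight)
  verdict <- if (is.na(record$ic50_molar)) {
    "inconclusive"
  } else if (record$ic50_molar > window_max) {
    "resistant"
  } else {
    "sensitive"
  }
  ann <- character(0)
  if (!is.na(record$ic50_fold)) {
    if (record$ic50_fold >= th$ic50_fold_resistant) {
      ann <- c(ann, "ic50_fold_typical_of_clinical_resistance")
    } else if (record$ic50_fold < th$ic50_fold_sensitive) {
      ann <- c(ann, "ic50_fold_typical_of_non_observed")
    }
  }
  if (!is.na(record$catalytic_fold) &&
      record$catalytic_fold > th$catalytic_fold_max) {
    ann <- c(ann, "catalytic_shift_possibly_not_tolerated")
  }
  list(verdict = verdict, window_max_molar = window_max, annotations = ann)
}

#' Read triage measurements from CSV and classify them
#'
#' Expected columns: `label`, `ic50_molar`, and optionally `kd_fold`,
#' `ic50_fold`, `catalytic_fold`; plus per-drug `window_max_ng_ml` and
#' `molecular_weight` (columns or arguments).
#'
#' @param path CSV file.
#' @param window_max_ng_ml,molecular_weight used when absent as columns.
#' @return data.frame of records with `verdict` and `annotations` appended.
#' @export
triage_csv <- function(path, window_max_ng_ml = NULL,
                       molecular_weight = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  get_col <- function(col, fallback) {
    if (col %in% names(tab)) tab[[col]] else {
      if (is.null(fallback)) stop("missing column/argument: ", col)
      rep(fallback, nrow(tab))
    }
  }
  win <- get_col("window_max_ng_ml", window_max_ng_ml)
  mw <- get_col("molecular_weight", molecular_weight)
  opt <- function(col) if (col %in% names(tab)) tab[[col]] else
    rep(NA_real_, nrow(tab))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    rec <- triage_record(tab$label[i],
                         ic50_molar = opt("ic50_molar")[i],
                         kd_fold = opt("kd_fold")[i],
                         ic50_fold = opt("ic50_fold")[i],
                         catalytic_fold = opt("catalytic_fold")[i],
                         window_max_ng_ml = win[i], molecular_weight = mw[i])
    cls <- classify_mutant(rec)
    data.frame(label = tab$label[i], verdict = cls$verdict,
               window_max_molar = cls$window_max_molar,
               annotations = paste(cls$annotations, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  cbind(tab, do.call(rbind, out)[, -1L, drop = FALSE])
}
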