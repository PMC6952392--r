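# Adapter around an external side-chain repacker and a Vina-style docking
# engine. The adapter only prepares inputs, launches the tools through
# configurable command templates, and parses their outputs; their internals
# are never re-implemented here.

#' Configure the external repack+dock backend
#'
#' Command templates are shell commands with `{placeholder}` substitution:
#'
#' * `repack_cmd`: `{receptor}` (wild-type PDB), `{mutations}` (TSV of
#'   substitutions: position, wt, mut), `{out}` (mutant PDB to write).
#' * `dock_cmd`: `{receptor}`, `{ligand}`, `{out}` (docked pose file),
#'   `{log}`, `{seed}`, `{cx} {cy} {cz}` (box centre), `{size}` (box edge),
#'   `{exhaustiveness}`.
#'
#' The docking box defaults to a 22.5 angstrom cube centred on the
#' crystallographic ligand. The engine seed is derived per genotype from the
#' run seed so repeated runs are reproducible.
#'
#' @param receptor path to the prepared wild-type receptor (PDB/PDBQT).
#' @param drug_ligand,atp_ligand prepared ligand files (PDBQT).
#' @param atp_reference_pose [ligand_pose()] of crystallographic ATP, used
#'   for the pose-RMSD constraint.
#' @param repack_cmd,dock_cmd command templates (see Details).
#' @param box list with `center` (xyz) and `size` (edge, angstroms).
#' @param exhaustiveness docking search effort.
#' @param workdir directory for per-genotype intermediate files (retained).
#' @param base_seed run seed from which per-genotype engine seeds derive.
#' @param check_executables verify at configuration time that the first
#'   token of each command template resolves on PATH (so a missing tool is a
#'   startup error, not a mid-run one).
#' @return an `energy_backend` of type `"dock"`.
#' @export
dock_backend <- function(receptor, drug_ligand, atp_ligand,
                         atp_reference_pose, repack_cmd, dock_cmd,
                         box = list(center = c(0, 0, 0), size = 22.5),
                         exhaustiveness = 8L, workdir = tempfile("dock"),
                         base_seed = 1L, check_executables = TRUE) {
  if (check_executables) {
    for (cmd in c(repack_cmd, dock_cmd)) {
      exe <- strsplit(trimws(cmd), "[[:space:]]+")[[1L]][1L]
      if (!file.exists(exe) && Sys.which(exe) == "") {
        stop("external tool not found on PATH: ", exe,
             " (configure before starting a run)")
      }
    }
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  structure(list(type = "dock", receptor = receptor,
                 drug_ligand = drug_ligand, atp_ligand = atp_ligand,
                 atp_reference_pose = atp_reference_pose,
                 repack_cmd = repack_cmd, dock_cmd = dock_cmd, box = box,
                 exhaustiveness = exhaustiveness, workdir = workdir,
                 base_seed = base_seed),
            class = "energy_backend")
}

# fill {placeholders} in a command template
fill_template <- function(template, values) {
  for (k in names(values)) {
    template <- gsub(paste0("{", k, "}"), as.character(values[[k]]),
                     template, fixed = TRUE)
  }
  template
}

# deterministic per-genotype engine seed below 2^31
genotype_seed <- function(dna, base_seed) {
  h <- sum(utf8ToInt(dna) * seq_len(nchar(dna))) %% 1000003L
  (as.integer(base_seed) %% 1000003L) * 1000L + h %% 1000L
}

#' Parse the best-mode affinity from a Vina-style log
#'
#' Accepts either the result table (`mode | affinity ...`) or a
#' `REMARK VINA RESULT` line in an output pose file.
#'
#' @param lines character vector of log/output lines.
#' @return best-mode affinity, kcal/mol.
#' @export
parse_vina_affinity <- function(lines) {
  rem <- grep("^REMARK VINA RESULT:", lines, value = TRUE)
  if (length(rem)) {
    return(as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "",
                                          rem[1L])), "[[:space:]]+")[[1L]][1L]))
  }
  tab <- grep("^[[:space:]]*1[[:space:]]+-?[0-9.]+", lines, value = TRUE)
  if (length(tab)) {
    return(as.numeric(strsplit(trimws(tab[1L]), "[[:space:]]+")[[1L]][2L]))
  }
  stop("no affinity found in docking output")
}

#' Read a ligand pose from a PDBQT/PDB pose file
#'
#' Extracts atom names and coordinates of the first model/pose.
#'
#' @param path pose file with ATOM/HETATM records.
#' @param provenance pose provenance tag.
#' @return a [ligand_pose()].
#' @export
parse_pose_file <- function(path, provenance = "docked") {
  lines <- readLines(path, warn = FALSE)
  end <- grep("^ENDMDL", lines)
  if (length(end)) lines <- lines[seq_len(end[1L] - 1L)]
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(at) == 0L) stop("no atom records in pose file ", path)
  ligand_pose(data.frame(
    name = trimws(substr(at, 13, 16)),
    x = as.numeric(substr(at, 31, 38)),
    y = as.numeric(substr(at, 39, 46)),
    z = as.numeric(substr(at, 47, 54)),
    stringsAsFactors = FALSE), provenance = provenance)
}

# Evaluate one genotype with the external tools: repack mutated side chains
# on the fixed backbone, dock drug and ATP, return affinities and the docked
# ATP pose RMSD against the reference. Any tool failure marks the evaluation
# unsuccessful; the engine drops the genotype and continues.
dock_evaluate <- function(mutant, backend) {
  gdir <- file.path(backend$workdir,
                    substr(paste0("g", abs(genotype_seed(mutant$dna, 0L)),
                                  "_", mutant$dna), 1, 64))
  dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(reason) {
    writeLines(reason, file.path(gdir, "FAILED"))
    energy_evaluation(NA_real_, NA_real_, NA_real_, backend = "dock",
                      success = FALSE)
  }
  mut_tsv <- file.path(gdir, "mutations.tsv")
  utils::write.table(mutant$aa_mutations, mut_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mutant_pdb <- file.path(gdir, "mutant.pdb")
  status <- system(fill_template(backend$repack_cmd, list(
    receptor = backend$receptor, mutations = mut_tsv, out = mutant_pdb)),
    ignore.stdout = TRUE)
  if (status != 0L || !file.exists(mutant_pdb)) {
    return(fail("side-chain repacking failed"))
  }
  seed <- genotype_seed(mutant$dna, backend$base_seed)
  dock_one <- function(ligand, tag) {
    out <- file.path(gdir, paste0(tag, "_out.pdbqt"))
    log <- file.path(gdir, paste0(tag, ".log"))
    status <- system(fill_template(backend$dock_cmd, list(
      receptor = mutant_pdb, ligand = ligand, out = out, log = log,
      seed = seed, cx = backend$box$center[1], cy = backend$box$center[2],
      cz = backend$box$center[3], size = backend$box$size,
      exhaustiveness = backend$exhaustiveness)), ignore.stdout = TRUE)
    if (status != 0L || !file.exists(out)) return(NULL)
    lines <- c(if (file.exists(log)) readLines(log, warn = FALSE),
               readLines(out, warn = FALSE))
    list(affinity = parse_vina_affinity(lines), out = out)
  }
  drug <- dock_one(backend$drug_ligand, "drug")
  if (is.null(drug)) return(fail("drug docking failed"))
  atp <- dock_one(backend$atp_ligand, "atp")
  if (is.null(atp)) return(fail("ATP docking failed"))
  rmsd <- compute_pose_rmsd(backend$atp_reference_pose,
                            parse_pose_file(atp$out))
  energy_evaluation(drug$affinity, atp$affinity, rmsd, backend = "dock")
}
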