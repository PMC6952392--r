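# Target structures: PDB input, binding-site residue selection by
# heavy-atom contact distance, and ligand pose RMSD.

#' Load a protein-ligand structure from a PDB file
#'
#' Parses a PDB file (via bio3d), partitions protein (ATOM) from ligand
#' (HETATM, waters excluded) records, and resolves alternate locations to the
#' highest-occupancy conformer. Only the first model of multi-model files is
#' used.
#'
#' @param path PDB file.
#' @param require_ligand error if no non-water HETATM records are present.
#' @return object of class `structure_model`: list with `protein` (data.frame
#'   of atoms: `elety`, `resno`, `resid`, `chain`, `x`, `y`, `z`, `elesy`)
#'   and `ligands` (named list of [ligand_pose()] objects keyed
#'   `"RESID_CHAIN_RESNO"`).
#' @export
load_structure <- function(path, require_ligand = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- pdb$atom
  # resolve altloc: keep highest occupancy per (chain, resno, insert, elety)
  alt <- !is.na(atoms$alt) & atoms$alt != ""
  if (any(alt)) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
                 atoms$elety)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      i[which.max(atoms$o[i])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  cols <- c("elety", "resno", "resid", "chain", "x", "y", "z", "elesy")
  prot <- atoms[atoms$type == "ATOM", cols, drop = FALSE]
  het <- atoms[atoms$type == "HETATM" & !(atoms$resid %in% c("HOH", "WAT")),
               cols, drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein (ATOM) records in ", path)
  if (!all(is.finite(as.matrix(prot[, c("x", "y", "z")])))) {
    stop("non-finite protein coordinates in ", path)
  }
  ligands <- list()
  if (nrow(het)) {
    key <- paste(het$resid, het$chain, het$resno, sep = "_")
    for (k in unique(key)) {
      sub <- het[key == k, , drop = FALSE]
      ligands[[k]] <- ligand_pose(
        data.frame(name = sub$elety, x = sub$x, y = sub$y, z = sub$z,
                   element = sub$elesy, stringsAsFactors = FALSE),
        provenance = "reference")
    }
  }
  if (require_ligand && length(ligands) == 0L) {
    stop("no ligand (non-water HETATM) records in ", path)
  }
  structure(list(protein = prot, ligands = ligands, source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model:", length(unique(paste(x$protein$chain,
                                              x$protein$resno))),
      "protein residues,", length(x$ligands), "ligand(s)\n")
  if (length(x$ligands)) cat("  ligands:", paste(names(x$ligands),
                                                 collapse = ", "), "\n")
  invisible(x)
}

#' Construct a ligand pose
#'
#' @param atoms data.frame with `name`, `x`, `y`, `z` and optionally
#'   `element` (inferred from the atom name when absent).
#' @param provenance `"reference"` (crystallographic) or `"docked"`.
#' @return object of class `ligand_pose`.
#' @export
ligand_pose <- function(atoms, provenance = c("reference", "docked")) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L,
            all(c("name", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$element)) {
    atoms$element <- infer_element(atoms$name)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite ligand coordinates")
  }
  structure(list(atoms = atoms, provenance = provenance),
            class = "ligand_pose")
}

# PDB-style element inference from an atom name: first alphabetic character,
# except two-letter halogens/metals common in drugs (CL, BR, FE, ZN, MG).
infer_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", name)))
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")
  ifelse(substr(nm, 1, 2) %in% two, substr(nm, 1, 2), substr(nm, 1, 1))
}

# heavy = not hydrogen (or deuterium)
heavy_atoms <- function(pose) {
  pose$atoms[!(toupper(pose$atoms$element) %in% c("H", "D")), , drop = FALSE]
}

#' Select binding-site residues by heavy-atom contact distance
#'
#' Residues with any heavy atom within `cutoff` angstroms of any ligand heavy
#' atom. These are the residues subject to mutation in the evolutionary
#' simulation. The default 5 angstrom cutoff is a conventional heavy-atom
#' contact definition and is configurable.
#'
#' @param structure a [load_structure()] result.
#' @param ligand a [ligand_pose()] (e.g. `structure$ligands[[1]]`).
#' @param cutoff contact distance in angstroms (> 0).
#' @return sorted integer vector of residue numbers.
#' @export
define_binding_site <- function(structure, ligand, cutoff = 5.0) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(ligand, "ligand_pose"), cutoff > 0)
  prot <- structure$protein
  prot <- prot[!(toupper(prot$elesy) %in% c("H", "D")), , drop = FALSE]
  lig <- as.matrix(heavy_atoms(ligand)[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # min distance from each protein atom to the ligand
  d2min <- rep(Inf, nrow(pxyz))
  for (j in seq_len(nrow(lig))) {
    d2 <- (pxyz[, 1] - lig[j, 1])^2 + (pxyz[, 2] - lig[j, 2])^2 +
      (pxyz[, 3] - lig[j, 3])^2
    d2min <- pmin(d2min, d2)
  }
  sel <- sort(unique(prot$resno[d2min <= cutoff^2]))
  if (length(sel) == 0L) {
    warning("empty binding-site selection: cutoff ", cutoff,
            " angstrom too small")
  }
  sel
}

#' RMSD between two ligand poses
#'
#' Root-mean-square deviation over matched heavy atoms, paired by atom name.
#' No superposition is performed: mutant models are built on the fixed
#' wild-type backbone, so reference and docked poses already share one
#' coordinate frame.
#'
#' @param pose_a,pose_b [ligand_pose()] objects with identical heavy-atom
#'   name multisets.
#' @return RMSD in angstroms (>= 0).
#' @export
compute_pose_rmsd <- function(pose_a, pose_b) {
  a <- heavy_atoms(pose_a)
  b <- heavy_atoms(pose_b)
  if (nrow(a) != nrow(b) ||
      !identical(sort(a$name), sort(b$name))) {
    stop("atom-name multisets of the two poses do not match")
  }
  if (anyDuplicated(a$name)) {
    # duplicate names are paired in file order within each name
    a <- a[order(a$name), ]
    b <- b[order(b$name), ]
  } else {
    b <- b[match(a$name, b$name), ]
  }
  d2 <- (a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2
  sqrt(mean(d2))
}

#' Read a ligand pose from a TSV of atom names and coordinates
#'
#' Columns: `name`, `x`, `y`, `z`, optional `element`.
#'
#' @param path TSV file.
#' @param provenance pose provenance tag.
#' @return a [ligand_pose()].
#' @export
read_pose_tsv <- function(path, provenance = "reference") {
  ligand_pose(utils::read.delim(path, stringsAsFactors = FALSE),
              provenance = provenance)
}

#' Write a ligand pose as TSV
#' @param pose a [ligand_pose()].
#' @param path output path.
#' @export
write_pose_tsv <- function(pose, path) {
  utils::write.table(pose$atoms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
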