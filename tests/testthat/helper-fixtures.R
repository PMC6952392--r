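# Shared fixtures, built in code at test time.

# A minimal PDB: three residues (CA + CB each) and one two-atom ligand.
# Residue 1 sits ~3 A from the ligand, residue 2 ~9 A, residue 3 ~20 A.
toy_pdb_lines <- function() {
  fmt <- function(type, serial, name, resn, chain, resno, x, y, z,
                  occ = 1.00, alt = "") {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, alt, resn, chain, resno, x, y, z, occ, 0,
            toupper(substr(trimws(name), 1, 1)))
  }
  c(fmt("ATOM", 1, " CA ", "ALA", "A", 1, 3.0, 0.0, 0.0),
    fmt("ATOM", 2, " CB ", "ALA", "A", 1, 3.5, 1.0, 0.0),
    fmt("ATOM", 3, " CA ", "GLY", "A", 2, 9.0, 0.0, 0.0),
    fmt("ATOM", 4, " CA ", "LEU", "A", 3, 20.0, 0.0, 0.0),
    fmt("ATOM", 5, " CB ", "LEU", "A", 3, 21.0, 0.0, 0.0),
    "TER",
    fmt("HETATM", 6, " C1 ", "LIG", "A", 101, 0.0, 0.0, 0.0),
    fmt("HETATM", 7, " N1 ", "LIG", "A", 101, 0.5, 0.5, 0.0),
    "END")
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_lines(), path)
  path
}

# structure_model built directly (bypasses file I/O) for property tests
make_structure <- function(protein_df) {
  structure(list(protein = protein_df, ligands = list(), source = "toy"),
            class = "structure_model")
}

random_pose <- function(n, provenance = "reference") {
  ligand_pose(data.frame(name = paste0("C", seq_len(n)),
                         x = runif(n, -10, 10), y = runif(n, -10, 10),
                         z = runif(n, -10, 10), stringsAsFactors = FALSE),
              provenance = provenance)
}

# a tiny 3-residue gene: M1 A2 K3
toy_gene <- function() back_translate(1:3, "ATGGCTAAA", source_id = "toy")

# minimal stand-in run reports for aggregation tests
fake_report <- function(labels, counts, scores = NULL) {
  if (is.null(scores)) scores <- rev(seq_along(labels))
  sel <- data.frame(label = as.character(labels),
                    dna = if (length(labels))
                      paste0("DNA", seq_along(labels)) else character(0),
                    count = as.integer(counts),
                    score = as.numeric(scores),
                    num_mut = rep(1, length(labels)),
                    stringsAsFactors = FALSE)
  structure(list(seed = 0L,
                 termination = list(stop = TRUE, reason = "max_generations"),
                 generations = list(), final_selected = sel),
            class = "run_report")
}

# independent brute-force oracle: all single-nt variants of a codon
oracle_single_nt_variants <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  sp <- strsplit(codon, "")[[1]]
  for (p in 1:3) for (b in bases) {
    if (b != sp[p]) {
      v <- sp; v[p] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
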