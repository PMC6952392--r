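# DNA-level genetics of the drug-binding site: real codons, random
# single-nucleotide mutation, translation, and single-step accessibility.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Normalise a DNA/RNA string to the DNA alphabet
#'
#' Uppercases and converts U to T. Both alphabets are accepted on input
#' everywhere in the package; sequences are stored as DNA.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T\}.
#' @keywords internal
normalize_dna <- function(x) {
  x <- gsub("U", "T", toupper(x), fixed = TRUE)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid nucleotide alphabet in: ", paste(x[bad], collapse = ", "))
  }
  x
}

# Standard genetic code (NCBI table 1), DNA-keyed. Fixed for the package:
# kinase CDSs are nuclear genes.
genetic_code <- function() Biostrings::GENETIC_CODE

#' Split a codon-aligned DNA string into codons
#' @param dna single DNA string, length a multiple of 3.
#' @return character vector of 3-mers.
#' @keywords internal
split_codons <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  starts <- seq.int(1L, n, by = 3L)
  substring(dna, starts, starts + 2L)
}

#' Translate a codon-aligned DNA string with the standard genetic code
#'
#' @param dna single DNA (or RNA) string, length a multiple of 3.
#' @return character vector of one-letter amino acids; stop codons are `"*"`.
#' @examples
#' translate_dna("ATGGCTAAA")  # M A K
#' @export
translate_dna <- function(dna) {
  codons <- split_codons(normalize_dna(dna))
  aa <- unname(genetic_code()[codons])
  if (anyNA(aa)) stop("untranslatable codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}

#' Construct a binding-site gene
#'
#' The drug-binding-site residues represented by their actual gene codons,
#' tied to structure residue numbers. This is the wild-type genotype the
#' evolutionary simulation mutates.
#'
#' @param residues data.frame with columns `resno` (structure residue number,
#'   unique, strictly increasing), `wt_aa` (one-letter amino acid) and
#'   `codon` (3 nucleotides; U accepted, stored as T).
#' @param source_id free-text provenance (e.g. a PDB id plus a CDS id).
#' @return object of class `binding_site_gene` with elements `residues`,
#'   `source_id` and `dna` (the concatenated codons).
#' @export
binding_site_gene <- function(residues, source_id = "") {
  stopifnot(is.data.frame(residues))
  if (nrow(residues) == 0L) {
    residues <- data.frame(resno = integer(), wt_aa = character(),
                           codon = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("resno", "wt_aa", "codon") %in% names(residues)))
    residues$codon <- normalize_dna(residues$codon)
    if (any(nchar(residues$codon) != 3L)) stop("codons must have 3 nucleotides")
    if (is.unsorted(residues$resno, strictly = TRUE)) {
      stop("residue numbers must be unique and strictly increasing")
    }
    trans <- unname(genetic_code()[residues$codon])
    if (any(trans == "*")) stop("stop codon in wild-type binding-site gene")
    mism <- trans != residues$wt_aa
    if (any(mism)) {
      stop("codon/amino-acid mismatch at residue(s) ",
           paste(residues$resno[mism], collapse = ", "))
    }
  }
  structure(
    list(residues = residues, source_id = source_id,
         dna = paste(residues$codon, collapse = "")),
    class = "binding_site_gene"
  )
}

#' @export
print.binding_site_gene <- function(x, ...) {
  cat("Binding-site gene (", nrow(x$residues), " residues",
      if (nzchar(x$source_id)) paste0(", ", x$source_id), ")\n", sep = "")
  if (nrow(x$residues)) {
    lab <- paste0(x$residues$wt_aa, x$residues$resno, " [",
                  x$residues$codon, "]")
    cat(" ", paste(lab, collapse = " "), "\n")
  }
  invisible(x)
}

#' Back-translate selected residues into their real gene codons
#'
#' Looks up the actual codons of the selected structure residues in the coding
#' sequence, so that mutation accessibility reflects the true gene rather than
#' an arbitrary synonymous choice.
#'
#' @param residue_selection integer vector of structure residue numbers
#'   (e.g. from [define_binding_site()]).
#' @param cds coding DNA sequence: a character string, a
#'   [Biostrings::DNAString], or a path-free `DNAStringSet` of length one
#'   (see [read_cds()] for FASTA input). Length must be a multiple of 3.
#' @param offset structure residue number corresponding to the first codon of
#'   `cds` (the residue-number mapping).
#' @param source_id provenance string stored on the result.
#' @return a [binding_site_gene()].
#' @examples
#' back_translate(1:3, "ATGGCTAAA")  # M1, A2, K3
#' @export
back_translate <- function(residue_selection, cds, offset = 1L,
                           source_id = "") {
  cds <- as.character(cds)
  if (length(cds) != 1L) stop("cds must be a single sequence")
  cds <- normalize_dna(cds)
  codons <- split_codons(cds)
  residue_selection <- sort(unique(as.integer(residue_selection)))
  if (length(residue_selection) == 0L) {
    return(binding_site_gene(data.frame(), source_id = source_id))
  }
  idx <- residue_selection - as.integer(offset) + 1L
  out <- idx < 1L | idx > length(codons)
  if (any(out)) {
    stop("residue(s) not covered by the CDS mapping: ",
         paste(residue_selection[out], collapse = ", "))
  }
  codon <- codons[idx]
  wt_aa <- unname(genetic_code()[codon])
  if (any(wt_aa == "*")) {
    stop("selection includes a stop codon (residue ",
         paste(residue_selection[wt_aa == "*"], collapse = ", "), ")")
  }
  binding_site_gene(
    data.frame(resno = residue_selection, wt_aa = wt_aa, codon = codon,
               stringsAsFactors = FALSE),
    source_id = source_id
  )
}

#' Read a coding sequence from a FASTA file
#'
#' @param path FASTA file containing one DNA coding sequence (the first record
#'   is used).
#' @return single character DNA string.
#' @export
read_cds <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  normalize_dna(as.character(seqs[[1L]]))
}

#' Translate a mutant DNA sequence and classify its changes
#'
#' Compares a (possibly mutated) binding-site DNA sequence against the
#' wild-type gene codon by codon and classifies differences as silent,
#' missense or nonsense.
#'
#' @param dna mutant binding-site DNA, same length as the reference.
#' @param reference a [binding_site_gene()].
#' @return object of class `mutant_genotype`: list with `dna`,
#'   `aa_mutations` (data.frame `position`, `wt_aa`, `mut_aa`; missense only),
#'   `num_mut` (count of amino-acid mutations), `is_nonsense`, `is_silent`.
#' @export
translate_and_classify <- function(dna, reference) {
  stopifnot(inherits(reference, "binding_site_gene"))
  dna <- normalize_dna(dna)
  if (nchar(dna) != nchar(reference$dna)) {
    stop("mutant length ", nchar(dna), " != reference length ",
         nchar(reference$dna))
  }
  res <- reference$residues
  codons <- split_codons(dna)
  changed <- which(codons != res$codon)
  gc <- genetic_code()
  pos <- integer(0); wt <- character(0); mut <- character(0)
  nonsense <- FALSE
  for (i in changed) {
    aa <- unname(gc[[codons[i]]])
    if (aa == "*") {
      nonsense <- TRUE
    } else if (aa != res$wt_aa[i]) {
      pos <- c(pos, res$resno[i]); wt <- c(wt, res$wt_aa[i]); mut <- c(mut, aa)
    }
  }
  aa_mutations <- data.frame(position = pos, wt_aa = wt, mut_aa = mut,
                             stringsAsFactors = FALSE)
  structure(
    list(dna = dna, aa_mutations = aa_mutations, num_mut = nrow(aa_mutations),
         is_nonsense = nonsense,
         is_silent = length(changed) > 0L && nrow(aa_mutations) == 0L &&
           !nonsense),
    class = "mutant_genotype"
  )
}

#' Amino-acid-level label of a mutant genotype
#'
#' E.g. `"T315I"`; multiple substitutions are joined with `"+"`. Silent or
#' wild-type genotypes give `""`.
#'
#' @param genotype a `mutant_genotype`.
#' @return character label.
#' @export
mutation_label <- function(genotype) {
  m <- genotype$aa_mutations
  if (nrow(m) == 0L) return("")
  paste(paste0(m$wt_aa, m$position, m$mut_aa), collapse = "+")
}

#' Produce one offspring by random single-nucleotide mutation
#'
#' With probability `mutation_rate` the offspring carries one substitution at
#' a uniformly chosen position, replaced by one of the three alternative bases
#' uniformly; otherwise it is an exact copy of the parent. This per-offspring
#' Bernoulli semantics makes the expected number of mutation-bearing offspring
#' equal `rate * n_offspring` (a per-base mode is available in the batch
#' generator, [generate_offspring()]).
#'
#' @param parent a [binding_site_gene()] or `mutant_genotype`.
#' @param mutation_rate probability in \[0, 1\] that the offspring mutates.
#' @param reference the wild-type [binding_site_gene()]; defaults to `parent`
#'   when the parent is itself a binding-site gene.
#' @param rng_seed optional integer seed for reproducibility.
#' @return a `mutant_genotype`.
#' @export
mutate_offspring <- function(parent, mutation_rate, reference = NULL,
                             rng_seed = NULL) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (inherits(parent, "binding_site_gene")) {
    dna <- parent$dna
    if (is.null(reference)) reference <- parent
  } else {
    dna <- parent$dna
    if (is.null(reference)) stop("reference gene required for mutant parents")
  }
  if (stats::runif(1) < mutation_rate) {
    dna <- substitute_random_base(dna)
  }
  translate_and_classify(dna, reference)
}

# One uniformly placed single-nucleotide substitution (never a no-op).
substitute_random_base <- function(dna) {
  p <- sample.int(nchar(dna), 1L)
  cur <- substr(dna, p, p)
  new <- sample(setdiff(NUCLEOTIDES, cur), 1L)
  `substr<-`(dna, p, p, new)
}

#' Generate an offspring batch from one parent genotype
#'
#' Vectorised offspring generation used by the evolutionary engine. Offspring
#' that do not mutate are exact copies of the parent and are returned only as
#' a count; each mutation event yields one offspring DNA carrying a single
#' uniformly placed substitution on top of the parent sequence.
#'
#' @param parent_dna parent DNA string.
#' @param n_offspring number of offspring.
#' @param mutation_rate per-offspring mutation probability (default
#'   semantics), or per-base probability when `per_base = TRUE`.
#' @param per_base if `TRUE`, every base of every offspring mutates
#'   independently with probability `mutation_rate` (so one offspring can
#'   carry several new substitutions).
#' @return list with `n_offspring`, `n_copies` (unmutated copies of the
#'   parent) and `mutated_dna` (character vector, one element per offspring
#'   that acquired at least one new substitution).
#' @export
generate_offspring <- function(parent_dna, n_offspring, mutation_rate,
                               per_base = FALSE) {
  stopifnot(n_offspring >= 0, mutation_rate >= 0, mutation_rate <= 1)
  L <- nchar(parent_dna)
  if (!per_base) {
    n_events <- stats::rbinom(1L, n_offspring, mutation_rate)
    mutated <- character(n_events)
    if (n_events > 0L) {
      pos <- sample.int(L, n_events, replace = TRUE)
      alt <- sample.int(3L, n_events, replace = TRUE)
      bases <- strsplit(parent_dna, "")[[1L]]
      for (i in seq_len(n_events)) {
        dna <- parent_dna
        new <- setdiff(NUCLEOTIDES, bases[pos[i]])[alt[i]]
        substr(dna, pos[i], pos[i]) <- new
        mutated[i] <- dna
      }
    }
    list(n_offspring = n_offspring, n_copies = n_offspring - n_events,
         mutated_dna = mutated)
  } else {
    # total base-substitution events across the batch, then assigned to
    # offspring uniformly; offspring with >=1 event are materialised.
    n_events <- stats::rbinom(1L, n_offspring * L, mutation_rate)
    if (n_events == 0L) {
      return(list(n_offspring = n_offspring, n_copies = n_offspring,
                  mutated_dna = character(0)))
    }
    off <- sample.int(n_offspring, n_events, replace = TRUE)
    pos <- sample.int(L, n_events, replace = TRUE)
    alt <- sample.int(3L, n_events, replace = TRUE)
    bases <- strsplit(parent_dna, "")[[1L]]
    mutated <- vapply(split(seq_len(n_events), off), function(ev) {
      dna <- parent_dna
      for (i in ev) {
        new <- setdiff(NUCLEOTIDES, substr(dna, pos[i], pos[i]))[alt[i]]
        substr(dna, pos[i], pos[i]) <- new
      }
      dna
    }, character(1))
    list(n_offspring = n_offspring,
         n_copies = n_offspring - length(mutated),
         mutated_dna = unname(mutated))
  }
}

#' Minimum number of nucleotide substitutions between two codons
#'
#' The Hamming distance between codons: how many single-nucleotide changes
#' separate them. This is what makes some amino-acid substitutions easy to
#' reach in one mutational step and others practically inaccessible (e.g. the
#' threonine codon ACU needs two changes to reach the methionine codon AUG,
#' whereas the isoleucine codon AUU needs only one).
#'
#' @param codon_a,codon_b 3-letter codons (DNA or RNA alphabet).
#' @return integer in 0..3.
#' @examples
#' min_nt_substitutions("ACU", "AUG")  # 2
#' min_nt_substitutions("AUU", "AUG")  # 1
#' @export
min_nt_substitutions <- function(codon_a, codon_b) {
  codon_a <- normalize_dna(codon_a); codon_b <- normalize_dna(codon_b)
  if (nchar(codon_a) != 3L || nchar(codon_b) != 3L) {
    stop("codons must have 3 nucleotides")
  }
  sum(strsplit(codon_a, "")[[1L]] != strsplit(codon_b, "")[[1L]])
}

#' Amino acids reachable from a codon by one nucleotide substitution
#'
#' Enumerates all 9 single-nucleotide variants of a codon, translates them,
#' and counts the mutational routes to each amino acid. Synonymous variants
#' are reported as silent routes to the codon's own amino acid; stop codons
#' as nonsense routes.
#'
#' @param codon a valid 3-letter codon.
#' @return data.frame with columns `aa`, `n_routes` and `class`
#'   (`silent`/`missense`/`nonsense`), one row per reachable amino acid (or
#'   stop, labelled `"*"`).
#' @examples
#' accessible_substitutions("ACU")  # Met is absent: not single-step reachable
#' @export
accessible_substitutions <- function(codon) {
  codon <- normalize_dna(codon)
  if (nchar(codon) != 3L) stop("codon must have 3 nucleotides")
  gc <- genetic_code()
  wt_aa <- gc[[codon]]
  if (is.null(wt_aa)) stop("invalid codon ", codon)
  variants <- character(0)
  for (p in 1:3) {
    for (b in setdiff(NUCLEOTIDES, substr(codon, p, p))) {
      v <- codon
      substr(v, p, p) <- b
      variants <- c(variants, v)
    }
  }
  aa <- unname(gc[variants])
  tab <- table(aa)
  out <- data.frame(aa = names(tab), n_routes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$class <- ifelse(out$aa == "*", "nonsense",
                      ifelse(out$aa == wt_aa, "silent", "missense"))
  out[order(out$aa), , drop = FALSE]
}

#' Export single-step mutation routes of a binding-site gene as TSV
#'
#' One row per (residue, reachable amino acid): position, wild-type amino
#' acid, reachable substitution, and the number of single-nucleotide routes.
#'
#' @param gene a [binding_site_gene()].
#' @param path output TSV path; if `NULL`, the table is returned only.
#' @return the table, invisibly when written.
#' @export
mutation_routes_table <- function(gene, path = NULL) {
  rows <- lapply(seq_len(nrow(gene$residues)), function(i) {
    acc <- accessible_substitutions(gene$residues$codon[i])
    data.frame(position = gene$residues$resno[i],
               wt = gene$residues$wt_aa[i],
               mut = acc$aa, routes = acc$n_routes, class = acc$class,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
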