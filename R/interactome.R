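# Data model and geometry for the structural interactome.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V","X")

#' Create a protein record
#'
#' A protein is an opaque identifier plus its amino-acid sequence in
#' one-letter code. The alphabet is restricted to the 20 standard residues
#' plus 'X' for unknowns.
#'
#' @param id Protein identifier (e.g. a UniProt-style accession).
#' @param sequence Amino-acid sequence, single string, one-letter codes.
#' @return An object of class `ppi_protein`.
#' @export
protein <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("invalid residue code(s) in sequence of ", id, ": ",
         paste(bad, collapse = ","))
  structure(list(id = id, sequence = paste(chars, collapse = "")),
            class = "ppi_protein")
}

#' Create a chain structure
#'
#' Ordered residues of one polypeptide chain with 3D atom coordinates in
#' Angstrom. Residue positions must be strictly increasing and every
#' residue must carry at least one atom.
#'
#' @param chain_id Chain identifier.
#' @param positions Integer vector of 1-based residue positions,
#'   strictly increasing.
#' @param atoms List (same length as `positions`) of numeric matrices with
#'   3 columns (x, y, z), one row per atom.
#' @return An object of class `chain_structure`. Internally atoms are
#'   stored flat as a coordinate matrix plus a residue index for fast
#'   all-pairs distance work.
#' @export
chain_structure <- function(chain_id, positions, atoms) {
  positions <- as.integer(positions)
  stopifnot(length(positions) >= 1L, !anyNA(positions))
  if (any(diff(positions) <= 0L))
    stop("residue positions must be strictly increasing")
  stopifnot(is.list(atoms), length(atoms) == length(positions))
  n_at <- vapply(atoms, function(a) {
    a <- as.matrix(a)
    stopifnot(ncol(a) == 3L, is.numeric(a))
    nrow(a)
  }, integer(1))
  if (any(n_at == 0L)) stop("every residue must have at least one atom")
  coords <- do.call(rbind, lapply(atoms, function(a) {
    a <- as.matrix(a); storage.mode(a) <- "double"; a
  }))
  structure(list(chain_id = as.character(chain_id),
                 positions = positions,
                 coords = coords,
                 res_index = rep.int(seq_along(positions), n_at)),
            class = "chain_structure")
}

#' Create a sequence-alignment record
#'
#' Stands in for one BLAST hit of a protein sequence against a structure
#' chain: an E-value and an injective mapping from chain residue positions
#' to protein sequence positions.
#'
#' @param query_protein_id Protein identifier of the query.
#' @param chain_id Chain identifier of the subject.
#' @param e_value Non-negative alignment E-value.
#' @param residue_map Named integer vector: names are chain residue
#'   positions, values the aligned protein sequence positions.
#' @return An object of class `alignment_record`.
#' @export
alignment_record <- function(query_protein_id, chain_id, e_value, residue_map) {
  stopifnot(is.numeric(e_value), length(e_value) == 1L, e_value >= 0)
  rm <- as.integer(residue_map)
  names(rm) <- names(residue_map)
  if (is.null(names(rm)) || anyNA(suppressWarnings(as.integer(names(rm)))))
    stop("residue_map must be named by chain residue positions")
  if (anyDuplicated(rm)) stop("residue_map must be injective")
  structure(list(query_protein_id = query_protein_id,
                 chain_id = as.character(chain_id),
                 e_value = as.numeric(e_value),
                 residue_map = rm),
            class = "alignment_record")
}

#' Create a PPI record
#'
#' One interaction between two partner proteins, with per-partner
#' interface residue sets (protein sequence coordinates), an optional
#' binding free energy (kcal/mol) and an optional template annotation.
#' Homodimers (both partners identical) are allowed and flagged; their
#' interface sets are kept per chain role.
#'
#' @param partner_a,partner_b Protein identifiers.
#' @param interface_a,interface_b Integer vectors of interface residue
#'   positions on each partner.
#' @param delta_g Binding free energy in kcal/mol, `NA` if unknown.
#'   More negative means stronger binding.
#' @param template Optional list `list(structure_id=, chains=)`.
#' @param id Optional PPI identifier; defaults to "a:b" in input order.
#' @return An object of class `ppi_record`.
#' @export
ppi_record <- function(partner_a, partner_b, interface_a = integer(),
                       interface_b = integer(), delta_g = NA_real_,
                       template = NULL, id = NULL) {
  if (is.null(id)) id <- paste(partner_a, partner_b, sep = ":")
  structure(list(id = id,
                 partner_a = partner_a,
                 partner_b = partner_b,
                 interface_a = sort(unique(as.integer(interface_a))),
                 interface_b = sort(unique(as.integer(interface_b))),
                 delta_g = as.numeric(delta_g),
                 template = template,
                 homodimer = identical(partner_a, partner_b)),
            class = "ppi_record")
}

#' Assemble an interactome
#'
#' Collects proteins and PPI records into one structural-interactome
#' object. Every PPI partner must resolve to a protein, interface
#' positions must lie within the partner's sequence, and duplicate
#' unordered partner pairs are collapsed (first occurrence wins, stable
#' input order).
#'
#' @param proteins List of [protein()] objects.
#' @param ppis List of [ppi_record()] objects.
#' @param name Label for the interactome (e.g. a synthetic run id).
#' @return An object of class `interactome` with elements `name`,
#'   `sequences` (named character vector) and `ppis`.
#' @export
interactome <- function(proteins, ppis, name = "interactome") {
  seqs <- vapply(proteins, function(p) p$sequence, character(1))
  names(seqs) <- vapply(proteins, function(p) p$id, character(1))
  if (anyDuplicated(names(seqs))) stop("duplicate protein identifiers")
  keys <- vapply(ppis, function(p)
    paste(sort(c(p$partner_a, p$partner_b)), collapse = "\r"), character(1))
  ppis <- ppis[!duplicated(keys)]
  for (p in ppis) {
    for (side in c("a", "b")) {
      pid <- p[[paste0("partner_", side)]]
      if (!pid %in% names(seqs))
        stop("PPI partner ", pid, " not among proteins")
      ifc <- p[[paste0("interface_", side)]]
      if (length(ifc) && (min(ifc) < 1L || max(ifc) > nchar(seqs[[pid]])))
        stop("interface positions out of sequence bounds for ", pid)
    }
  }
  ids <- vapply(ppis, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate PPI identifiers")
  names(ppis) <- ids
  structure(list(name = name, sequences = seqs, ppis = ppis),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome>", x$name, "-", length(x$sequences), "proteins,",
      length(x$ppis), "PPIs\n")
  invisible(x)
}

#' Geometric interface residues between two chains
#'
#' A residue is an interface residue iff its minimum all-atom Euclidean
#' distance to the other chain is within `distance_cutoff` (inclusive;
#' boundary contacts count). The default 5 Angstrom is the conventional
#' atom-contact cutoff for residue-level interface annotation.
#'
#' @param chain_a,chain_b [chain_structure()] objects.
#' @param distance_cutoff Contact distance in Angstrom (> 0).
#' @return List with integer vectors `interface_a` and `interface_b` of
#'   residue positions. One side is non-empty iff the other is.
#' @export
compute_interface <- function(chain_a, chain_b, distance_cutoff = 5.0) {
  stopifnot(inherits(chain_a, "chain_structure"),
            inherits(chain_b, "chain_structure"))
  stopifnot(is.numeric(distance_cutoff), distance_cutoff > 0)
  A <- chain_a$coords
  B <- chain_b$coords
  if (nrow(A) == 0L || nrow(B) == 0L) stop("chain with zero atoms")
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  hit <- d2 <= distance_cutoff^2
  ia <- chain_a$positions[sort(unique(chain_a$res_index[rowSums(hit) > 0L]))]
  ib <- chain_b$positions[sort(unique(chain_b$res_index[colSums(hit) > 0L]))]
  list(interface_a = as.integer(ia), interface_b = as.integer(ib))
}

#' Annotate a PPI with a structural template
#'
#' Given a chain-pair interface (in chain coordinates) and a set of
#' pre-computed alignment records, a PPI is annotated with the chain pair
#' iff each partner aligns to a distinct chain of the pair such that the
#' fraction of that chain's interface residues covered by the alignment's
#' residue map is at least `coverage_threshold` (default 0.5, boundary
#' inclusive). Alignments are filtered at E-value <= `e_value_cutoff`,
#' keeping the smallest-E-value record per (protein, chain).
#'
#' @param ppi_partners Character vector of the two partner protein ids.
#' @param chain_pair List of the two [chain_structure()] chain ids,
#'   `list(chain_a =, chain_b =)` or a character vector of length 2.
#' @param chain_interface List with `interface_a`, `interface_b` in chain
#'   residue coordinates (as returned by [compute_interface()]).
#' @param alignments List of [alignment_record()] objects.
#' @param coverage_threshold Minimum mapped fraction of interface
#'   residues, in [0, 1]; values > 1 annotate nothing.
#' @param e_value_cutoff Alignment significance cutoff (default 1e-5).
#' @return A list `list(chains=, interface_a=, interface_b=)` with the
#'   interfaces re-expressed in protein sequence coordinates, or `NULL`
#'   when no chain assignment reaches the coverage threshold (including
#'   the case where both partners align only to the same chain).
#' @export
annotate_ppi_template <- function(ppi_partners, chain_pair, chain_interface,
                                  alignments, coverage_threshold = 0.5,
                                  e_value_cutoff = 1e-5) {
  chains <- unlist(chain_pair, use.names = FALSE)
  stopifnot(length(ppi_partners) == 2L, length(chains) == 2L)
  alignments <- Filter(function(a) a$e_value <= e_value_cutoff, alignments)
  best <- list()
  for (a in alignments) {
    key <- paste(a$query_protein_id, a$chain_id, sep = "\r")
    if (is.null(best[[key]]) || a$e_value < best[[key]]$e_value)
      best[[key]] <- a
  }
  ifc <- list(chain_interface$interface_a, chain_interface$interface_b)
  mapped <- function(protein, chain_i) {
    aln <- best[[paste(protein, chains[chain_i], sep = "\r")]]
    if (is.null(aln)) return(NULL)
    want <- ifc[[chain_i]]
    if (length(want) == 0L) return(NULL)
    have <- intersect(as.character(want), names(aln$residue_map))
    if (length(have) / length(want) < coverage_threshold) return(NULL)
    sort(unname(aln$residue_map[have]))
  }
  # try partner 1 -> chain 1, partner 2 -> chain 2, then the swap
  for (ord in list(c(1L, 2L), c(2L, 1L))) {
    m1 <- mapped(ppi_partners[1], ord[1])
    m2 <- mapped(ppi_partners[2], ord[2])
    if (!is.null(m1) && !is.null(m2))
      return(list(chains = chains[ord], interface_a = m1, interface_b = m2))
  }
  NULL
}

#' Count mutually exclusive PPIs
#'
#' For a given PPI, counts the other PPIs of either partner that share
#' that partner's binding interface. Interface sharing is measured as
#' `|intersection| / min(|set1|, |set2|)` and two PPIs are mutually
#' exclusive when this overlap reaches `overlap_threshold` (default 0.5).
#' Empty interface sets contribute nothing. The count is binned as
#' "0", "1-4" or ">=5", the bins used to separate single-interface date
#' hubs from multi-interface party hubs.
#'
#' @param interactome An [interactome()].
#' @param ppi A [ppi_record()] belonging to the interactome (or its id).
#' @param overlap_threshold Overlap fraction in (0, 1].
#' @param index Optional precomputed protein-to-PPI index (internal, used
#'   by [exclusivity_bins()] to avoid rebuilding it per PPI).
#' @return List with `count` (integer) and `bin` (character).
#' @export
count_mutually_exclusive <- function(interactome, ppi, overlap_threshold = 0.5,
                                     index = NULL) {
  stopifnot(inherits(interactome, "interactome"))
  if (is.character(ppi)) ppi <- interactome$ppis[[ppi]]
  stopifnot(inherits(ppi, "ppi_record"),
            overlap_threshold > 0, overlap_threshold <= 1)
  overlap <- function(s1, s2) {
    if (length(s1) == 0L || length(s2) == 0L) return(0)
    length(intersect(s1, s2)) / min(length(s1), length(s2))
  }
  iface_on <- function(q, prot) {
    out <- list()
    if (q$partner_a == prot) out <- c(out, list(q$interface_a))
    if (q$partner_b == prot) out <- c(out, list(q$interface_b))
    out
  }
  if (is.null(index)) index <- ppi_index(interactome)
  partners <- unique(c(ppi$partner_a, ppi$partner_b))
  hits <- character()
  for (prot in partners) {
    own <- iface_on(ppi, prot)
    for (qid in index[[prot]]) {
      if (qid == ppi$id) next
      q <- interactome$ppis[[qid]]
      for (s_own in own) for (s_q in iface_on(q, prot)) {
        if (overlap(s_own, s_q) >= overlap_threshold) hits <- c(hits, q$id)
      }
    }
  }
  count <- length(unique(hits))
  bin <- if (count == 0L) "0" else if (count <= 4L) "1-4" else ">=5"
  list(count = count, bin = bin)
}

# protein id -> character vector of PPI ids touching it
ppi_index <- function(interactome) {
  idx <- new.env(parent = emptyenv())
  for (p in interactome$ppis) {
    for (prot in unique(c(p$partner_a, p$partner_b)))
      assign(prot, c(if (exists(prot, idx, inherits = FALSE))
        get(prot, idx), p$id), idx)
  }
  idx
}

#' Exclusivity bins for every PPI in an interactome
#'
#' @inheritParams count_mutually_exclusive
#' @return Data frame with columns `ppi_id`, `n_exclusive`, `bin`.
#' @export
exclusivity_bins <- function(interactome, overlap_threshold = 0.5) {
  idx <- ppi_index(interactome)
  res <- lapply(interactome$ppis, function(p)
    count_mutually_exclusive(interactome, p, overlap_threshold, index = idx))
  data.frame(ppi_id = names(interactome$ppis),
             n_exclusive = vapply(res, `[[`, integer(1), "count"),
             bin = vapply(res, `[[`, character(1), "bin"),
             row.names = NULL, stringsAsFactors = FALSE)
}
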