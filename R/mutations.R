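# Missense mutation filtering, flank verification, and interface mapping.

#' Validate a mutation table
#'
#' Mutation records are plain data frames with one row per missense
#' variant: `protein_id`, `position` (1-based), `wt`, `mut` (one-letter
#' residues), `mclass` ("common" or "disease"), `maf` (minor allele
#' frequency, required for common records, NA allowed for disease).
#'
#' @param mutations Data frame of mutation records.
#' @return The validated data frame (invisibly unchanged), with an error
#'   on malformed input.
#' @export
validate_mutations <- function(mutations) {
  need <- c("protein_id", "position", "wt", "mut", "mclass", "maf")
  missing_cols <- setdiff(need, names(mutations))
  if (length(missing_cols))
    stop("mutation table lacks column(s): ", paste(missing_cols, collapse = ","))
  if (!all(mutations$mclass %in% c("common", "disease")))
    stop("mclass must be 'common' or 'disease'")
  if (any(mutations$wt == mutations$mut))
    stop("wild-type and mutant residues must differ")
  common <- mutations$mclass == "common"
  if (any(common & is.na(mutations$maf)))
    stop("common records require a minor allele frequency")
  if (any(!is.na(mutations$maf) & (mutations$maf < 0 | mutations$maf > 1)))
    stop("maf must lie in [0, 1]")
  if (any(mutations$position < 1L))
    stop("positions are 1-based")
  mutations
}

#' Verify a mutation position by flanking-sequence match
#'
#' Confirms that a transcript-reported mutation position is consistent
#' with the reference protein sequence. The flanking window spans
#' `min(flank_length, available)` residues on each side of the mutation
#' plus the wild-type residue itself, taken from the transcript sequence;
#' the mutation is accepted iff this window occurs in `protein_sequence`
#' at the identical positions. A wild-type residue mismatch at the stated
#' position therefore rejects (it falls inside the window).
#'
#' @param transcript List with `sequence` (amino-acid string) and
#'   `position` (1-based mutation position on the transcript). A
#'   `protein_id` element may be present but is not consulted.
#' @param protein_sequence Reference (UniProt-style) protein sequence.
#' @param flank_length Residues per side, default 10.
#' @return `TRUE` if accepted, `FALSE` otherwise.
#' @export
verify_flank <- function(transcript, protein_sequence, flank_length = 10L) {
  pos <- as.integer(transcript$position)
  tseq <- transcript$sequence
  stopifnot(pos >= 1L, pos <= nchar(tseq))
  left <- max(1L, pos - flank_length)
  right <- min(nchar(tseq), pos + flank_length)
  if (right > nchar(protein_sequence)) return(FALSE)
  substr(tseq, left, right) == substr(protein_sequence, left, right)
}

#' Filter common and disease mutation sets
#'
#' Applies the cohort-level filters: disease records are deduplicated by
#' (protein, position); common records are restricted to minor allele
#' frequency >= `maf_min` (boundary inclusive, default 1\%), deduplicated
#' by (protein, position), and any common record sharing a (protein,
#' position) with a kept disease record is discarded. Deduplication keeps
#' the first record in stable input order. The operation is idempotent.
#'
#' @param common,disease Mutation data frames (see [validate_mutations()]).
#' @param maf_min Minimum minor allele frequency for common records.
#' @return List with elements `common` and `disease`.
#' @export
filter_mutation_sets <- function(common, disease, maf_min = 0.01) {
  key <- function(df) paste(df$protein_id, df$position, sep = "\r")
  if (nrow(disease)) disease <- disease[!duplicated(key(disease)), , drop = FALSE]
  if (nrow(common)) {
    common <- common[!is.na(common$maf) & common$maf >= maf_min, , drop = FALSE]
    common <- common[!duplicated(key(common)), , drop = FALSE]
    common <- common[!key(common) %in% key(disease), , drop = FALSE]
  }
  rownames(common) <- NULL
  rownames(disease) <- NULL
  list(common = common, disease = disease)
}

#' Locate mutations on PPI binding interfaces
#'
#' For each mutation, lists the PPIs whose interface on the mutated
#' protein contains the mutation position. Mutations on proteins absent
#' from the interactome, or outside every interface, get an empty list
#' (they are retained as non-interfacial).
#'
#' @param mutations Mutation data frame (assumed flank-verified).
#' @param interactome An [interactome()].
#' @return List (one element per mutation row) of character vectors of
#'   PPI ids.
#' @export
locate_interfacial <- function(mutations, interactome) {
  stopifnot(inherits(interactome, "interactome"))
  # protein -> data.frame(ppi_id, position) over both partner roles
  tab <- new.env(parent = emptyenv())
  add <- function(prot, pid, ifc) {
    if (!length(ifc)) return()
    cur <- if (exists(prot, tab, inherits = FALSE)) get(prot, tab) else NULL
    assign(prot, rbind(cur, data.frame(ppi_id = pid, position = ifc,
                                       stringsAsFactors = FALSE)), tab)
  }
  for (p in interactome$ppis) {
    add(p$partner_a, p$id, p$interface_a)
    add(p$partner_b, p$id, p$interface_b)
  }
  lapply(seq_len(nrow(mutations)), function(i) {
    prot <- mutations$protein_id[i]
    if (!exists(prot, tab, inherits = FALSE)) return(character())
    m <- get(prot, tab)
    unique(m$ppi_id[m$position == mutations$position[i]])
  })
}

#' Attach per-PPI binding-energy changes to mutations
#'
#' Joins a ddG effect table (see [read_ddg_tsv()]) onto interfacial PPI
#' lists, producing one row per (mutation, interfacial PPI) with the ddG
#' value when available (NA when the energy calculation is missing).
#'
#' @param mutations Mutation data frame.
#' @param interfacial List from [locate_interfacial()] parallel to
#'   `mutations` rows.
#' @param effects ddG data frame with columns `protein_id`, `position`,
#'   `mut`, `ppi_id`, `ddg`.
#' @return Data frame with columns `mutation_row`, `protein_id`,
#'   `position`, `mut`, `mclass`, `ppi_id`, `ddg`.
#' @export
attach_effects <- function(mutations, interfacial, effects) {
  stopifnot(length(interfacial) == nrow(mutations))
  n_per <- lengths(interfacial)
  idx <- rep.int(seq_len(nrow(mutations)), n_per)
  out <- data.frame(
    mutation_row = idx,
    protein_id = mutations$protein_id[idx],
    position = mutations$position[idx],
    mut = mutations$mut[idx],
    mclass = mutations$mclass[idx],
    ppi_id = unlist(interfacial, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    ekey <- paste(effects$protein_id, effects$position, effects$mut,
                  effects$ppi_id, sep = "\r")
    okey <- paste(out$protein_id, out$position, out$mut, out$ppi_id,
                  sep = "\r")
    out$ddg <- effects$ddg[match(okey, ekey)]
  } else {
    out$ddg <- numeric()
  }
  out
}
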