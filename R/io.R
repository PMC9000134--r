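# File formats: PDB coordinates, FASTA sequences, TSV tables.

#' Read chain structures from a PDB-format file
#'
#' Parses ATOM records only (hetero/solvent records are excluded) from the
#' first MODEL of a standard fixed-column PDB file and returns one
#' [chain_structure()] per chain. All atoms present are used, including
#' hydrogens if recorded. Alternate location indicators other than ' ' or
#' 'A' are skipped.
#'
#' @param path Path to a PDB file.
#' @return Named list of [chain_structure()] objects, one per chain id.
#' @export
read_pdb_chains <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  at <- lines[startsWith(lines, "ATOM  ")]
  if (!length(at)) stop("no ATOM records in ", path)
  altloc <- substr(at, 17, 17)
  at <- at[altloc %in% c(" ", "A")]
  chain <- substr(at, 22, 22)
  resseq <- as.integer(substr(at, 23, 26))
  x <- as.numeric(substr(at, 31, 38))
  y <- as.numeric(substr(at, 39, 46))
  z <- as.numeric(substr(at, 47, 54))
  out <- list()
  for (ch in unique(chain)) {
    sel <- chain == ch
    pos <- resseq[sel]
    coords <- cbind(x[sel], y[sel], z[sel])
    upos <- sort(unique(pos))
    atoms <- lapply(upos, function(p) coords[pos == p, , drop = FALSE])
    out[[ch]] <- chain_structure(ch, upos, atoms)
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return List of [protein()] objects.
#' @export
read_fasta_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("^\\s*(\\S+).*$", "\\1", names(seqs))
  Map(protein, ids, as.character(seqs), USE.NAMES = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins List of [protein()] objects, or an [interactome()].
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta_proteins <- function(proteins, path, width = 60L) {
  seqs <- if (inherits(proteins, "interactome")) proteins$sequences else {
    stats::setNames(vapply(proteins, `[[`, character(1), "sequence"),
                    vapply(proteins, `[[`, character(1), "id"))
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

.join_pos <- function(x) paste(x, collapse = ",")
.split_pos <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer())
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Serialize an interactome's PPIs to TSV
#'
#' One PPI per row with comma-separated interface positions per partner.
#' Sequences travel separately as FASTA ([write_fasta_proteins()]).
#'
#' @param interactome An [interactome()].
#' @param path Output path.
#' @export
write_interactome_tsv <- function(interactome, path) {
  df <- data.frame(
    ppi_id = vapply(interactome$ppis, `[[`, character(1), "id"),
    partner_a = vapply(interactome$ppis, `[[`, character(1), "partner_a"),
    partner_b = vapply(interactome$ppis, `[[`, character(1), "partner_b"),
    interface_a = vapply(interactome$ppis, function(p)
      .join_pos(p$interface_a), character(1)),
    interface_b = vapply(interactome$ppis, function(p)
      .join_pos(p$interface_b), character(1)),
    delta_g = vapply(interactome$ppis, `[[`, numeric(1), "delta_g"),
    stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an interactome from TSV + FASTA
#'
#' @param ppi_path TSV written by [write_interactome_tsv()].
#' @param fasta_path FASTA of partner sequences.
#' @param name Interactome label.
#' @return An [interactome()].
#' @export
read_interactome_tsv <- function(ppi_path, fasta_path, name = "interactome") {
  df <- data.table::fread(ppi_path, sep = "\t", colClasses = list(
    character = c("ppi_id", "partner_a", "partner_b",
                  "interface_a", "interface_b")), data.table = FALSE)
  prots <- read_fasta_proteins(fasta_path)
  ppis <- lapply(seq_len(nrow(df)), function(i)
    ppi_record(df$partner_a[i], df$partner_b[i],
               .split_pos(df$interface_a[i]), .split_pos(df$interface_b[i]),
               delta_g = df$delta_g[i], id = df$ppi_id[i]))
  interactome(prots, ppis, name = name)
}

#' Read a mutation table from TSV
#'
#' Expected columns: `protein_id`, `position`, `wt`, `mut`, `mclass`
#' (common/disease), `maf` (NA allowed for disease records).
#'
#' @param path TSV path.
#' @return Data frame of mutation records.
#' @export
read_mutations_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = c(
                            "protein_id", "wt", "mut", "mclass")))
  validate_mutations(df)
}

#' Write a mutation table to TSV
#' @param mutations Data frame of mutation records.
#' @param path Output path.
#' @export
write_mutations_tsv <- function(mutations, path) {
  data.table::fwrite(mutations, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read per-PPI binding-energy changes from TSV
#'
#' Shape of a FoldX BuildModel summary: one row per (mutation, PPI) with
#' columns `protein_id`, `position`, `mut`, `ppi_id`, `ddg` (kcal/mol,
#' positive = destabilizing).
#'
#' @param path TSV path.
#' @return Data frame of ddG effects.
#' @export
read_ddg_tsv <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = list(character = c(
                      "protein_id", "mut", "ppi_id")))
}

#' Write per-PPI binding-energy changes to TSV
#' @param effects Data frame as described in [read_ddg_tsv()].
#' @param path Output path.
#' @export
write_ddg_tsv <- function(effects, path) {
  data.table::fwrite(effects, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an expression experiment to TSV (genes x conditions)
#' @param experiment An [expression_experiment()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(experiment, path) {
  df <- data.frame(gene = rownames(experiment$matrix),
                   experiment$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an expression experiment from TSV
#' @param path TSV with a `gene` column then one column per condition.
#' @param experiment_id Experiment identifier.
#' @param kind One of "time_course", "tissue", "promoter".
#' @return An [expression_experiment()].
#' @export
read_expression_tsv <- function(path, experiment_id, kind) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = "gene"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  expression_experiment(experiment_id, kind, m, colnames(m))
}

#' Write a bundle of expression experiments plus a manifest
#'
#' The manifest (`manifest.tsv`) lists `experiment_id`, `kind` and `file`
#' for each experiment.
#'
#' @param experiments List of [expression_experiment()] objects.
#' @param dir Output directory (created if missing).
#' @export
write_expression_bundle <- function(experiments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(experiments, function(e) {
    f <- paste0("expr_", e$experiment_id, ".tsv")
    write_expression_tsv(e, file.path(dir, f))
    f
  }, character(1))
  manifest <- data.frame(
    experiment_id = vapply(experiments, `[[`, character(1), "experiment_id"),
    kind = vapply(experiments, `[[`, character(1), "kind"),
    file = files, stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(dir)
}

#' Read a bundle of expression experiments via its manifest
#' @param dir Directory written by [write_expression_bundle()].
#' @return List of [expression_experiment()] objects.
#' @export
read_expression_bundle <- function(dir) {
  manifest <- data.table::fread(file.path(dir, "manifest.tsv"), sep = "\t",
                                data.table = FALSE)
  lapply(seq_len(nrow(manifest)), function(i)
    read_expression_tsv(file.path(dir, manifest$file[i]),
                        manifest$experiment_id[i], manifest$kind[i]))
}
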