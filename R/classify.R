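# Transient/permanent PPI classification from binding energy and
# expression data.
#
# All threshold comparisons are strict: a co-expression exactly at the
# median is "permanent", an imbalance exactly at the median is
# "balanced". "Majority" means strictly more than half of the
# experiments with a defined value; even splits fall to the
# permanent/balanced side.

#' Create an expression experiment
#'
#' @param experiment_id Identifier.
#' @param kind One of "time_course", "tissue" (transcript abundance
#'   across tissues) or "promoter" (promoter-activity across tissue
#'   samples, treated as a second tissue-expression source). Time-course
#'   experiments must have at least 5 conditions.
#' @param matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   conditions in columns; NA marks an undefined value.
#' @param condition_labels Ordered condition (time point or tissue)
#'   labels; defaults to the matrix column names.
#' @return Object of class `expression_experiment`.
#' @export
expression_experiment <- function(experiment_id, kind, matrix,
                                  condition_labels = colnames(matrix)) {
  kind <- match.arg(kind, c("time_course", "tissue", "promoter"))
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stop("matrix must have gene rownames")
  if (kind == "time_course" && ncol(matrix) < 5L)
    stop("time-course experiments require at least 5 time points")
  if (length(condition_labels) != ncol(matrix))
    stop("condition_labels must match the number of columns")
  if (any(matrix < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  colnames(matrix) <- condition_labels
  structure(list(experiment_id = as.character(experiment_id), kind = kind,
                 matrix = matrix, condition_labels = condition_labels),
            class = "expression_experiment")
}

#' Classifier configuration
#'
#' Thresholds for the transient/permanent classifiers. Median thresholds
#' left NULL are derived from the dataset itself by [derive_median()]
#' over all defined per-PPI values, which by construction yields ~50\%
#' transient (resp. unbalanced) prevalence for single-value properties.
#'
#' @param dg_weak_cutoff Binding free energy cutoff in kcal/mol; a PPI
#'   with delta G >= cutoff is weak. Default -25.
#' @param ddg_cutoff Binding-energy-change cutoff for edgetic disruption
#'   (kcal/mol), default 0.5; see [predict_disruptions()].
#' @param overlap_threshold Interface-sharing overlap for mutual
#'   exclusivity, default 0.5.
#' @param min_shared Minimum shared defined conditions for a Pearson
#'   correlation, default 5.
#' @param median_temporal,median_spatial_expr,median_spatial_promoter
#'   Co-expression median thresholds (supplied or derived).
#' @param median_balance_time,median_balance_space_expr,median_balance_space_promoter
#'   Abundance-imbalance median thresholds (supplied or derived).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(dg_weak_cutoff = -25, ddg_cutoff = 0.5,
                              overlap_threshold = 0.5, min_shared = 5L,
                              median_temporal = NULL,
                              median_spatial_expr = NULL,
                              median_spatial_promoter = NULL,
                              median_balance_time = NULL,
                              median_balance_space_expr = NULL,
                              median_balance_space_promoter = NULL) {
  cfg <- list(dg_weak_cutoff = dg_weak_cutoff, ddg_cutoff = ddg_cutoff,
              overlap_threshold = overlap_threshold,
              min_shared = as.integer(min_shared),
              median_temporal = median_temporal,
              median_spatial_expr = median_spatial_expr,
              median_spatial_promoter = median_spatial_promoter,
              median_balance_time = median_balance_time,
              median_balance_space_expr = median_balance_space_expr,
              median_balance_space_promoter = median_balance_space_promoter)
  supplied <- !vapply(cfg, is.null, logical(1))
  if (!all(vapply(cfg[supplied], function(x) is.numeric(x) && all(is.finite(x)),
                  logical(1))))
    stop("supplied thresholds must be finite numbers")
  structure(cfg, class = "classifier_config")
}

#' Classify interaction strength from binding free energy
#'
#' A PPI is weak iff its binding free energy is greater than or equal to
#' the cutoff (boundary inclusive: delta G = -25 kcal/mol is weak),
#' otherwise strong. Missing energies yield "unknown".
#'
#' @param delta_g Binding free energy (kcal/mol); vectorized.
#' @param cutoff Weakness cutoff, default -25 kcal/mol.
#' @return Character vector in {"weak", "strong", "unknown"}.
#' @export
classify_strength <- function(delta_g, cutoff = -25) {
  out <- ifelse(is.na(delta_g), "unknown",
                ifelse(delta_g >= cutoff, "weak", "strong"))
  as.character(out)
}

#' Pearson co-expression of two interaction partners
#'
#' Sample Pearson correlation over the conditions where both genes have
#' defined values. Undefined (NA) when either gene is absent, fewer than
#' `min_shared` conditions are shared, or either profile has zero
#' variance on the shared conditions.
#'
#' @param experiment An [expression_experiment()].
#' @param gene_a,gene_b Gene identifiers (matrix rownames).
#' @param min_shared Minimum shared defined conditions, default 5.
#' @return List with `r` (numeric or NA) and `n_shared`.
#' @export
pairwise_coexpression <- function(experiment, gene_a, gene_b,
                                  min_shared = 5L) {
  m <- experiment$matrix
  if (!(gene_a %in% rownames(m)) || !(gene_b %in% rownames(m)))
    return(list(r = NA_real_, n_shared = 0L))
  xa <- m[gene_a, ]
  xb <- m[gene_b, ]
  ok <- !is.na(xa) & !is.na(xb)
  n <- sum(ok)
  if (n < min_shared) return(list(r = NA_real_, n_shared = n))
  if (stats::sd(xa[ok]) == 0 || stats::sd(xb[ok]) == 0)
    return(list(r = NA_real_, n_shared = n))
  list(r = stats::cor(xa[ok], xb[ok]), n_shared = n)
}

#' Temporal transience from co-expression across experiments
#'
#' A PPI is transient in an experiment iff its partner co-expression is
#' strictly below `global_median`; overall it is transient in time iff it
#' is transient in strictly more than half of the experiments with a
#' defined correlation. "unknown" when no experiment is defined.
#'
#' @param r_values Numeric vector of per-experiment correlations (NA =
#'   undefined) for one PPI.
#' @param global_median Median co-expression of all interaction partners
#'   across all experiments (supplied or derived from the dataset).
#' @return "transient", "permanent" or "unknown".
#' @export
classify_temporal <- function(r_values, global_median) {
  r <- r_values[!is.na(r_values)]
  if (!length(r)) return("unknown")
  if (sum(r < global_median) > length(r) / 2) "transient" else "permanent"
}

#' Spatial transience from a single tissue-wide co-expression
#'
#' @param r Tissue co-expression of the partners (NA = undefined).
#' @param median_threshold Median co-expression over all PPIs in the
#'   structural interactome for the same data source.
#' @return "transient" (r strictly below the median), "permanent"
#'   (at or above), or "unknown". Vectorized over `r`.
#' @export
classify_spatial <- function(r, median_threshold) {
  as.character(ifelse(is.na(r), "unknown",
                      ifelse(r < median_threshold, "transient", "permanent")))
}

#' Abundance imbalance of two interaction partners
#'
#' Mean absolute log10 expression difference over the conditions where
#' both partners have defined, strictly positive values (zero or missing
#' values are skipped pointwise; no pseudocount). Undefined when no
#' condition is valid.
#'
#' @param experiment An [expression_experiment()].
#' @param gene_a,gene_b Gene identifiers.
#' @return List with `value` (numeric or NA) and `n_valid`.
#' @export
abundance_imbalance <- function(experiment, gene_a, gene_b) {
  m <- experiment$matrix
  if (!(gene_a %in% rownames(m)) || !(gene_b %in% rownames(m)))
    return(list(value = NA_real_, n_valid = 0L))
  xa <- m[gene_a, ]
  xb <- m[gene_b, ]
  ok <- !is.na(xa) & !is.na(xb) & xa > 0 & xb > 0
  if (!any(ok)) return(list(value = NA_real_, n_valid = 0L))
  list(value = mean(abs(log10(xa[ok]) - log10(xb[ok]))), n_valid = sum(ok))
}

#' Stoichiometric balance classification
#'
#' A PPI is unbalanced in an experiment iff its mean absolute log10
#' expression difference is strictly greater than `global_median`. With
#' `majority_mode = TRUE` (time-course data) per-experiment verdicts are
#' aggregated by strict majority as in [classify_temporal()]; with
#' `majority_mode = FALSE` (tissue data) a single value decides.
#'
#' @param values Numeric vector of per-experiment imbalance values (NA =
#'   undefined) for one PPI; length 1 when `majority_mode = FALSE`.
#' @param global_median Median imbalance among all experiments and all
#'   interaction partners.
#' @param majority_mode Aggregate across experiments by majority?
#' @return "unbalanced", "balanced" or "unknown".
#' @export
classify_balance <- function(values, global_median, majority_mode = TRUE) {
  v <- values[!is.na(values)]
  if (!length(v)) return("unknown")
  if (!majority_mode) v <- v[1L]
  if (sum(v > global_median) > length(v) / 2) "unbalanced" else "balanced"
}

#' Sample median of defined values
#'
#' Standard sample median (mean of the two middle order statistics for
#' even counts) after dropping NA entries; errors when nothing remains.
#'
#' @param values Numeric vector.
#' @return The median as a length-1 numeric.
#' @export
derive_median <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no defined values to take a median of")
  stats::median(v)
}

# per-PPI coexpression (or imbalance) values for one experiment,
# vectorised over the PPI list
.ppi_values <- function(interactome, experiment, fun, ...) {
  vapply(interactome$ppis, function(p) {
    res <- fun(experiment, p$partner_a, p$partner_b, ...)
    as.numeric(res[[1L]])
  }, numeric(1))
}

#' Classify every PPI in an interactome
#'
#' Runs all eight transient/permanent property classifiers: strength
#' (binding free energy), temporal co-expression (time-course
#' experiments, majority rule), spatial co-expression (tissue and
#' promoter sources), stoichiometric balance over time and over space
#' (both tissue sources), and mutual-exclusivity bins. Median thresholds
#' not supplied in `config` are derived from the dataset (the median of
#' all defined per-PPI values, pooled across experiments for time-course
#' data).
#'
#' @param interactome An [interactome()].
#' @param experiments List of [expression_experiment()] objects; kinds
#'   "time_course", "tissue" and "promoter" feed the temporal, spatial
#'   and promoter-based classifiers respectively.
#' @param config A [classifier_config()].
#' @return Data frame (one row per PPI): `ppi_id`, `strength`,
#'   `temporal`, `spatial_expr`, `spatial_promoter`, `balance_time`,
#'   `balance_space_expr`, `balance_space_promoter`, `exclusivity_bin`,
#'   plus the thresholds used as attribute `"thresholds"`.
#' @export
classify_interactome <- function(interactome, experiments,
                                 config = classifier_config()) {
  stopifnot(inherits(interactome, "interactome"))
  kinds <- vapply(experiments, `[[`, character(1), "kind")
  tc <- experiments[kinds == "time_course"]
  tissue <- experiments[kinds == "tissue"]
  promoter <- experiments[kinds == "promoter"]
  n_ppi <- length(interactome$ppis)

  # temporal: PPIs x experiments matrices of r and imbalance
  r_tc <- sapply(tc, function(e)
    .ppi_values(interactome, e, pairwise_coexpression,
                min_shared = config$min_shared))
  b_tc <- sapply(tc, function(e)
    .ppi_values(interactome, e, abundance_imbalance))
  if (length(tc)) {
    r_tc <- matrix(r_tc, nrow = n_ppi)
    b_tc <- matrix(b_tc, nrow = n_ppi)
    med_t <- config$median_temporal %||% derive_median(as.vector(r_tc))
    med_bt <- config$median_balance_time %||% derive_median(as.vector(b_tc))
    temporal <- apply(r_tc, 1L, classify_temporal, global_median = med_t)
    balance_time <- apply(b_tc, 1L, classify_balance, global_median = med_bt,
                          majority_mode = TRUE)
  } else {
    med_t <- med_bt <- NA_real_
    temporal <- balance_time <- rep("unknown", n_ppi)
  }

  spatial_one <- function(exps, med_r_sup, med_b_sup) {
    if (!length(exps))
      return(list(spatial = rep("unknown", n_ppi),
                  balance = rep("unknown", n_ppi),
                  med_r = NA_real_, med_b = NA_real_))
    e <- exps[[1L]]  # one pooled matrix per tissue source
    r <- .ppi_values(interactome, e, pairwise_coexpression,
                     min_shared = config$min_shared)
    b <- .ppi_values(interactome, e, abundance_imbalance)
    med_r <- med_r_sup %||% derive_median(r)
    med_b <- med_b_sup %||% derive_median(b)
    list(spatial = classify_spatial(r, med_r),
         balance = vapply(b, classify_balance, character(1),
                          global_median = med_b, majority_mode = FALSE),
         med_r = med_r, med_b = med_b)
  }
  sp_e <- spatial_one(tissue, config$median_spatial_expr,
                      config$median_balance_space_expr)
  sp_p <- spatial_one(promoter, config$median_spatial_promoter,
                      config$median_balance_space_promoter)

  dg <- vapply(interactome$ppis, `[[`, numeric(1), "delta_g")
  excl <- exclusivity_bins(interactome, config$overlap_threshold)

  out <- data.frame(
    ppi_id = names(interactome$ppis),
    strength = classify_strength(dg, config$dg_weak_cutoff),
    temporal = temporal,
    spatial_expr = sp_e$spatial,
    spatial_promoter = sp_p$spatial,
    balance_time = balance_time,
    balance_space_expr = sp_e$balance,
    balance_space_promoter = sp_p$balance,
    exclusivity_bin = excl$bin,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- list(
    temporal = med_t, balance_time = med_bt,
    spatial_expr = sp_e$med_r, balance_space_expr = sp_e$med_b,
    spatial_promoter = sp_p$med_r, balance_space_promoter = sp_p$med_b)
  out
}

#' Write PPI classification labels to TSV
#' @param labels Data frame from [classify_interactome()].
#' @param path Output path.
#' @export
write_labels_tsv <- function(labels, path) {
  data.table::fwrite(labels, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read PPI classification labels from TSV
#' @param path TSV written by [write_labels_tsv()].
#' @return Data frame of labels.
#' @export
read_labels_tsv <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = "character")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
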