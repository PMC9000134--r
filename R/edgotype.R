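# Structure-based edgotype prediction and Table-1-style tabulation.

# property name -> labels column and the transient/permanent group values
PROPERTY_GROUPS <- list(
  strength = list(col = "strength", transient = "weak", permanent = "strong"),
  temporal = list(col = "temporal", transient = "transient",
                  permanent = "permanent"),
  spatial_expr = list(col = "spatial_expr", transient = "transient",
                      permanent = "permanent"),
  spatial_promoter = list(col = "spatial_promoter", transient = "transient",
                          permanent = "permanent"),
  balance_time = list(col = "balance_time", transient = "unbalanced",
                      permanent = "balanced"),
  balance_space_expr = list(col = "balance_space_expr",
                            transient = "unbalanced", permanent = "balanced"),
  balance_space_promoter = list(col = "balance_space_promoter",
                                transient = "unbalanced",
                                permanent = "balanced"),
  exclusivity_1_4 = list(col = "exclusivity_bin", transient = "1-4",
                         permanent = "0"),
  exclusivity_5plus = list(col = "exclusivity_bin", transient = ">=5",
                           permanent = "0"))

#' Predict edgetic PPI disruptions from interfacial ddG
#'
#' A mutation edgetically disrupts a PPI iff it lies on the interface
#' mediating that PPI and its binding-energy change exceeds the cutoff
#' strictly (ddG > 0.5 kcal/mol by default; a ddG of exactly 0.5 never
#' disrupts). Non-interfacial PPIs are never disrupted regardless of
#' ddG. Interfacial rows lacking a ddG value are left undisrupted and
#' flagged incomplete. Cutoffs of 1, 2 and 3 kcal/mol are the usual
#' robustness sweep.
#'
#' @param effects Data frame of (mutation, PPI) rows as produced by
#'   [attach_effects()]: at least columns `ppi_id` and `ddg`; an optional
#'   logical `on_interface` column (default TRUE for every row, since
#'   [attach_effects()] emits interfacial pairs only).
#' @param ddg_cutoff Disruption cutoff in kcal/mol, default 0.5.
#' @return The input with logical columns `on_interface`, `disrupted`
#'   and `incomplete` appended.
#' @export
predict_disruptions <- function(effects, ddg_cutoff = 0.5) {
  stopifnot(is.numeric(ddg_cutoff), length(ddg_cutoff) == 1L)
  if (is.null(effects$on_interface))
    effects$on_interface <- rep(TRUE, nrow(effects))
  effects$incomplete <- effects$on_interface & is.na(effects$ddg)
  effects$disrupted <- effects$on_interface & !is.na(effects$ddg) &
    effects$ddg > ddg_cutoff
  effects
}

#' Assign the edgotype of one mutation
#'
#' Edgetic iff the mutation disrupts at least one PPI, quasi-wild-type
#' otherwise; mono-edgetic iff it disrupts exactly one. Quasi-null
#' (stability-mediated loss of all PPIs) is not predicted structurally:
#' strongly detrimental mutations are assumed quasi-null downstream, so
#' the engine only emits edgetic/quasi-wild-type.
#'
#' @param calls Disruption calls for one mutation (rows of the
#'   [predict_disruptions()] output).
#' @param n_ppis_of_protein Number of PPIs of the mutated protein.
#' @return List with `n_disrupted`, `n_ppis_of_protein`, `label`
#'   ("edgetic"/"quasi_wild_type") and `mono_edgetic`.
#' @export
assign_edgotype <- function(calls, n_ppis_of_protein = NA_integer_) {
  n_disrupted <- if (nrow(calls)) sum(calls$disrupted) else 0L
  list(n_disrupted = as.integer(n_disrupted),
       n_ppis_of_protein = as.integer(n_ppis_of_protein),
       label = if (n_disrupted >= 1L) "edgetic" else "quasi_wild_type",
       mono_edgetic = n_disrupted == 1L)
}

#' Edgotype assignments for a whole cohort
#'
#' @param mutations Mutation data frame.
#' @param calls [predict_disruptions()] output whose `mutation_row`
#'   indexes rows of `mutations`.
#' @param interactome Optional [interactome()] used to count each
#'   protein's PPIs.
#' @return Data frame: one row per mutation with `n_disrupted`, `label`,
#'   `mono_edgetic`.
#' @export
assign_edgotypes <- function(mutations, calls, interactome = NULL) {
  n <- nrow(mutations)
  n_disrupted <- integer(n)
  if (nrow(calls)) {
    agg <- tapply(calls$disrupted, calls$mutation_row, sum)
    n_disrupted[as.integer(names(agg))] <- as.integer(agg)
  }
  deg <- rep(NA_integer_, n)
  if (!is.null(interactome)) {
    idx <- ppi_index(interactome)
    deg <- vapply(mutations$protein_id, function(p)
      if (exists(p, idx, inherits = FALSE)) length(get(p, idx)) else 0L,
      integer(1))
  }
  data.frame(mutation_row = seq_len(n),
             protein_id = mutations$protein_id,
             mclass = mutations$mclass,
             n_disrupted = n_disrupted,
             n_ppis_of_protein = deg,
             label = ifelse(n_disrupted >= 1L, "edgetic", "quasi_wild_type"),
             mono_edgetic = n_disrupted == 1L,
             stringsAsFactors = FALSE)
}

#' Tabulate edgetic disruptions per mutation class and PPI group
#'
#' Produces one Table-1-shaped row for a transient/permanent property:
#' totals of eligible common and disease mutations and, per class, the
#' number of mutations edgetically disrupting at least one PPI of the
#' transient group and of the permanent group. A mutation is eligible
#' iff its protein has at least one PPI carrying a group label for the
#' property (this reproduces the per-property varying totals); a
#' mutation disrupting PPIs in both groups counts once in each group
#' cell. With `mono_edgetic = TRUE` only mutations disrupting exactly
#' one PPI of a group count in that group's cell.
#'
#' @param mutations Mutation data frame (columns `protein_id`, `mclass`).
#' @param calls [predict_disruptions()] output (`mutation_row`, `ppi_id`,
#'   `disrupted`).
#' @param interactome An [interactome()].
#' @param labels Data frame from [classify_interactome()].
#' @param property One of `names(PROPERTY_GROUPS)`: "strength",
#'   "temporal", "spatial_expr", "spatial_promoter", "balance_time",
#'   "balance_space_expr", "balance_space_promoter", "exclusivity_1_4",
#'   "exclusivity_5plus".
#' @param mono_edgetic Count only single-PPI disrupters per group?
#' @return One-row data frame with columns `property`, `common_total`,
#'   `common_disrupt_T`, `common_disrupt_P`, `disease_total`,
#'   `disease_disrupt_T`, `disease_disrupt_P`.
#' @export
tabulate_edgotypes <- function(mutations, calls, interactome, labels,
                               property, mono_edgetic = FALSE) {
  grp <- PROPERTY_GROUPS[[property]]
  if (is.null(grp)) stop("unknown property: ", property)
  lab <- stats::setNames(labels[[grp$col]], labels$ppi_id)

  idx <- ppi_index(interactome)
  eligible <- vapply(mutations$protein_id, function(p) {
    if (!exists(p, idx, inherits = FALSE)) return(FALSE)
    any(lab[get(p, idx)] %in% c(grp$transient, grp$permanent), na.rm = TRUE)
  }, logical(1))

  call_lab <- lab[calls$ppi_id]
  count_group <- function(value, class) {
    rows <- calls$disrupted & !is.na(call_lab) & call_lab == value
    per_mut <- tapply(rows, calls$mutation_row, sum)
    hit <- if (mono_edgetic) per_mut == 1L else per_mut >= 1L
    mut_rows <- as.integer(names(per_mut))[hit]
    sum(mutations$mclass[mut_rows] == class & eligible[mut_rows])
  }
  data.frame(
    property = property,
    common_total = sum(eligible & mutations$mclass == "common"),
    common_disrupt_T = count_group(grp$transient, "common"),
    common_disrupt_P = count_group(grp$permanent, "common"),
    disease_total = sum(eligible & mutations$mclass == "disease"),
    disease_disrupt_T = count_group(grp$transient, "disease"),
    disease_disrupt_P = count_group(grp$permanent, "disease"),
    stringsAsFactors = FALSE)
}
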