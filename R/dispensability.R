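# Bayesian estimation of dispensable PPI content with log-scale
# ratio-of-proportions confidence intervals.
#
# Model. Missense mutations are effectively neutral (N), mildly
# deleterious (M) or strongly detrimental (S) with prior probabilities
# P(N), P(M), P(S). Common variants from healthy individuals proxy N,
# disease variants proxy M, and S-class mutations are assumed
# quasi-null (they destabilize the protein) so their edgetic rate
# P(T|S) is 0. For a PPI group T (e.g. weak transient PPIs), the
# marginal edgetic-disruption probability of a new missense mutation is
#
#   P(T) = P(T|N) P(N) + P(T|M) P(M) + P(T|S) P(S)
#
# and the dispensable content of group T is the posterior
#
#   P(N|T) = P(T|N) P(N) / P(T),
#
# equivalently 1/P(N|T) = 1 + (P(M)/P(N)) (P(T|M)/P(T|N)), so it depends
# on the data only through the rate ratio.

#' Prior probabilities of mutation fitness classes
#'
#' @param p_neutral,p_mild,p_detrimental Probabilities of the neutral,
#'   mildly deleterious and strongly detrimental classes; must sum to 1
#'   (tolerance 1e-9). The defaults (0.27, 0.53, 0.20) are the
#'   population-genetics estimates for new human missense mutations.
#' @return Named numeric vector of class `prior_set`.
#' @export
prior_set <- function(p_neutral = 0.27, p_mild = 0.53, p_detrimental = 0.20) {
  p <- c(N = p_neutral, M = p_mild, S = p_detrimental)
  if (any(p < 0 | p > 1)) stop("priors must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) stop("priors must sum to 1")
  structure(p, class = "prior_set")
}

#' Per-class edgetic disruption rates from tabulated counts
#'
#' Converts one Table-1-shaped count row into the conditional
#' proportions P(T|N) = common disrupters / common total and
#' P(T|M) = disease disrupters / disease total for the chosen group.
#'
#' @param counts One-row data frame from [tabulate_edgotypes()] (or with
#'   the same columns).
#' @param group "T" for the transient-side group, "P" for the
#'   permanent-side group.
#' @return List of class `edgotype_rates`: `p_t_n`, `p_t_m`, `p_t_s`
#'   (fixed 0) and the counts behind each proportion.
#' @export
rates_from_counts <- function(counts, group = c("T", "P")) {
  group <- match.arg(group)
  a <- counts[[paste0("common_disrupt_", group)]]
  b <- counts[[paste0("disease_disrupt_", group)]]
  n1 <- counts$common_total
  n2 <- counts$disease_total
  if (n1 <= 0 || n2 <= 0) stop("zero denominator in count row")
  structure(list(p_t_n = a / n1, p_t_m = b / n2, p_t_s = 0,
                 a = a, n1 = n1, b = b, n2 = n2),
            class = "edgotype_rates")
}

#' Dispensable content of a PPI group
#'
#' Point estimate of the fraction of group-T PPIs that are effectively
#' neutral upon edgetic disruption: the marginal P(T) by total
#' probability and the posterior P(N|T) by Bayes' theorem (see the model
#' note at the top of this file). The closed form
#' 1/P(N|T) = 1 + (P(M)/P(N)) (P(T|M)/P(T|N)) is algebraically identical
#' and is used for the confidence interval mapping.
#'
#' @param rates An [rates_from_counts()] object, or a list with `p_t_n`
#'   and `p_t_m`.
#' @param priors A [prior_set()].
#' @return List of class `dispensable_estimate`: `p_t` (marginal),
#'   `p_n_given_t` (dispensable content), `ratio` = P(T|N)/P(T|M), and
#'   `defined` (FALSE when P(T) = 0, in which case the estimate is
#'   flagged undefined).
#' @export
dispensable_content <- function(rates, priors = prior_set()) {
  pn <- rates$p_t_n
  pm <- rates$p_t_m
  ps <- rates$p_t_s %||% 0
  p_t <- pn * priors[["N"]] + pm * priors[["M"]] + ps * priors[["S"]]
  if (p_t == 0)
    return(structure(list(p_t = 0, p_n_given_t = NA_real_, ratio = NA_real_,
                          defined = FALSE), class = "dispensable_estimate"))
  structure(list(p_t = p_t,
                 p_n_given_t = pn * priors[["N"]] / p_t,
                 ratio = if (pm > 0) pn / pm else NA_real_,
                 defined = TRUE),
            class = "dispensable_estimate")
}

# Eq-3 transform: rate ratio r = P(T|N)/P(T|M) -> P(N|T), monotone
# increasing in r at fixed priors.
.ratio_to_content <- function(r, priors) {
  k <- priors[["M"]] / priors[["N"]]
  1 / (1 + k / r)
}

#' Confidence interval for dispensable content (Bland method)
#'
#' 95\% interval for the ratio of two independent proportions on the log
#' scale: r = (a/n1)/(b/n2), SE(ln r) = sqrt(1/a - 1/n1 + 1/b - 1/n2),
#' interval r * exp(-/+ z SE). Each ratio endpoint is then mapped through
#' the monotone closed form 1/P(N|T) = 1 + (P(M)/P(N))/r to a bound on
#' dispensable content, so endpoint order is preserved. Zero numerators
#' fall back to a continuity-corrected variant (0.5 added to all four
#' counts) and the result is flagged approximate.
#'
#' @param counts Numeric vector or list `(a, n1, b, n2)`: common
#'   disrupters and total, disease disrupters and total. An
#'   [rates_from_counts()] object also works.
#' @param priors A [prior_set()].
#' @param level Confidence level, default 0.95 (z = 1.96 under the
#'   normal approximation).
#' @return List with `ci_low`, `ci_high` (bounds on dispensable
#'   content), `ratio_low`, `ratio_high` (bounds on the rate ratio) and
#'   `corrected` (TRUE when the continuity correction was applied).
#' @export
bland_ci <- function(counts, priors = prior_set(), level = 0.95) {
  if (is.list(counts) && !is.null(counts$a)) {
    a <- counts$a; n1 <- counts$n1; b <- counts$b; n2 <- counts$n2
  } else {
    counts <- as.numeric(counts)
    a <- counts[1L]; n1 <- counts[2L]; b <- counts[3L]; n2 <- counts[4L]
  }
  stopifnot(n1 > 0, n2 > 0, a >= 0, b >= 0, a <= n1, b <= n2)
  corrected <- a == 0 || b == 0
  if (corrected) {
    a <- a + 0.5; n1 <- n1 + 0.5; b <- b + 0.5; n2 <- n2 + 0.5
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  r <- (a / n1) / (b / n2)
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  ratio_low <- r * exp(-z * se)
  ratio_high <- r * exp(z * se)
  list(ci_low = .ratio_to_content(ratio_low, priors),
       ci_high = .ratio_to_content(ratio_high, priors),
       ratio_low = ratio_low, ratio_high = ratio_high,
       corrected = corrected)
}

#' Prior sensitivity of dispensable content
#'
#' Evaluates P(N|T) over a grid of (P(N), P(M)) prior pairs at fixed
#' rates, via the closed form. The uninformative point P(M)/P(N) = 1 is
#' always included; as P(M)/P(N) tends to 0 the dispensable content
#' tends to 1.
#'
#' @param rates List with `p_t_n`, `p_t_m` (e.g. [rates_from_counts()]).
#' @param prior_grid Data frame or matrix with columns `p_neutral`,
#'   `p_mild` (P(S) absorbs the remainder). Default: the uninformative
#'   point only.
#' @return Data frame with the grid plus `mn_ratio` = P(M)/P(N) and
#'   `p_n_given_t`.
#' @export
prior_sensitivity <- function(rates,
                              prior_grid = data.frame(p_neutral = 0.4,
                                                      p_mild = 0.4)) {
  prior_grid <- as.data.frame(prior_grid)
  rr <- rates$p_t_n / rates$p_t_m
  mn <- prior_grid$p_mild / prior_grid$p_neutral
  data.frame(prior_grid, mn_ratio = mn,
             p_n_given_t = 1 / (1 + mn / rr))
}

#' Printed Table-1-style edgotype counts for the two human structural
#' interactomes
#'
#' The published per-property disruption counts for the Y2H-derived
#' (Y2H-SI) and literature-derived (Lit-SI) structural interactomes,
#' provided as tabulated input so the estimator can be run without the
#' upstream prediction stages. For the exclusivity rows the
#' permanent-side group ("no mutually exclusive partner") is shared
#' between the "1-4" and ">=5" rows; the ">=5" rows carry NA in the
#' permanent cells.
#'
#' @return Data frame with columns `property`, `si`, `common_total`,
#'   `common_disrupt_T`, `common_disrupt_P`, `disease_total`,
#'   `disease_disrupt_T`, `disease_disrupt_P`.
#' @export
reference_counts <- function() {
  tab <- rbind(
    c("strength",               "Y2H", 1080,  3, 13,  348,  7, 36),
    c("strength",               "Lit", 2867, 27, 29, 1572, 51, 68),
    c("temporal",               "Y2H", 1080,  7,  9,  347, 18, 24),
    c("temporal",               "Lit", 2867, 16, 40, 1571, 57, 61),
    c("spatial_expr",           "Y2H", 1075,  4,  7,  336, 12, 19),
    c("spatial_expr",           "Lit", 2859, 19, 29, 1563, 61, 49),
    c("spatial_promoter",       "Y2H", 1080,  3, 13,  345, 23, 17),
    c("spatial_promoter",       "Lit", 2862, 19, 32, 1570, 57, 60),
    c("balance_time",           "Y2H", 1080,  1, 15,  347,  8, 34),
    c("balance_time",           "Lit", 2867, 12, 44, 1570, 32, 85),
    c("balance_space_expr",     "Y2H", 1080, 11,  5,  343, 21, 17),
    c("balance_space_expr",     "Lit", 2866, 32, 23, 1567, 58, 56),
    c("balance_space_promoter", "Y2H", 1080,  6, 10,  344, 22, 17),
    c("balance_space_promoter", "Lit", 2862, 22, 29, 1568, 48, 67),
    c("exclusivity_1_4",        "Y2H", 1079,  4,  2,  348, 24,  8),
    c("exclusivity_1_4",        "Lit", 2865, 30, 10, 1566, 50, 34),
    c("exclusivity_5plus",      "Y2H", 1079,  9, NA,  348, 11, NA),
    c("exclusivity_5plus",      "Lit", 2865, 14, NA, 1566, 29, NA))
  out <- data.frame(property = tab[, 1], si = tab[, 2],
                    stringsAsFactors = FALSE)
  num <- apply(tab[, 3:8], 2, as.numeric)
  colnames(num) <- c("common_total", "common_disrupt_T", "common_disrupt_P",
                     "disease_total", "disease_disrupt_T",
                     "disease_disrupt_P")
  cbind(out, as.data.frame(num))
}

#' Full dispensable-content analysis over a count table
#'
#' For every property row and both PPI groups: the conditional
#' proportions, their ratio, the marginal disruption probability, the
#' dispensable content and its 95\% confidence interval. Rows whose
#' permanent-side cells are NA (shared-group rows) report the transient
#' side only.
#'
#' @param counts Count table shaped like [reference_counts()] (the
#'   output of [tabulate_edgotypes()] row-bound over properties works,
#'   after adding an `si` column, or with `si` absent).
#' @param priors A [prior_set()].
#' @param level Confidence level for the intervals.
#' @return Data frame with one row per (property row, group).
#' @export
run_full_analysis <- function(counts, priors = prior_set(), level = 0.95) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, , drop = FALSE]
    per_group <- lapply(c("T", "P"), function(g) {
      if (is.na(row[[paste0("common_disrupt_", g)]])) return(NULL)
      rates <- rates_from_counts(row, g)
      est <- dispensable_content(rates, priors)
      ci <- if (est$defined)
        bland_ci(rates, priors, level) else
          list(ci_low = NA_real_, ci_high = NA_real_, corrected = NA)
      data.frame(property = row$property,
                 si = row$si %||% NA_character_,
                 group = g,
                 p_t_n = rates$p_t_n, p_t_m = rates$p_t_m,
                 ratio = est$ratio,
                 p_t = est$p_t,
                 p_n_given_t = est$p_n_given_t,
                 ci_low = ci$ci_low, ci_high = ci$ci_high,
                 defined = est$defined,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_group)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# round half away from zero, the usual convention of printed tables
# (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format an analysis at printed precision
#'
#' Rounds the analysis of [run_full_analysis()] to report precision
#' (half away from zero): proportions and dispensable content as
#' percentages with 1 decimal, and the rate ratio to 2 decimals computed
#' from the rounded percentages, so the printed table is internally
#' consistent at its own precision.
#'
#' @param analysis Data frame from [run_full_analysis()].
#' @return Data frame with percentage columns `p_t_n_pct`, `p_t_m_pct`,
#'   `ratio`, `p_n_given_t_pct`, `ci_low_pct`, `ci_high_pct`.
#' @export
format_analysis <- function(analysis) {
  pn <- round_half_up(100 * analysis$p_t_n, 1)
  pm <- round_half_up(100 * analysis$p_t_m, 1)
  data.frame(property = analysis$property, si = analysis$si,
             group = analysis$group,
             p_t_n_pct = pn, p_t_m_pct = pm,
             ratio = round_half_up(pn / pm, 2),
             p_n_given_t_pct = round_half_up(100 * analysis$p_n_given_t, 1),
             ci_low_pct = round_half_up(100 * analysis$ci_low),
             ci_high_pct = round_half_up(100 * analysis$ci_high),
             stringsAsFactors = FALSE)
}
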