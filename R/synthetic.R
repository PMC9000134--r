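# Seeded synthetic-data generator: interactome with toy coordinates and
# binding energies, expression experiments, and mutation cohorts with
# known ground-truth disruption rates.
#
# The generator states a world resembling the Y2H-derived human
# structural interactome: 1,916 PPIs among 1,468 proteins, 57% weak
# interactions, 1,080 common and 348 disease mutations, 63 time-course
# experiments (>= 5 points each), 16 tissues and 183 promoter-activity
# samples, interfacial binding-energy changes averaging 0.33 kcal/mol
# for common and 1.1 kcal/mol for disease mutations.

# deterministic sub-stream seed below 2^31
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 69069 + k * 1009) %% 2147483629)
}

#' Synthetic-data generator configuration
#'
#' Defaults state the generator's world (see the package vignette for
#' rationale); all randomness derives from `seed`.
#'
#' @param n_proteins,n_ppis Network size (defaults 1468 proteins, 1916
#'   PPIs, the Y2H-derived structural interactome scale).
#' @param hub_fraction Fraction of proteins acting as single-interface
#'   (date-hub-like) hubs whose PPIs share one binding interface.
#' @param hub_degree_range Range of hub degrees (spans the 1-4 and >= 5
#'   mutual-exclusivity bins).
#' @param weak_fraction Target share of weak PPIs (delta G >= -25
#'   kcal/mol), default 0.57.
#' @param dg_weak_mean,dg_weak_sd,dg_strong_mean,dg_strong_sd Two-class
#'   binding free energy mixture (kcal/mol); each component is truncated
#'   on its side of the -25 kcal/mol boundary so the realized weak share
#'   is binomial around `weak_fraction`.
#' @param seq_length_range Protein sequence length range.
#' @param interface_size_range Interface residue-set size range.
#' @param n_time_experiments Number of time-course experiments (63).
#' @param time_points_range Conditions per time-course experiment
#'   (minimum 5).
#' @param n_tissues,n_promoter_samples Conditions of the two
#'   tissue-expression sources (16 and 183).
#' @param expr_noise_sd Per-gene log10 expression spread per condition.
#' @param abundance_sd Between-gene spread of mean log10 abundance; the
#'   per-pair imbalance offset is the difference of partner means.
#' @param n_common,n_disease Cohort sizes (1080 and 348).
#' @param interfacial_fraction_common,interfacial_fraction_disease Share
#'   of each cohort placed on PPI interfaces.
#' @param ddg_mean_common,ddg_mean_disease Class means of the interfacial
#'   binding-energy change (kcal/mol), defaults 0.33 and 1.1.
#' @param ddg_sd Spread of the (zero-truncated) ddG draws.
#' @param true_disrupt_rate_common,true_disrupt_rate_disease Ground-truth
#'   probability for a mutation of each class to edgetically disrupt a
#'   weak (transient-group) PPI; defaults 0.003 and 0.02.
#' @param seed Master seed; fixes every stream.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 1468L, n_ppis = 1916L,
                             hub_fraction = 0.08,
                             hub_degree_range = c(3L, 9L),
                             weak_fraction = 0.57,
                             dg_weak_mean = -15, dg_weak_sd = 5,
                             dg_strong_mean = -35, dg_strong_sd = 6,
                             seq_length_range = c(120L, 400L),
                             interface_size_range = c(6L, 12L),
                             n_time_experiments = 63L,
                             time_points_range = c(5L, 15L),
                             n_tissues = 16L, n_promoter_samples = 183L,
                             expr_noise_sd = 0.4, abundance_sd = 0.5,
                             n_common = 1080L, n_disease = 348L,
                             interfacial_fraction_common = 0.15,
                             interfacial_fraction_disease = 0.25,
                             ddg_mean_common = 0.33, ddg_mean_disease = 1.1,
                             ddg_sd = 0.5,
                             true_disrupt_rate_common = 0.003,
                             true_disrupt_rate_disease = 0.02,
                             seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$hub_fraction, cfg$weak_fraction,
             cfg$interfacial_fraction_common, cfg$interfacial_fraction_disease,
             cfg$true_disrupt_rate_common, cfg$true_disrupt_rate_disease)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(cfg$n_proteins, cfg$n_ppis, cfg$n_common, cfg$n_disease) < 1))
    stop("counts must be positive")
  if (cfg$time_points_range[1] < 5L)
    stop("time-course experiments need at least 5 points")
  if (cfg$true_disrupt_rate_common > cfg$interfacial_fraction_common ||
      cfg$true_disrupt_rate_disease > cfg$interfacial_fraction_disease)
    stop("disruption rate cannot exceed the interfacial fraction")
  structure(cfg, class = "generator_config")
}

# toy two-chain point cloud whose 5 A interface equals the declared
# sets: interface atoms 3 A apart across chains (< 4), everything else
# >= 20 A away (> 8)
.toy_chains <- function(len_a, ifc_a, len_b, ifc_b) {
  coords_for <- function(len, ifc, y_ifc, y_other) {
    is_ifc <- seq_len(len) %in% ifc
    k <- cumsum(is_ifc)           # interface rank, aligned across chains
    x <- ifelse(is_ifc, (k - 1L) * 0.05, seq_len(len) * 0.05)
    y <- ifelse(is_ifc, y_ifc, y_other)
    lapply(seq_len(len), function(i) matrix(c(x[i], y[i], 0), ncol = 3))
  }
  list(a = chain_structure("A", seq_len(len_a),
                           coords_for(len_a, ifc_a, 0, -20)),
       b = chain_structure("B", seq_len(len_b),
                           coords_for(len_b, ifc_b, 3, 23)))
}

#' Generate a synthetic structural interactome
#'
#' Builds a network with hub proteins whose PPIs share one binding
#' interface (exercising the mutual-exclusivity bins), per-PPI interface
#' residue sets, binding free energies from the two-component
#' weak/strong mixture, and (optionally) toy two-chain coordinates whose
#' geometric 5 Angstrom interface equals the declared sets (interface
#' residues sit within 4 A of the partner chain, all other residues at
#' least 8 A away).
#'
#' @param config A [generator_config()].
#' @param coordinates Attach toy chain structures? (TRUE by default;
#'   skipping them speeds up large runs that do not touch geometry.)
#' @return An [interactome()]; when `coordinates` is TRUE each PPI
#'   record carries a `chains` element with the two
#'   [chain_structure()]s.
#' @export
generate_interactome <- function(config = generator_config(),
                                 coordinates = TRUE) {
  set.seed(.sub_seed(config$seed, 1L))
  np <- config$n_proteins
  max_pairs <- np * (np - 1) / 2
  if (config$n_ppis > max_pairs) stop("n_ppis exceeds the number of pairs")
  ids <- sprintf("P%05d", seq_len(np))
  lens <- sample(seq(config$seq_length_range[1], config$seq_length_range[2]),
                 np, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste(sample(AA_ALPHABET[1:20], l, replace = TRUE), collapse = ""),
    character(1))
  proteins <- Map(protein, ids, seqs)

  isz <- function() sample(seq(config$interface_size_range[1],
                               config$interface_size_range[2]), 1L)
  # non-hub interfaces are kept disjoint per protein, so interface
  # sharing (mutual exclusivity) arises only from hub proteins
  used <- new.env(parent = emptyenv())
  pick_interface <- function(id, len, size, register = TRUE) {
    size <- min(size, len)
    taken <- if (exists(id, used, inherits = FALSE)) get(id, used) else
      integer()
    starts <- seq_len(len - size + 1L)
    free <- starts[vapply(starts, function(s)
      !any(seq(s, s + size - 1L) %in% taken), logical(1))]
    s <- if (length(free)) resample1(free) else resample1(starts)
    ifc <- seq(s, s + size - 1L)
    if (register) assign(id, c(taken, ifc), used)
    ifc
  }

  n_hub <- round(config$hub_fraction * np)
  hubs <- if (n_hub > 0) sample(ids, n_hub) else character()
  hub_iface <- lapply(stats::setNames(nm = hubs), function(h)
    pick_interface(h, lens[match(h, ids)], isz()))

  edges <- list()
  seen <- new.env(parent = emptyenv())
  add_edge <- function(a, b, ifc_a, ifc_b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (exists(key, seen, inherits = FALSE)) return(FALSE)
    assign(key, TRUE, seen)
    edges[[length(edges) + 1L]] <<- ppi_record(a, b, ifc_a, ifc_b)
    TRUE
  }
  # date-hub edges: all of a hub's PPIs reuse the hub's single interface
  for (h in hubs) {
    deg <- sample(seq(config$hub_degree_range[1], config$hub_degree_range[2]),
                  1L)
    partners <- sample(setdiff(ids, h), deg)
    for (p in partners) {
      if (length(edges) >= config$n_ppis) break
      add_edge(h, p, hub_iface[[h]],
               pick_interface(p, lens[match(p, ids)], isz()))
    }
    if (length(edges) >= config$n_ppis) break
  }
  # remaining edges: random pairs with their own interfaces
  guard <- 0L
  while (length(edges) < config$n_ppis && guard < 50L * config$n_ppis) {
    guard <- guard + 1L
    pair <- sample(ids, 2L)
    add_edge(pair[1], pair[2],
             pick_interface(pair[1], lens[match(pair[1], ids)], isz()),
             pick_interface(pair[2], lens[match(pair[2], ids)], isz()))
  }
  if (length(edges) < config$n_ppis)
    stop("could not place the requested number of PPIs")

  # two-component delta G mixture, truncated at the -25 boundary so the
  # weak share is exactly binomial(weak_fraction)
  n_e <- length(edges)
  weak <- stats::runif(n_e) < config$weak_fraction
  draw_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      cand <- stats::rnorm(length(need), mean, sd)
      ok <- cand >= lower & cand < upper
      out[need[ok]] <- cand[ok]
      need <- need[!ok]
    }
    out
  }
  dg <- numeric(n_e)
  dg[weak] <- draw_trunc(sum(weak), config$dg_weak_mean, config$dg_weak_sd,
                         lower = -25)
  dg[!weak] <- draw_trunc(sum(!weak), config$dg_strong_mean,
                          config$dg_strong_sd, upper = -25)
  for (i in seq_len(n_e)) edges[[i]]$delta_g <- dg[i]

  if (coordinates) {
    for (i in seq_len(n_e)) {
      e <- edges[[i]]
      ch <- .toy_chains(lens[match(e$partner_a, ids)], e$interface_a,
                        lens[match(e$partner_b, ids)], e$interface_b)
      edges[[i]]$chains <- ch
    }
  }
  interactome(proteins, edges, name = sprintf("synthetic-%d", config$seed))
}

#' Simulate one interaction pair's expression profiles
#'
#' Exact per-pair construction used by the generator contract tests:
#' partner log10 profiles are bivariate normal with correlation `r` and
#' mean difference `offset`, then exponentiated to expression scale.
#'
#' @param r Target Pearson correlation of the log profiles, in [-1, 1].
#' @param offset Log10 abundance offset between the partners.
#' @param n Number of conditions.
#' @param sd Per-gene log10 spread.
#' @param base Mean log10 abundance of partner b.
#' @return List with numeric vectors `a` and `b` of length `n`.
#' @export
simulate_pair_profiles <- function(r, offset, n, sd = 0.4, base = 2) {
  stopifnot(r >= -1, r <= 1, n >= 1)
  u <- stats::rnorm(n)
  v <- stats::rnorm(n)
  za <- base + offset + sd * u
  zb <- base + sd * (r * u + sqrt(1 - r^2) * v)
  list(a = 10^za, b = 10^zb)
}

#' Generate synthetic expression experiments
#'
#' Gene profiles follow a one-factor model per experiment: gene g has a
#' co-expression loading lambda_g in [0, 1] and mean log10 abundance
#' mu_g, and its log10 expression at condition c is
#' mu_g + sd (lambda_g f_c + sqrt(1 - lambda_g^2) eps_gc) with a shared
#' standard-normal factor f_c. Any two genes then have log-scale
#' correlation lambda_a lambda_b and log10 abundance offset mu_a - mu_b,
#' which are recorded as the per-pair ground truth. Produces
#' `n_time_experiments` time-course experiments plus one tissue and one
#' promoter-activity source.
#'
#' @param config A [generator_config()].
#' @param interactome The [generate_interactome()] output (genes =
#'   proteins).
#' @return List of [expression_experiment()]s with attribute
#'   `"ground_truth"`: per-gene `loading` and `mu`, and per-PPI
#'   `target_r` and `offset`.
#' @export
generate_expression <- function(config, interactome) {
  set.seed(.sub_seed(config$seed, 2L))
  genes <- names(interactome$sequences)
  ng <- length(genes)
  lambda <- stats::runif(ng)
  mu <- stats::rnorm(ng, mean = 2, sd = config$abundance_sd)
  names(lambda) <- names(mu) <- genes

  one_experiment <- function(id, kind, n_cond, labels) {
    f <- stats::rnorm(n_cond)
    eps <- matrix(stats::rnorm(ng * n_cond), ng, n_cond)
    z <- mu + config$expr_noise_sd *
      (outer(lambda, f) + sqrt(1 - lambda^2) * eps)
    m <- 10^z
    rownames(m) <- genes
    colnames(m) <- labels
    expression_experiment(id, kind, m, labels)
  }
  n_pts <- sample(seq(config$time_points_range[1],
                      config$time_points_range[2]),
                  config$n_time_experiments, replace = TRUE)
  experiments <- c(
    lapply(seq_len(config$n_time_experiments), function(i)
      one_experiment(sprintf("tc%02d", i), "time_course", n_pts[i],
                     paste0("t", seq_len(n_pts[i])))),
    list(one_experiment("tissue", "tissue", config$n_tissues,
                        paste0("tissue", seq_len(config$n_tissues))),
         one_experiment("promoter", "promoter", config$n_promoter_samples,
                        paste0("sample", seq_len(config$n_promoter_samples)))))
  pa <- vapply(interactome$ppis, `[[`, character(1), "partner_a")
  pb <- vapply(interactome$ppis, `[[`, character(1), "partner_b")
  attr(experiments, "ground_truth") <- list(
    loading = lambda, mu = mu,
    pairs = data.frame(ppi_id = names(interactome$ppis),
                       target_r = unname(lambda[pa] * lambda[pb]),
                       offset = unname(mu[pa] - mu[pb]),
                       stringsAsFactors = FALSE))
  experiments
}

#' Generate synthetic mutation cohorts with known ground truth
#'
#' Each mutation disrupts a weak (transient-group) PPI with its class's
#' ground-truth probability: disrupters are placed on the interface of a
#' randomly chosen weak PPI and given a binding-energy change drawn
#' above the 0.5 kcal/mol cutoff; the remaining interfacial mutations
#' (up to the class's interfacial fraction) get changes drawn at or
#' below the cutoff; all other mutations sit outside every interface.
#' Positions shared between several interfaces receive explicit
#' non-disrupting changes for the untargeted PPIs, so the realized
#' disruption set is exactly the intended one. ddG draws are normals
#' truncated at zero (destabilizing only) with the class means of the
#' configuration.
#'
#' @param config A [generator_config()].
#' @param interactome The [generate_interactome()] output.
#' @return List with `mutations` (one data frame, common + disease),
#'   `effects` (ddG table, see [read_ddg_tsv()]) and `ground_truth`
#'   (intended per-mutation disruption sets, the class rates, and the
#'   analytic dispensable content implied by the rates and default
#'   priors).
#' @export
generate_mutations <- function(config, interactome) {
  set.seed(.sub_seed(config$seed, 3L))
  seqs <- interactome$sequences
  ppis <- interactome$ppis
  dg <- vapply(ppis, `[[`, numeric(1), "delta_g")
  weak_ids <- names(ppis)[classify_strength(dg) == "weak"]
  if (!length(weak_ids)) stop("no weak PPIs to target")

  # interface membership lookup: protein -> (ppi, position) table
  iface <- do.call(rbind, lapply(ppis, function(p) rbind(
    if (length(p$interface_a))
      data.frame(protein_id = p$partner_a, ppi_id = p$id,
                 position = p$interface_a, stringsAsFactors = FALSE),
    if (length(p$interface_b))
      data.frame(protein_id = p$partner_b, ppi_id = p$id,
                 position = p$interface_b, stringsAsFactors = FALSE))))
  iface_key <- paste(iface$protein_id, iface$position, sep = "\r")

  rtrunc_ddg <- function(n, mean, lower, upper) {
    # zero-truncated normal, further conditioned to (lower, upper]
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      cand <- stats::rnorm(length(need), mean, config$ddg_sd)
      ok <- cand > max(0, lower) & cand <= upper
      out[need[ok]] <- cand[ok]
      need <- need[!ok]
    }
    out
  }

  iface_env <- new.env(parent = emptyenv())   # key -> ppi ids at position
  for (i in seq_len(nrow(iface))) {
    k <- iface_key[i]
    assign(k, c(if (exists(k, iface_env, inherits = FALSE))
      get(k, iface_env), iface$ppi_id[i]), iface_env)
  }

  make_class <- function(n, class, ifrac, rate, ddg_mean) {
    disrupt <- stats::runif(n) < rate
    n_iface <- round(ifrac * n)
    extra <- which(!disrupt)[sample.int(sum(!disrupt),
                                        max(0L, n_iface - sum(disrupt)))]
    is_iface <- disrupt
    is_iface[extra] <- TRUE
    prot <- character(n); pos <- integer(n); target <- rep(NA_character_, n)
    eff <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_iface[i]) {
        if (disrupt[i]) {
          tgt <- resample1(weak_ids)
          p <- ppis[[tgt]]
          side <- resample1(c("a", "b"))
          prot[i] <- p[[paste0("partner_", side)]]
          pos[i] <- resample1(p[[paste0("interface_", side)]])
          target[i] <- tgt
        } else {
          j <- sample.int(nrow(iface), 1L)
          prot[i] <- iface$protein_id[j]
          pos[i] <- iface$position[j]
        }
        hit <- get(paste(prot[i], pos[i], sep = "\r"), iface_env)
        ddg <- rtrunc_ddg(length(hit), ddg_mean, 0, 0.5)
        if (!is.na(target[i]))
          ddg[hit == target[i]] <- rtrunc_ddg(1L, ddg_mean, 0.5, Inf)
        eff[[i]] <- list(ppi_id = hit, ddg = ddg)
      } else {
        prot[i] <- resample1(names(seqs))
        repeat {
          pos[i] <- sample.int(nchar(seqs[[prot[i]]]), 1L)
          if (!exists(paste(prot[i], pos[i], sep = "\r"), iface_env,
                      inherits = FALSE)) break
        }
      }
    }
    wt <- unname(substr(seqs[prot], pos, pos))
    mut <- vapply(wt, function(w) resample1(setdiff(AA_ALPHABET[1:20], w)),
                  character(1), USE.NAMES = FALSE)
    n_eff <- vapply(eff, function(e) if (is.null(e)) 0L else
      length(e$ppi_id), integer(1))
    eidx <- rep.int(seq_len(n), n_eff)
    list(mutations = data.frame(
           protein_id = prot, position = pos, wt = wt, mut = mut,
           mclass = class,
           maf = if (class == "common") stats::runif(n, 0.01, 0.5) else
             NA_real_,
           stringsAsFactors = FALSE),
         effects = data.frame(
           protein_id = prot[eidx], position = pos[eidx], mut = mut[eidx],
           ppi_id = unlist(lapply(eff, `[[`, "ppi_id")),
           ddg = unlist(lapply(eff, `[[`, "ddg")),
           stringsAsFactors = FALSE),
         targets = target)
  }
  com <- make_class(config$n_common, "common",
                    config$interfacial_fraction_common,
                    config$true_disrupt_rate_common, config$ddg_mean_common)
  dis <- make_class(config$n_disease, "disease",
                    config$interfacial_fraction_disease,
                    config$true_disrupt_rate_disease,
                    config$ddg_mean_disease)

  mutations <- rbind(com$mutations, dis$mutations)
  rownames(mutations) <- NULL
  effects <- rbind(com$effects, dis$effects)
  rownames(effects) <- NULL
  truth_sets <- as.list(c(com$targets, dis$targets))
  truth_sets <- lapply(truth_sets, function(t)
    if (is.na(t)) character() else t)
  rc <- config$true_disrupt_rate_common
  rd <- config$true_disrupt_rate_disease
  priors <- prior_set()
  list(mutations = validate_mutations(mutations),
       effects = effects,
       ground_truth = list(
         disrupt_sets = truth_sets,
         rate_common = rc, rate_disease = rd,
         analytic_p_n_given_t =
           1 / (1 + (priors[["M"]] / priors[["N"]]) * (rd / rc))))
}

# sample() misbehaves on length-1 vectors; this does not
resample1 <- function(x) x[sample.int(length(x), 1L)]

#' Simulate Table-1-style counts at known disruption rates
#'
#' Count-level cohort simulation for estimator parameter-recovery
#' studies: each mutation independently disrupts a transient-group PPI
#' with its class's rate (per-mutation Bernoulli draws, so the realized
#' counts are binomial).
#'
#' @param n_common,n_disease Cohort sizes.
#' @param rate_common,rate_disease Ground-truth per-class disruption
#'   probabilities.
#' @return One-row count data frame consumable by [rates_from_counts()].
#' @export
simulate_edgotype_counts <- function(n_common, n_disease,
                                     rate_common, rate_disease) {
  data.frame(property = "synthetic",
             common_total = n_common,
             common_disrupt_T = sum(stats::runif(n_common) < rate_common),
             common_disrupt_P = NA_real_,
             disease_total = n_disease,
             disease_disrupt_T = sum(stats::runif(n_disease) < rate_disease),
             disease_disrupt_P = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate the complete synthetic input bundle
#'
#' @param config A [generator_config()].
#' @param coordinates Attach toy coordinates to the interactome?
#' @return List with `interactome`, `experiments`, `mutations`,
#'   `effects`, `ground_truth` and the `config`.
#' @export
generate_bundle <- function(config = generator_config(),
                            coordinates = FALSE) {
  net <- generate_interactome(config, coordinates = coordinates)
  experiments <- generate_expression(config, net)
  muts <- generate_mutations(config, net)
  list(interactome = net, experiments = experiments,
       mutations = muts$mutations, effects = muts$effects,
       ground_truth = c(muts$ground_truth,
                        list(expression = attr(experiments, "ground_truth"))),
       config = config)
}

#' Write a synthetic bundle to its external file formats
#'
#' Interactome as TSV + FASTA, mutations and ddG effects as TSV,
#' expression experiments as TSV with a manifest.
#'
#' @param bundle From [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactome_tsv(bundle$interactome, file.path(dir, "ppis.tsv"))
  write_fasta_proteins(bundle$interactome, file.path(dir, "proteins.fasta"))
  write_mutations_tsv(bundle$mutations, file.path(dir, "mutations.tsv"))
  write_ddg_tsv(bundle$effects, file.path(dir, "ddg.tsv"))
  write_expression_bundle(bundle$experiments, file.path(dir, "expression"))
  invisible(dir)
}

#' Read a synthetic bundle back from disk
#' @param dir Directory written by [write_bundle()].
#' @return List with `interactome`, `experiments`, `mutations`, `effects`.
#' @export
read_bundle <- function(dir) {
  list(interactome = read_interactome_tsv(file.path(dir, "ppis.tsv"),
                                          file.path(dir, "proteins.fasta")),
       experiments = read_expression_bundle(file.path(dir, "expression")),
       mutations = read_mutations_tsv(file.path(dir, "mutations.tsv")),
       effects = read_ddg_tsv(file.path(dir, "ddg.tsv")))
}
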