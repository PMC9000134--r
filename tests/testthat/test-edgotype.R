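# edgotype prediction and Table-1-style tabulation

test_that("the disruption rule is strict in ddG and gated by the interface", {
  eff <- data.frame(mutation_row = 1:3, ppi_id = c("p1", "p2", "p3"),
                    ddg = c(0.5, 0.51, 5.0),
                    on_interface = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  calls <- predict_disruptions(eff)
  expect_identical(calls$disrupted, c(FALSE, TRUE, FALSE))
  # missing ddG on an interfacial pair: undisrupted, flagged incomplete
  eff$ddg[2] <- NA
  calls <- predict_disruptions(eff)
  expect_identical(calls$disrupted, c(FALSE, FALSE, FALSE))
  expect_identical(calls$incomplete, c(FALSE, TRUE, FALSE))
})

test_that("edgotype labels follow the disruption count", {
  mk <- function(disrupted) data.frame(disrupted = disrupted)
  expect_identical(assign_edgotype(mk(logical(0)))$label, "quasi_wild_type")
  one <- assign_edgotype(mk(c(TRUE, FALSE)))
  expect_identical(one$label, "edgetic")
  expect_true(one$mono_edgetic)
  three <- assign_edgotype(mk(rep(TRUE, 3)))
  expect_identical(three$label, "edgetic")
  expect_false(three$mono_edgetic)
})

# small labelled cohort used by the tabulation tests
tab_fixture <- function(seed = 31) {
  cfg <- generator_config(n_proteins = 70, n_ppis = 90, n_common = 150,
                          n_disease = 80, n_time_experiments = 5,
                          n_promoter_samples = 15,
                          true_disrupt_rate_common = 0.05,
                          true_disrupt_rate_disease = 0.15, seed = seed)
  net <- generate_interactome(cfg, coordinates = FALSE)
  muts <- generate_mutations(cfg, net)
  hits <- locate_interfacial(muts$mutations, net)
  calls <- predict_disruptions(attach_effects(muts$mutations, hits,
                                              muts$effects))
  dg <- vapply(net$ppis, `[[`, numeric(1), "delta_g")
  labels <- data.frame(ppi_id = names(net$ppis),
                       strength = classify_strength(dg),
                       stringsAsFactors = FALSE)
  list(net = net, mutations = muts$mutations, calls = calls, labels = labels)
}

test_that("tabulation equals an exhaustive per-mutation recount", {
  fx <- tab_fixture()
  tab <- tabulate_edgotypes(fx$mutations, fx$calls, fx$net, fx$labels,
                            "strength")
  lab <- setNames(fx$labels$strength, fx$labels$ppi_id)
  # brute-force recount
  slow <- c(common_total = 0, common_T = 0, common_P = 0,
            disease_total = 0, disease_T = 0, disease_P = 0)
  for (i in seq_len(nrow(fx$mutations))) {
    prot <- fx$mutations$protein_id[i]
    prot_ppis <- Filter(function(p) p$partner_a == prot || p$partner_b == prot,
                        fx$net$ppis)
    if (!length(prot_ppis)) next
    if (!any(lab[vapply(prot_ppis, `[[`, character(1), "id")] %in%
             c("weak", "strong"))) next
    cls <- fx$mutations$mclass[i]
    slow[paste0(cls, "_total")] <- slow[paste0(cls, "_total")] + 1
    mine <- fx$calls[fx$calls$mutation_row == i & fx$calls$disrupted, ]
    if (any(lab[mine$ppi_id] == "weak"))
      slow[paste0(cls, "_T")] <- slow[paste0(cls, "_T")] + 1
    if (any(lab[mine$ppi_id] == "strong"))
      slow[paste0(cls, "_P")] <- slow[paste0(cls, "_P")] + 1
  }
  expect_identical(tab$common_total, as.integer(slow["common_total"]))
  expect_identical(tab$common_disrupt_T, as.integer(slow["common_T"]))
  expect_identical(tab$common_disrupt_P, as.integer(slow["common_P"]))
  expect_identical(tab$disease_total, as.integer(slow["disease_total"]))
  expect_identical(tab$disease_disrupt_T, as.integer(slow["disease_T"]))
  expect_identical(tab$disease_disrupt_P, as.integer(slow["disease_P"]))
  # disrupt counts never exceed the number of edgetic mutations
  edg <- assign_edgotypes(fx$mutations, fx$calls)
  expect_lte(tab$common_disrupt_T + 0, sum(edg$label == "edgetic" &
                                             edg$mclass == "common"))
})

test_that("tabulation is invariant to mutation order", {
  fx <- tab_fixture(seed = 32)
  perm <- sample(nrow(fx$mutations))
  muts_p <- fx$mutations[perm, ]
  calls_p <- fx$calls
  calls_p$mutation_row <- match(calls_p$mutation_row, perm)
  t1 <- tabulate_edgotypes(fx$mutations, fx$calls, fx$net, fx$labels,
                           "strength")
  t2 <- tabulate_edgotypes(muts_p, calls_p, fx$net, fx$labels, "strength")
  expect_identical(t1[-1], t2[-1])
})

test_that("raising the ddG cutoff never increases a disrupt count", {
  fx <- tab_fixture(seed = 33)
  eff <- fx$calls[, c("mutation_row", "protein_id", "position", "mut",
                      "mclass", "ppi_id", "ddg")]
  prev <- NULL
  for (ct in c(0.5, 1, 2, 3)) {
    calls <- predict_disruptions(eff, ddg_cutoff = ct)
    tab <- tabulate_edgotypes(fx$mutations, calls, fx$net, fx$labels,
                              "strength")
    if (!is.null(prev)) {
      expect_lte(tab$common_disrupt_T, prev$common_disrupt_T)
      expect_lte(tab$common_disrupt_P, prev$common_disrupt_P)
      expect_lte(tab$disease_disrupt_T, prev$disease_disrupt_T)
      expect_lte(tab$disease_disrupt_P, prev$disease_disrupt_P)
    }
    prev <- tab
  }
})

test_that("the mono-edgetic variant counts single-PPI disrupters only", {
  labels <- data.frame(ppi_id = c("q1", "q2", "q3"),
                       strength = c("weak", "weak", "strong"),
                       stringsAsFactors = FALSE)
  seqs <- paste(rep("ACDEFGHIKL", 3), collapse = "")
  prots <- lapply(c("A", "B", "C", "D"), function(i) protein(i, seqs))
  net <- interactome(prots, list(ppi_record("A", "B", 1:5, 1:5, id = "q1"),
                                 ppi_record("A", "C", 1:5, 1:5, id = "q2"),
                                 ppi_record("A", "D", 8:9, 1:5, id = "q3")))
  muts <- rbind(mut_df("A", 1), mut_df("A", 2, mclass = "disease"))
  # mutation 1 disrupts q1+q2 (both weak); mutation 2 disrupts q1 only
  calls <- data.frame(mutation_row = c(1L, 1L, 2L),
                      ppi_id = c("q1", "q2", "q1"),
                      disrupted = TRUE, stringsAsFactors = FALSE)
  full <- tabulate_edgotypes(muts, calls, net, labels, "strength")
  mono <- tabulate_edgotypes(muts, calls, net, labels, "strength",
                             mono_edgetic = TRUE)
  expect_identical(full$common_disrupt_T, 1L)
  expect_identical(mono$common_disrupt_T, 0L)   # disrupts two weak PPIs
  expect_identical(mono$disease_disrupt_T, 1L)
})

test_that("an all-quiet cohort tabulates to zero disrupt cells", {
  fx <- tab_fixture(seed = 34)
  calls <- fx$calls
  calls$disrupted <- FALSE
  tab <- tabulate_edgotypes(fx$mutations, calls, fx$net, fx$labels,
                            "strength")
  expect_identical(tab$common_disrupt_T + tab$common_disrupt_P +
                     tab$disease_disrupt_T + tab$disease_disrupt_P, 0L)
  expect_error(tabulate_edgotypes(fx$mutations, calls, fx$net, fx$labels,
                                  "nope"), "unknown property")
})
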