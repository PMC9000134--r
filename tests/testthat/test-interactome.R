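# interactome data model, interface geometry, template annotation,
# mutual exclusivity

test_that("compute_interface handles boundary and trivial geometries", {
  a1 <- point_chain("A", matrix(c(0, 0, 0), 1))
  b_far <- point_chain("B", matrix(c(6, 0, 0), 1))
  out <- compute_interface(a1, b_far, 5)
  expect_identical(out$interface_a, integer())
  expect_identical(out$interface_b, integer())

  # distance exactly 5.0 is inclusive
  b_at5 <- point_chain("B", matrix(c(3, 4, 0), 1))
  out <- compute_interface(a1, b_at5, 5)
  expect_identical(out$interface_a, 1L)
  expect_identical(out$interface_b, 1L)
})

test_that("compute_interface matches the brute-force all-pairs oracle", {
  set.seed(11)
  for (i in 1:20) {
    ca <- random_chain("A", sample(3:12, 1))
    cb <- random_chain("B", sample(3:12, 1))
    cutoff <- runif(1, 2, 8)
    fast <- compute_interface(ca, cb, cutoff)
    slow <- oracle_interface(ca, cb, cutoff)
    expect_identical(fast$interface_a, as.integer(slow$interface_a))
    expect_identical(fast$interface_b, as.integer(slow$interface_b))
    # one side non-empty iff the other is
    expect_identical(length(fast$interface_a) > 0,
                     length(fast$interface_b) > 0)
  }
})

test_that("shrinking the cutoff never adds interface residues", {
  set.seed(12)
  for (i in 1:10) {
    ca <- random_chain("A", 8)
    cb <- random_chain("B", 8)
    cuts <- sort(runif(4, 1, 10), decreasing = TRUE)
    prev <- compute_interface(ca, cb, cuts[1])
    for (ct in cuts[-1]) {
      cur <- compute_interface(ca, cb, ct)
      expect_true(all(cur$interface_a %in% prev$interface_a))
      expect_true(all(cur$interface_b %in% prev$interface_b))
      prev <- cur
    }
  }
})

test_that("compute_interface rejects invalid input", {
  a <- point_chain("A", matrix(c(0, 0, 0), 1))
  expect_error(compute_interface(a, a, distance_cutoff = -1))
  expect_error(chain_structure("A", c(1, 1), list(matrix(0, 1, 3),
                                                  matrix(0, 1, 3))),
               "strictly increasing")
  expect_error(chain_structure("A", 1, list(matrix(numeric(), 0, 3))),
               "at least one atom")
})

test_that("template annotation applies the coverage rule inclusively", {
  ifc <- list(interface_a = 1:10, interface_b = 1:10)
  # residue_map covering exactly 5 of 10 interface residues on both sides
  half_map <- function(prot, chain) {
    m <- 1:10
    names(m) <- as.character(1:10)
    alignment_record(prot, chain, 1e-10, m[1:5])
  }
  full_map <- function(prot, chain, shift = 0L) {
    m <- (1:10) + shift
    names(m) <- as.character(1:10)
    alignment_record(prot, chain, 1e-10, m)
  }
  ann <- annotate_ppi_template(c("p1", "p2"), c("X", "Y"), ifc,
                               list(half_map("p1", "X"), half_map("p2", "Y")))
  expect_false(is.null(ann))  # 0.5 boundary inclusive

  # 4 of 10 on one side is below threshold
  m4 <- 1:4; names(m4) <- as.character(1:4)
  ann <- annotate_ppi_template(c("p1", "p2"), c("X", "Y"), ifc,
                               list(alignment_record("p1", "X", 1e-10, m4),
                                    half_map("p2", "Y")))
  expect_null(ann)

  # identity alignments: protein-coordinate interface equals chain interface
  ann <- annotate_ppi_template(c("p1", "p2"), c("X", "Y"), ifc,
                               list(full_map("p1", "X"), full_map("p2", "Y")))
  expect_identical(ann$interface_a, 1:10)
  expect_identical(ann$interface_b, 1:10)
  # re-expression via the residue map
  ann <- annotate_ppi_template(c("p1", "p2"), c("X", "Y"), ifc,
                               list(full_map("p1", "X"),
                                    full_map("p2", "Y", shift = 100L)))
  expect_identical(ann$interface_b, 101:110)

  # both partners aligning only to the same chain -> no annotation
  ann <- annotate_ppi_template(c("p1", "p2"), c("X", "Y"), ifc,
                               list(full_map("p1", "X"), full_map("p2", "X")))
  expect_null(ann)

  # E-value filter: hits above 1e-5 are discarded
  ann <- annotate_ppi_template(c("p1", "p2"), c("X", "Y"), ifc,
                               list(alignment_record("p1", "X", 1e-3,
                                                     full_map("p1", "X")$residue_map),
                                    full_map("p2", "Y")))
  expect_null(ann)
})

test_that("coverage threshold extremes annotate all or nothing", {
  ifc <- list(interface_a = 1:10, interface_b = 1:10)
  m1 <- c("3" = 3L)  # covers a single interface residue
  alns <- list(alignment_record("p1", "X", 0, m1),
               alignment_record("p2", "Y", 0, m1))
  expect_false(is.null(annotate_ppi_template(c("p1", "p2"), c("X", "Y"),
                                             ifc, alns,
                                             coverage_threshold = 0.01)))
  full <- 1:10; names(full) <- as.character(1:10)
  alns <- list(alignment_record("p1", "X", 0, full),
               alignment_record("p2", "Y", 0, full))
  expect_null(annotate_ppi_template(c("p1", "p2"), c("X", "Y"), ifc, alns,
                                    coverage_threshold = 1.01))
})

test_that("mutual exclusivity counts and bins follow interface overlap", {
  seqs <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  prots <- lapply(c("H", paste0("P", 1:6), "Q1", "Q2", "Q3"),
                  function(id) protein(id, seqs))
  # hub with 6 PPIs over an identical interface
  hub_ppis <- lapply(1:6, function(i)
    ppi_record("H", paste0("P", i), 1:8, 10:15))
  # 3 PPIs of one protein on disjoint interfaces
  disj <- lapply(1:3, function(i)
    ppi_record("Q1", c("Q2", "Q3", "P1")[i],
               seq(10 * i, 10 * i + 4), 30:35,
               id = paste0("D", i)))
  net <- interactome(prots, c(hub_ppis, disj))
  for (i in 1:6) {
    r <- count_mutually_exclusive(net, paste0("H:P", i))
    expect_identical(r$count, 5L)
    expect_identical(r$bin, ">=5")
  }
  for (i in 1:3) {
    r <- count_mutually_exclusive(net, paste0("D", i))
    expect_identical(r$count, 0L)
    expect_identical(r$bin, "0")
  }
})

test_that("a PPI with no neighbours reports bin 0 and relabeling is symmetric", {
  seqs <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  prots <- lapply(c("X", "Y", "Z"), function(id) protein(id, seqs))
  fwd <- interactome(prots, list(ppi_record("X", "Y", 1:5, 6:10),
                                 ppi_record("X", "Z", 1:5, 6:10)))
  rev <- interactome(prots, list(ppi_record("Y", "X", 6:10, 1:5,
                                            id = "X:Y"),
                                 ppi_record("X", "Z", 1:5, 6:10)))
  lone <- interactome(prots[1:2], list(ppi_record("X", "Y", 1:5, 6:10)))
  expect_identical(count_mutually_exclusive(lone, "X:Y")$bin, "0")
  expect_identical(count_mutually_exclusive(fwd, "X:Y")$count,
                   count_mutually_exclusive(rev, "X:Y")$count)
})

test_that("interactome validates partners, bounds and duplicates", {
  p <- protein("A", "ACDEF")
  q <- protein("B", "ACDEFGHIKL")
  expect_error(interactome(list(p), list(ppi_record("A", "B"))),
               "not among proteins")
  expect_error(interactome(list(p, q), list(ppi_record("A", "B", 1:9, 1:2))),
               "out of sequence bounds")
  # duplicate unordered pair collapses, first wins
  net <- interactome(list(p, q),
                     list(ppi_record("A", "B", 1:2, 1:2, id = "first"),
                          ppi_record("B", "A", 3:4, 3:4, id = "second")))
  expect_identical(names(net$ppis), "first")
  # homodimer allowed and flagged
  hd <- ppi_record("A", "A", 1:2, 3:4)
  expect_true(hd$homodimer)
})

test_that("protein constructor enforces the amino-acid alphabet", {
  expect_error(protein("p", "ACDZ"), "invalid residue")
  expect_silent(protein("p", "ACDX"))
})

test_that("PDB chains round-trip through the fixed-column format", {
  coords_a <- matrix(c(0, 0, 0, 1, 0, 0, 0.5, 1, 0), 3, 3, byrow = TRUE)
  lines <- c("HEADER    TOY",
             pdb_atom_line(1, "A", 1, 0, 0, 0),
             pdb_atom_line(2, "A", 1, 1, 0, 0),       # two atoms, residue 1
             pdb_atom_line(3, "A", 3, 0.5, 1, 0),
             pdb_atom_line(4, "B", 7, 10, 0, 0),
             "TER",
             "HETATM    5  O   HOH A 100      9.0   9.0   9.0",
             "ENDMDL",
             pdb_atom_line(6, "C", 1, 99, 99, 99),     # second model: ignored
             "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  chains <- read_pdb_chains(f)
  expect_setequal(names(chains), c("A", "B"))
  expect_identical(chains$A$positions, c(1L, 3L))
  expect_identical(sum(chains$A$res_index == 1L), 2L)  # both altloc-free atoms
  expect_equal(chains$B$coords, matrix(c(10, 0, 0), 1), ignore_attr = TRUE)
})

test_that("interactome TSV + FASTA round-trips", {
  net <- toy_interactome()
  dir <- withr::local_tempdir()
  write_interactome_tsv(net, file.path(dir, "ppis.tsv"))
  write_fasta_proteins(net, file.path(dir, "prot.fasta"))
  back <- read_interactome_tsv(file.path(dir, "ppis.tsv"),
                               file.path(dir, "prot.fasta"), name = "toy")
  expect_identical(back$sequences, net$sequences)
  expect_identical(names(back$ppis), names(net$ppis))
  for (id in names(net$ppis)) {
    expect_identical(back$ppis[[id]]$interface_a, net$ppis[[id]]$interface_a)
    expect_identical(back$ppis[[id]]$interface_b, net$ppis[[id]]$interface_b)
    expect_equal(back$ppis[[id]]$delta_g, net$ppis[[id]]$delta_g)
  }
})
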