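# Shared fixtures and independent oracles, built in code.

# single-atom-per-residue chain at given coordinates
point_chain <- function(chain_id, coords, positions = seq_len(nrow(coords))) {
  chain_structure(chain_id, positions,
                  lapply(seq_len(nrow(coords)), function(i)
                    coords[i, , drop = FALSE]))
}

# random toy chain: n_res residues, 1-3 atoms each, coords in a box
random_chain <- function(chain_id, n_res, box = 12) {
  atoms <- lapply(seq_len(n_res), function(i) {
    k <- sample(1:3, 1)
    matrix(stats::runif(3 * k, 0, box), ncol = 3)
  })
  chain_structure(chain_id, seq_len(n_res), atoms)
}

# brute-force all-atom-pairs interface oracle (loops, no vectorisation)
oracle_interface <- function(chain_a, chain_b, cutoff) {
  res_atoms <- function(ch) lapply(seq_along(ch$positions), function(i)
    ch$coords[ch$res_index == i, , drop = FALSE])
  aa <- res_atoms(chain_a)
  bb <- res_atoms(chain_b)
  min_dist <- function(m1, m2) {
    best <- Inf
    for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2)))
      best <- min(best, sqrt(sum((m1[i, ] - m2[j, ])^2)))
    best
  }
  ia <- ib <- logical(0)
  ia <- vapply(aa, function(m1) any(vapply(bb, function(m2)
    min_dist(m1, m2) <= cutoff, logical(1))), logical(1))
  ib <- vapply(bb, function(m2) any(vapply(aa, function(m1)
    min_dist(m1, m2) <= cutoff, logical(1))), logical(1))
  list(interface_a = chain_a$positions[ia], interface_b = chain_b$positions[ib])
}

# tiny interactome: one hub H bound to partners over a shared interface,
# plus isolated pairs
toy_interactome <- function(hub_partners = 3L, lone_pairs = 2L,
                            seq_len_ = 40L) {
  seqs <- function(n, prefix) {
    vapply(seq_len(n), function(i)
      paste(rep(c("A", "C", "D", "E"), length.out = seq_len_), collapse = ""),
      character(1))
  }
  ids <- c("H", paste0("B", seq_len(hub_partners)),
           paste0("L", seq_len(2 * lone_pairs)))
  prots <- lapply(ids, function(id)
    protein(id, paste(rep("ACDEFGHIKL", 4), collapse = "")))
  hub_ifc <- 5:10
  ppis <- lapply(seq_len(hub_partners), function(i)
    ppi_record("H", paste0("B", i), hub_ifc, 11:15))
  ppis <- c(ppis, lapply(seq_len(lone_pairs), function(i)
    ppi_record(paste0("L", 2 * i - 1), paste0("L", 2 * i), 1:6, 20:26)))
  interactome(prots, ppis, name = "toy")
}

# small mutation table helper
mut_df <- function(protein_id, position, wt = "A", mut = "V",
                   mclass = "common", maf = 0.05) {
  data.frame(protein_id = protein_id, position = position, wt = wt,
             mut = mut, mclass = mclass,
             maf = ifelse(mclass == "common", maf, NA_real_),
             stringsAsFactors = FALSE)
}

# fixed-column PDB ATOM line
pdb_atom_line <- function(serial, chain, resseq, x, y, z, name = " CA ",
                          resname = "ALA") {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, resname, chain, resseq, x, y, z)
}
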