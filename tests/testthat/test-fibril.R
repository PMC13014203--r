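test_that("native contacts follow the heavy-atom minimum-distance rule", {
  d <- withr::local_tempdir()
  # fully extended trace, 0.38 nm rise: every |i-j| >= 4 pair is far
  sp <- generator_spec(seed = 1,
                       fibril_spec = list(EXT = data.frame(i = integer(0),
                                                           j = integer(0))))
  X <- cbind(0.38 * (0:19), 0, 0)
  f <- file.path(d, "ext.pdb")
  bio3d::write.pdb(file = f, xyz = as.vector(t(X)) * 10,
                   resno = 1:20, resid = rep("ALA", 20), eleno = 1:20,
                   elety = rep("CA", 20), chain = rep("A", 20),
                   elesy = rep("C", 20))
  ext <- extract_native_contacts(load_fibril_structure(f, "first"))
  expect_equal(nrow(ext$contacts), 0L)
  # compact random monomer against the brute-force oracle via the
  # one-frame-ensemble equivalence
  set.seed(21)
  Y <- matrix(stats::runif(14 * 3, 0, 1.1), ncol = 3)
  f2 <- file.path(d, "cmp.pdb")
  bio3d::write.pdb(file = f2, xyz = as.vector(t(Y)) * 10,
                   resno = 1:14, resid = rep("GLY", 14), eleno = 1:14,
                   elety = rep("CA", 14), chain = rep("A", 14),
                   elesy = rep("C", 14))
  nat <- extract_native_contacts(load_fibril_structure(f2, "first"))
  ens <- make_ensemble_from_coords(Y)
  cm <- compute_contact_map(ens)
  expect_equal(nat$contacts$i_full, cm$pairs$i)
  expect_equal(nat$contacts$j_full, cm$pairs$j)
  expect_equal(oracle_contact_map(ens)[cbind(nat$contacts$i_full,
                                             nat$contacts$j_full)],
               rep(1, nrow(nat$contacts)))
})

test_that("per-residue minimum distance governs contacts, not single atoms", {
  # two 'residues' whose closest atoms are side-chain-like extras at 0.40 nm
  # while their first atoms sit 0.48 nm apart
  top <- make_multiatom_topology(c(2L, 1L, 1L, 1L, 2L))
  coords <- rbind(c(0, 0, 0), c(0.02, 0, 0),      # residue 1
                  c(2, 0, 0), c(4, 0, 0), c(6, 0, 0),
                  c(0.5, 0, 0), c(0.42, 0, 0))    # residue 5, atom at 0.40
  arr <- array(coords, c(nrow(coords), 3L, 1L))
  ens <- fib_ensemble(top, arr)
  cm <- compute_contact_map(ens, cutoff = 0.45)
  expect_equal(cm$pairs[cm$pairs$i == 1 & cm$pairs$j == 5, "p"], 1.0)
})

test_that("mmCIF and PDB renderings give identical contact sets", {
  d <- withr::local_tempdir()
  set.seed(8)
  X <- matrix(stats::runif(12 * 3, 0, 1.0), ncol = 3)
  fp <- file.path(d, "m.pdb"); fc <- file.path(d, "m.cif")
  bio3d::write.pdb(file = fp, xyz = as.vector(t(X)) * 10,
                   resno = 1:12, resid = rep("ALA", 12), eleno = 1:12,
                   elety = rep("CA", 12), chain = rep("A", 12),
                   elesy = rep("C", 12))
  write_cif_trace(X, fc)
  a <- extract_native_contacts(load_fibril_structure(fp, "first"))
  b <- extract_native_contacts(load_fibril_structure(fc, "first"))
  expect_equal(a$contacts, b$contacts)
})

test_that("chain policies select monomers as documented", {
  d <- withr::local_tempdir()
  set.seed(31)
  X <- matrix(stats::runif(10 * 3, 0, 0.9), ncol = 3)
  # two identical chains stacked 0.9 nm apart along z (a protofilament stack)
  f <- file.path(d, "stack.pdb")
  bio3d::write.pdb(file = f,
                   xyz = as.vector(t(rbind(X, sweep(X, 2, c(0, 0, 0.9), "+")))) * 10,
                   resno = rep(1:10, 2), resid = rep("ALA", 20),
                   eleno = 1:20, elety = rep("CA", 20),
                   chain = rep(c("A", "B"), each = 10), elesy = rep("C", 20))
  ca <- extract_native_contacts(load_fibril_structure(f, "central"))
  cf <- extract_native_contacts(load_fibril_structure(f, "first"))
  expect_equal(ca$contacts, cf$contacts)
  ex <- load_fibril_structure(f, "explicit", chain_id = "B")
  expect_equal(ex$source_chain, "B")
  expect_error(load_fibril_structure(f, "explicit", chain_id = "Z"),
               class = "fibmod_empty_structure_error")
})

test_that("renumber offsets express contacts in full-length numbering", {
  d <- withr::local_tempdir()
  # residue 6 sits 0.3 nm from residue 1 and > 0.45 nm from everything else
  X <- rbind(c(0, 0, 0), c(0.7, 0, 0), c(1.4, 0, 0), c(2.1, 0, 0),
             c(2.8, 0, 0), c(0, 0.3, 0))
  f <- file.path(d, "off.pdb")
  bio3d::write.pdb(file = f, xyz = as.vector(t(X)) * 10,
                   resno = 1:6, resid = rep("ALA", 6), eleno = 1:6,
                   elety = rep("CA", 6), chain = rep("A", 6),
                   elesy = rep("C", 6))
  nat <- extract_native_contacts(
    load_fibril_structure(f, "first", renumber_offset = 243L))
  expect_equal(nat$contacts$i_full, 244L)
  expect_equal(nat$contacts$j_full, 249L)
})

test_that("clustering by shared contacts recovers designed blocks", {
  mk <- function(id, pairs) native_contact_set(id, pairs)
  s1 <- mk("a", data.frame(i = c(1, 5), j = c(7, 11)))
  s2 <- mk("b", data.frame(i = c(1, 20), j = c(7, 26)))
  cl <- cluster_fibrils(list(s1, s2))
  expect_equal(cl$clusters, list(c("a", "b")))
  # pairwise-disjoint contacts: all singletons, with a warning
  t1 <- mk("x", data.frame(i = 1, j = 7))
  t2 <- mk("y", data.frame(i = 2, j = 8))
  t3 <- mk("z", data.frame(i = 3, j = 9))
  expect_warning(cl3 <- cluster_fibrils(list(t1, t2, t3)),
                 "singletons")
  expect_equal(lengths(cl3$clusters), rep(1L, 3))
  # designed 9-structure block set, generated as PDB files end to end
  dirn <- withr::local_tempdir()
  man <- generate_fibril_set(generator_spec(seed = 2), dirn)
  res <- load_fibril_manifest(file.path(dirn, "manifest.tsv"))
  expect_equal(lengths(res$clustering$clusters), c(3L, 2L, 1L, 1L, 1L, 1L))
  expect_equal(res$clustering$clusters[[1]], c("A", "B", "C"))
  expect_equal(res$clustering$clusters[[2]], c("D", "E"))
})

test_that("clustering is invariant to input order and stricter rules only split", {
  dirn <- withr::local_tempdir()
  generate_fibril_set(generator_spec(seed = 3), dirn)
  res <- load_fibril_manifest(file.path(dirn, "manifest.tsv"))
  sets <- res$contact_sets
  ref <- cluster_fibrils(sets)
  set.seed(4)
  for (rep in 1:5) {
    shuf <- sample(length(sets))
    expect_equal(cluster_fibrils(sets[shuf])$clusters, ref$clusters)
  }
  for (ms in 1:4) {
    n1 <- length(cluster_fibrils(sets, min_shared = ms)$clusters)
    n2 <- length(cluster_fibrils(sets, min_shared = ms + 1L)$clusters)
    expect_lte(n1, n2)
  }
  # Jaccard edge rule at a permissive threshold reproduces the blocks
  expect_equal(cluster_fibrils(sets, min_jaccard = 0.1)$clusters,
               ref$clusters)
})
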