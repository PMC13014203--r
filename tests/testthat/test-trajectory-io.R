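test_that("loading skips equilibration frames and is idempotent", {
  sp <- generator_spec(seed = 11, chain_length = 8, n_frames = 10)
  ens <- generate_ensemble(sp, ratio = 0)
  d <- withr::local_tempdir()
  write_ensemble(ens, file.path(d, "traj.pdb"), file.path(d, "top.json"))
  got <- load_ensemble(file.path(d, "top.json"), file.path(d, "traj.pdb"),
                       skip_frames = 4)
  expect_equal(n_frames(got), 6L)
  a <- load_ensemble(file.path(d, "top.json"), file.path(d, "traj.pdb"))
  b <- load_ensemble(file.path(d, "top.json"), file.path(d, "traj.pdb"))
  expect_identical(a$coords, b$coords)
  expect_identical(a$topology$atoms, b$topology$atoms)
})

test_that("multi-model PDB coordinates are converted from Angstrom to nm", {
  d <- withr::local_tempdir()
  pdb <- file.path(d, "t.pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       1.500   2.500   3.500  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       4.500   5.500   6.500  1.00  0.00           C",
    "ENDMDL", "END"), pdb)
  ens <- load_ensemble(pdb, pdb, skip_frames = 0)
  expect_equal(n_frames(ens), 2L)
  expect_equal(ens$coords[1, , 1], c(1, 2, 3) / 10)
  expect_equal(ens$coords[2, , 2], c(4.5, 5.5, 6.5) / 10)
})

test_that("ensembles round-trip through PDB and TSV within precision", {
  sp <- generator_spec(seed = 12, chain_length = 10, n_frames = 5,
                       binding_spec = data.frame(residue = 3, k_on = 1,
                                                 k_off = 1))
  ens <- generate_ensemble(sp, ratio = 1)
  d <- withr::local_tempdir()
  write_ensemble(ens, file.path(d, "traj.pdb"), file.path(d, "top.json"))
  got <- load_ensemble(file.path(d, "top.json"), file.path(d, "traj.pdb"))
  expect_lt(max(abs(got$coords - ens$coords)), 1e-3)
  expect_equal(got$box[, , 1], ens$box[, , 1], tolerance = 1e-3)
  write_ensemble(ens, file.path(d, "traj.tsv"))
  got2 <- load_ensemble(file.path(d, "top.json"), file.path(d, "traj.tsv"))
  expect_lt(max(abs(got2$coords - ens$coords)), 1e-9)
})

test_that("atom-count mismatches raise topology errors", {
  sp <- generator_spec(seed = 13, chain_length = 6, n_frames = 3)
  ens <- generate_ensemble(sp, ratio = 0)
  d <- withr::local_tempdir()
  write_ensemble(ens, file.path(d, "traj.pdb"))
  # a topology that declares one atom more than the trajectory holds
  atoms <- ens$topology$atoms
  atoms <- rbind(atoms, data.frame(atom_id = 99L, name = "CA", element = "C",
                                   role = "protein", mol = 7L,
                                   resname = "ALA", chain = "A"))
  write_topology_json(fib_topology(atoms), file.path(d, "bad.json"))
  expect_error(load_ensemble(file.path(d, "bad.json"), file.path(d, "traj.pdb")),
               class = "fibmod_topology_error")
  expect_error(load_ensemble(file.path(d, "nope.json"), file.path(d, "traj.pdb")),
               class = "fibmod_io_error")
})

test_that("hydrogens are dropped at topology construction", {
  atoms <- data.frame(atom_id = 1:4, name = c("CA", "HA", "CA", "H1"),
                      element = c("C", "H", "C", "H"),
                      role = "protein", mol = c(1L, 1L, 2L, 2L),
                      resname = "ALA", chain = "A")
  top <- fib_topology(atoms)
  expect_equal(nrow(top$atoms), 2L)
  expect_true(all(top$atoms$element == "C"))
})

test_that("periodic-image QC flags exactly the frames the 26-image oracle flags", {
  # compact chain far from its images
  X <- cbind(seq(0, 0.9, length.out = 6), 0, 0) + 4
  ens <- make_ensemble_from_coords(X, n_frames = 2,
                                   box = diag(rep(8, 3)))
  qc <- periodic_image_violation_fraction(ens, 0.3)
  expect_equal(qc$fraction, 0)
  # chain spanning nearly the whole box along x: forced violation
  Y <- cbind(seq(0.05, 7.95, length.out = 12), 4, 4)
  ens2 <- make_ensemble_from_coords(Y, n_frames = 2, box = diag(rep(8, 3)))
  expect_equal(periodic_image_violation_fraction(ens2, 0.3)$fraction, 1)
  # random ensembles against the brute-force image enumeration
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(3:6, 1)
    coords <- array(stats::runif(n * 3 * 4, 0, 2.4), c(n, 3, 4))
    ens3 <- fib_ensemble(make_bead_topology(n), coords,
                         box = diag(rep(2.5, 3)))
    thr <- stats::runif(1, 0.2, 1.0)
    expect_equal(periodic_image_violation_fraction(ens3, thr)$flags,
                 oracle_image_flags(ens3, thr))
  }
  ens_nobox <- make_ensemble_from_coords(X, n_frames = 1)
  expect_error(periodic_image_violation_fraction(ens_nobox),
               class = "fibmod_qc_error")
})

test_that("QC frame exclusion leaves retained per-frame values untouched", {
  sp <- generator_spec(seed = 14, chain_length = 10, n_frames = 20)
  ens <- generate_ensemble(sp, ratio = 0)
  rg_all <- radius_of_gyration(ens, weighting = "uniform")$series
  keep <- c(1:7, 12:20)
  sub <- subset_frames(ens, keep)
  rg_sub <- radius_of_gyration(sub, weighting = "uniform")$series
  expect_identical(rg_sub, rg_all[keep])
})
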