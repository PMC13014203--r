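test_that("ligand count profiles count distinct molecules per residue", {
  # residues far apart; one ligand pinned 0.40 nm from residue 3
  X <- rbind(cbind(2 * (0:4), 0, 0), c(4, 0.4, 0))
  ens <- make_ensemble_from_coords(X, n_frames = 3, nlig = 1)
  bp <- ligand_count_profile(ens)
  expect_equal(bp$profile$n_ligand, c(0, 0, 1, 0, 0))
  # two ligands near residue 3 in half the frames, far otherwise: mean 1.0
  top <- make_bead_topology(5, nlig = 2)
  base <- rbind(cbind(2 * (0:4), 0, 0), c(4, 0.4, 0), c(4, -0.4, 0))
  far <- base; far[6:7, 1] <- 50
  arr <- array(NA_real_, c(7, 3, 4))
  for (f in 1:4) arr[, , f] <- if (f %% 2) base else far
  ens2 <- fib_ensemble(top, arr)
  expect_equal(ligand_count_profile(ens2)$profile$n_ligand[3], 1.0)
  expect_error(ligand_count_profile(make_ensemble_from_coords(X[1:5, ])),
               class = "fibmod_no_ligand_error")
})

test_that("ligand counts equal the brute-force triple loop on random instances", {
  for (seed in 1:6) {
    ens <- random_ensemble(200 + seed, n_res = sample(4:8, 1), max_atoms = 3L,
                           n_frames = 10L, nlig = sample(1:3, 1),
                           box_edge = if (seed %% 2) 2.0 else NULL)
    cutoff <- stats::runif(1, 0.3, 1.0)
    bp <- ligand_count_profile(ens, cutoff)
    oc <- oracle_ligand_counts(ens, cutoff)
    expect_equal(bp$profile$n_ligand, rowMeans(oc), tolerance = 1e-12)
  }
})

test_that("mediated contacts require the same ligand molecule to bridge", {
  # ligand permanently bridging residues 1 and 5 of a wide chain
  X <- rbind(cbind(c(0, 3, 6, 9, 1.0), 0, 0), c(0.5, 0, 0))
  ens <- make_ensemble_from_coords(X, n_frames = 2, nlig = 1)
  mm <- mediated_contact_map(ens, cutoff = 0.6)
  expect_equal(mm$pairs[mm$pairs$i == 1 & mm$pairs$j == 5, "p"], 1.0)
  # two residues near two DIFFERENT ligands never share one
  Y <- rbind(cbind(c(0, 3, 6, 9, 12), 0, 0), c(0.5, 0, 0), c(12.5, 0, 0))
  ens2 <- make_ensemble_from_coords(Y, n_frames = 2, nlig = 2)
  mm2 <- mediated_contact_map(ens2, cutoff = 0.6)
  expect_false(any(mm2$pairs$i == 1 & mm2$pairs$j == 5))
  # random instances vs the (i, ligand, j) brute force
  for (seed in 1:5) {
    ens3 <- random_ensemble(300 + seed, n_res = sample(5:8, 1), max_atoms = 2L,
                            n_frames = 8L, nlig = 2L)
    got <- mediated_contact_map(ens3, cutoff = 0.8)
    expect_equal(map_as_dense(got), oracle_mediated(ens3, cutoff = 0.8),
                 tolerance = 1e-12)
  }
})

test_that("single binding events are timed from entry to exit", {
  # ligand within r_on of residue 3 for frames 1..100, far afterwards
  nf <- 140L
  top <- make_bead_topology(5, nlig = 1)
  arr <- array(NA_real_, c(6, 3, nf))
  chain <- cbind(2 * (0:4), 0, 0)
  for (f in seq_len(nf)) {
    arr[1:5, , f] <- chain
    arr[6, , f] <- if (f <= 100) c(4, 0.4, 0) else c(30, 0, 0)
  }
  dt <- 0.25e-3  # 0.25 ps output cadence in ns
  ens <- fib_ensemble(top, arr, times = (seq_len(nf) - 1) * dt)
  rs <- residence_analysis(ens)
  expect_equal(rs$per_residue$n_events[3], 1L)
  expect_equal(rs$per_residue$mean_tau_residue[3], 100 * dt, tolerance = 1e-9)
  expect_equal(rs$per_residue$mean_tau_protein[3], 100 * dt, tolerance = 1e-9)
  expect_equal(rs$per_residue$exchange_rate[3], 1 / (nf * dt))
  # bound for the whole trajectory: censored, no completed events
  arr2 <- arr; for (f in seq_len(nf)) arr2[6, , f] <- c(4, 0.4, 0)
  expect_warning(
    rs2 <- residence_analysis(fib_ensemble(top, arr2,
                                           times = (seq_len(nf) - 1) * dt)),
    "censored")
  expect_equal(rs2$per_residue$n_events[3], 0L)
  expect_equal(rs2$per_residue$n_censored[3], 1L)
  expect_true(is.na(rs2$per_residue$mean_tau_residue[3]))
})

test_that("dead-zone excursions do not terminate binding events", {
  top <- make_bead_topology(5, nlig = 1)
  nf <- 6L
  arr <- array(NA_real_, c(6, 3, nf))
  chain <- cbind(2 * (0:4), 0, 0)
  dlig <- c(0.4, 0.5, 0.55, 0.4, 0.7, 0.7)  # dips into the dead zone
  for (f in seq_len(nf)) {
    arr[1:5, , f] <- chain
    arr[6, , f] <- c(4, dlig[f], 0)
  }
  rs <- residence_analysis(fib_ensemble(top, arr,
                                        times = (seq_len(nf) - 1) * 0.1))
  expect_equal(rs$per_residue$n_events[3], 1L)
  expect_equal(rs$per_residue$mean_tau_residue[3], 4 * 0.1, tolerance = 1e-9)
})

test_that("telegraph binding recovers the exponential dwell time", {
  sp <- generator_spec(seed = 77, chain_length = 8, n_frames = 20000,
                       frame_dt = 0.05,
                       binding_spec = data.frame(residue = 4, k_on = 1,
                                                 k_off = 0.5))
  ens <- generate_ensemble(sp, ratio = 1)
  rs <- residence_analysis(ens)
  tau <- rs$per_residue$mean_tau_residue[4]
  expect_gt(rs$per_residue$n_events[4], 250)
  expect_lt(abs(tau - 2) / 2, 0.1)
  # protein-level residence dominates per-residue residence
  done <- rs$events[!rs$events$censored & !is.na(rs$events$tau_protein), ]
  expect_true(all(done$tau_protein >= done$tau_residue - 1e-12))
  # completed events per residue are recoverable from the exchange rate
  n_back <- rs$per_residue$exchange_rate * rs$analyzed_time
  expect_equal(round(n_back), n_back, tolerance = 1e-9)
  expect_equal(as.integer(round(n_back)), rs$per_residue$n_events)
})
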