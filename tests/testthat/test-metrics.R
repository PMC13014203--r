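test_that("radius of gyration matches closed forms", {
  # all atoms coincident
  ens0 <- make_ensemble_from_coords(matrix(1, 5, 3), n_frames = 4)
  expect_equal(radius_of_gyration(ens0, "uniform")$series, rep(0, 4))
  # two equal-mass atoms 2 nm apart: R_g = d/2
  ens2 <- make_ensemble_from_coords(rbind(c(0, 0, 0), c(2, 0, 0)),
                                    n_frames = 4)
  expect_equal(radius_of_gyration(ens2, "uniform")$mean, 1, tolerance = 1e-12)
  # linear rod of n beads, spacing d: R_g = d sqrt((n^2 - 1)/12)
  n <- 7; d <- 0.4
  rod <- make_ensemble_from_coords(cbind(d * (0:(n - 1)), 0, 0), n_frames = 4)
  expect_equal(radius_of_gyration(rod, "uniform")$mean,
               d * sqrt((n^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(radius_of_gyration(rod, "uniform")$mean, 0.8, tolerance = 1e-12)
})

test_that("the four-block SEM matches the hand-computed value", {
  # per-frame R_g of a two-atom chain is half the pair distance
  dists <- c(1.0, 1.2, 0.8, 0.9, 1.4, 1.3, 0.7, 1.1)
  top <- make_bead_topology(2)
  arr <- array(0, c(2, 3, 8))
  arr[2, 1, ] <- dists
  rg <- radius_of_gyration(fib_ensemble(top, arr), weighting = "uniform",
                           n_blocks = 4)
  blocks <- c(mean(dists[1:2]), mean(dists[3:4]), mean(dists[5:6]),
              mean(dists[7:8])) / 2
  expect_equal(rg$series, dists / 2, tolerance = 1e-12)
  expect_equal(rg$mean, mean(dists) / 2, tolerance = 1e-12)
  expect_equal(rg$block_error, stats::sd(blocks) / sqrt(4), tolerance = 1e-12)
  expect_true(is.na(suppressWarnings(
    radius_of_gyration(subset_frames(fib_ensemble(top, arr), 1:3),
                       n_blocks = 4)$block_error)))
})

test_that("R_g is invariant to rigid rotation and translation", {
  ens <- random_ensemble(91, n_res = 8, max_atoms = 3, n_frames = 6)
  ref <- radius_of_gyration(ens)$series
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- ens
  for (f in 1:6)
    rot$coords[, , f] <- matrix(ens$coords[, , f], ncol = 3) %*% t(R) + 5
  expect_equal(radius_of_gyration(rot)$series, ref, tolerance = 1e-10)
})

test_that("R_g histograms integrate to one", {
  ens <- random_ensemble(92, n_res = 10, n_frames = 50)
  h <- radius_of_gyration(ens, "uniform")$histogram
  width <- diff(h$mid)[1]
  expect_equal(sum(h$density) * width, 1, tolerance = 1e-6)
})

test_that("the RDF of uniform uncorrelated selections is flat at one", {
  set.seed(93)
  nA <- 60; nB <- 60; nf <- 60; edge <- 6
  top <- make_bead_topology(nA, nlig = nB)
  coords <- array(stats::runif((nA + nB) * 3 * nf, 0, edge),
                  c(nA + nB, 3, nf))
  ens <- fib_ensemble(top, coords, box = diag(rep(edge, 3)))
  rdf <- radial_distribution(ens, bin_width = 0.1, r_max = 3)
  sel <- rdf$profile$r >= 1
  expect_lt(max(abs(rdf$profile$g[sel] - 1)), 0.05)
  # all ligand atoms farther than r_max in every frame: g is identically zero
  coords3 <- array(0.01, c(nA + nB, 3, 2))
  coords3[(nA + 1):(nA + nB), , ] <- edge / 2
  ens3 <- fib_ensemble(top, coords3, box = diag(rep(edge, 3)))
  rdf3 <- radial_distribution(ens3, bin_width = 0.1, r_max = 2.5)
  expect_true(all(rdf3$profile$g == 0))
  expect_error(radial_distribution(ens, bin_width = 0.1, r_max = 4),
               class = "fibmod_range_error")
})

test_that("RDF histograms equal brute-force pair binning on small instances", {
  set.seed(94)
  nA <- 5; nB <- 4; nf <- 3; edge <- 4
  top <- make_bead_topology(nA, nlig = nB)
  coords <- array(stats::runif((nA + nB) * 3 * nf, 0, edge),
                  c(nA + nB, 3, nf))
  ens <- fib_ensemble(top, coords, box = diag(rep(edge, 3)))
  bw <- 0.25; rmax <- 2
  rdf <- radial_distribution(ens, bin_width = bw, r_max = rmax)
  edges <- seq(0, rmax, by = bw)
  counts <- numeric(length(edges) - 1)
  for (f in 1:nf) for (a in 1:nA) for (b in 1:nB) {
    dd <- oracle_min_image_dist(coords[a, , f], coords[nA + b, , f],
                                rep(edge, 3))
    if (dd < rmax) counts[findInterval(dd, edges)] <-
        counts[findInterval(dd, edges)] + 1
  }
  shell <- 4 / 3 * pi * diff(edges^3)
  g_oracle <- counts * edge^3 / (nf * nA * nB * shell)
  expect_equal(rdf$profile$g, g_oracle, tolerance = 1e-10)
})

test_that("the Flory exponent is recovered from power-law distance profiles", {
  s <- 1:60
  for (nu in c(0.33, 0.5, 0.59, 1.0)) {
    fit <- flory_fit_profile(s, 0.55 * s^nu, prefactor = 0.55,
                             fit_range = c(5, 59))
    expect_equal(fit$nu, nu, tolerance = 1e-10)
    expect_lt(fit$residual, 1e-10)
  }
  # straight rod with 0.55 nm spacing: nu = 1 exactly
  rod <- make_ensemble_from_coords(cbind(0.55 * (0:29), 0, 0))
  expect_equal(flory_fit(rod)$nu, 1, tolerance = 1e-10)
})

test_that("Gaussian chains give the ideal-chain exponent", {
  set.seed(95)
  N <- 40; nf <- 2000
  sigma <- 0.55 / sqrt(3)
  steps <- array(stats::rnorm(N * 3 * nf, 0, sigma), c(N, 3, nf))
  coords <- apply(steps, c(2, 3), cumsum)
  ens <- fib_ensemble(make_bead_topology(N), coords)
  fit <- flory_fit(ens)
  expect_equal(fit$nu, 0.5, tolerance = 0.02)
})

test_that("secondary-structure fractions reduce codes correctly", {
  m <- matrix("E", nrow = 10, ncol = 4)
  ssf <- ss_fractions(m)
  expect_true(all(ssf$fractions$f_beta == 1))
  m2 <- matrix(rep(c("H", "C"), each = 5), nrow = 10, ncol = 3)
  ssf2 <- ss_fractions(m2)
  expect_true(all(ssf2$fractions$f_H == 0.5 & ssf2$fractions$f_C == 0.5))
  # random matrices against a counting oracle; rows always sum to 1
  set.seed(96)
  codes <- c("H", "G", "I", "E", "B", "T", "S", "C")
  m3 <- matrix(sample(codes, 200, replace = TRUE), nrow = 20)
  ssf3 <- ss_fractions(m3)
  for (r in seq_len(ncol(m3))) {
    expect_equal(ssf3$fractions$f_H[r],
                 mean(m3[, r] %in% c("H", "G", "I")))
    expect_equal(ssf3$fractions$f_beta[r], mean(m3[, r] %in% c("E", "B")))
  }
  sums <- with(ssf3$fractions, f_H + f_beta + f_C)
  expect_equal(sums, rep(1, ncol(m3)))
  expect_error(ss_fractions(matrix("Q", 2, 2)), class = "fibmod_mapping_error")
})

test_that("per-frame assignment strings round-trip through the reader", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ss.txt")
  writeLines(c("HHEEC", "CCEEH", "HHHHH"), f)
  m <- read_ss_assignments(f)
  expect_equal(dim(m), c(3L, 5L))
  expect_equal(m[2, ], c("C", "C", "E", "E", "H"))
  ssf <- ss_fractions(m)
  expect_equal(ssf$fractions$f_H[1], 2 / 3)
})
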