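mk_map <- function(ratio, pairs, nres = 12, nf = 1000) {
  contact_map(pairs, n_residues = nres, n_frames = nf,
              condition = ligand_condition(ratio))
}

test_that("slopes of exact linear occupancies are recovered to machine precision", {
  ratios <- c(0, 1, 5, 10)
  maps <- lapply(ratios, function(r)
    mk_map(r, data.frame(i = c(1, 3), j = c(6, 9),
                         p = c(0.2 + 0.01 * r, 0.5))))
  native <- native_contact_set("fib1", data.frame(i_full = c(1, 3),
                                                  j_full = c(6, 9)))
  mod <- modulation_coefficients(ratio_series(maps), native)
  expect_equal(mod$entries$k, c(0.01, 0), tolerance = 1e-12)
  expect_equal(mod$entries$intercept, c(0.2, 0.5), tolerance = 1e-12)
  expect_equal(mod$entries$r2[1], 1, tolerance = 1e-12)
  expect_true(is.na(mod$entries$r2[2]))   # flat series has no variance
  expect_equal(mod$entries$n_points, c(4L, 4L))
})

test_that("with two conditions the slope is exactly delta P over delta ratio", {
  set.seed(61)
  ij <- subset(expand.grid(i = 1:12, j = 1:12), j - i >= 4)
  sel <- ij[sample(nrow(ij), 10), ]
  p0 <- stats::runif(10); p5 <- stats::runif(10)
  m0 <- mk_map(0, data.frame(sel, p = p0))
  m5 <- mk_map(5, data.frame(sel, p = p5))
  native <- native_contact_set("fib", data.frame(i_full = sel$i,
                                                 j_full = sel$j))
  mod <- modulation_coefficients(ratio_series(list(m0, m5)), native)
  dl <- contact_delta(m5, m0)
  key <- paste(dl$pairs$i, dl$pairs$j)
  expect_equal(mod$entries$k,
               dl$pairs$delta[match(paste(mod$entries$i, mod$entries$j), key)] / 5,
               tolerance = 1e-14)
})

test_that("coefficients are invariant to condition order and scale affinely", {
  ratios <- c(0, 1, 5, 10)
  set.seed(62)
  ps <- stats::runif(4)
  maps <- lapply(seq_along(ratios), function(k)
    mk_map(ratios[k], data.frame(i = 2, j = 8, p = ps[k])))
  native <- native_contact_set("f", data.frame(i_full = 2, j_full = 8))
  k1 <- modulation_coefficients(ratio_series(maps), native)$entries$k
  k2 <- modulation_coefficients(ratio_series(maps[c(3, 1, 4, 2)]),
                                native)$entries$k
  expect_equal(k1, k2)
  expect_equal(k1, oracle_ols(ratios, ps))
  # scaling every ratio by c scales k by 1/c
  maps3 <- lapply(seq_along(ratios), function(k)
    mk_map(ratios[k] * 4, data.frame(i = 2, j = 8, p = ps[k])))
  k3 <- modulation_coefficients(ratio_series(maps3), native)$entries$k
  expect_equal(k3, k1 / 4, tolerance = 1e-12)
})

test_that("programmed linear occupancies are recovered within binomial error", {
  ratios <- c(0, 1, 5, 10)
  slopes <- c(-0.01, 0.01)
  pc <- data.frame(i = c(2, 14), j = c(9, 21), intercept = c(0.4, 0.3),
                   slope = slopes)
  sp <- generator_spec(seed = 63, chain_length = 24, n_frames = 800,
                       programmed_contacts = pc)
  maps <- lapply(ratios, function(r)
    compute_contact_map(generate_ensemble(sp, ratio = r)))
  native <- native_contact_set("design", data.frame(i_full = pc$i,
                                                    j_full = pc$j))
  mod <- modulation_coefficients(ratio_series(maps), native)
  xc <- ratios - mean(ratios)
  for (p in 1:2) {
    ptrue <- pc$intercept[p] + pc$slope[p] * ratios
    se <- sqrt(sum(xc^2 * ptrue * (1 - ptrue) / 800)) / sum(xc^2)
    expect_lt(abs(mod$entries$k[p] - slopes[p]), 3 * se)
  }
})

test_that("missing pairs count as zero probability, not missing data", {
  maps <- list(mk_map(0, data.frame(i = 1, j = 6, p = 0.4)),
               mk_map(10, data.frame(i = 2, j = 7, p = 0.4)))
  native <- native_contact_set("f", data.frame(i_full = 1, j_full = 6))
  mod <- modulation_coefficients(ratio_series(maps), native)
  expect_equal(mod$entries$k, (0 - 0.4) / 10)
})

test_that("series validation and range mapping guard the regression", {
  m <- mk_map(0, data.frame(i = 1, j = 6, p = 0.5))
  expect_error(ratio_series(list(m)), class = "fibmod_series_error")
  expect_error(ratio_series(list(m, m)), class = "fibmod_series_error")
  m2 <- mk_map(5, data.frame(i = 1, j = 6, p = 0.7))
  native_out <- native_contact_set("f", data.frame(i_full = 40, j_full = 50))
  expect_error(
    suppressWarnings(
      modulation_coefficients(ratio_series(list(m, m2)), native_out)),
    class = "fibmod_modulation_error")
  native_mix <- native_contact_set("f", data.frame(i_full = c(1, 40),
                                                   j_full = c(6, 50)))
  expect_warning(
    mod <- modulation_coefficients(ratio_series(list(m, m2)), native_mix),
    "dropped")
  expect_equal(nrow(mod$entries), 1L)
})

test_that("report classification matches element-wise thresholding", {
  ratios <- c(0, 10)
  set.seed(64)
  ij <- subset(expand.grid(i = 1:12, j = 1:12), j - i >= 4)
  sel <- ij[sample(nrow(ij), 15), ]
  p0 <- stats::runif(15, 0.2, 0.6)
  p1 <- p0 + stats::runif(15, -0.2, 0.2)
  maps <- list(mk_map(0, data.frame(sel, p = p0)),
               mk_map(10, data.frame(sel, p = p1)))
  native <- native_contact_set("f", data.frame(i_full = sel$i,
                                               j_full = sel$j))
  mod <- modulation_coefficients(ratio_series(maps), native)
  thr <- 0.005
  rep_ <- modulation_map_report(mod, sign_threshold = thr)
  want <- ifelse(mod$entries$k > thr, "promoted",
                 ifelse(mod$entries$k < -thr, "suppressed", "unchanged"))
  expect_equal(rep_$entries$class, want)
  expect_equal(as.integer(rep_$counts),
               as.integer(table(factor(want, c("promoted", "suppressed",
                                               "unchanged")))))
  regions <- data.frame(name = c("N", "C"), start = c(1, 7), end = c(6, 12))
  rep2 <- modulation_map_report(mod, thr, regions)
  expect_equal(nrow(rep2$region_counts), 2L)
  # all-zero slopes: everything unchanged
  flat <- lapply(ratios, function(r) mk_map(r, data.frame(i = 1, j = 6, p = 0.5)))
  modf <- modulation_coefficients(ratio_series(flat),
                                  native_contact_set("f", data.frame(i_full = 1,
                                                                     j_full = 6)))
  expect_equal(modulation_map_report(modf, 0.001)$entries$class, "unchanged")
})
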