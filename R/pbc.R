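# Periodic-boundary helpers.  Boxes are 3x3 matrices whose ROWS are the box
# vectors a1, a2, a3 in nm, in the reduced (lower-triangular) convention used
# by MD engines: a1 = (xx,0,0), a2 = (yx,yy,0), a3 = (zx,zy,zz).

.box_is_diag <- function(box) {
  all(abs(box[upper.tri(box)]) < 1e-12) && all(abs(box[lower.tri(box)]) < 1e-12)
}

# Minimum-image reduction of displacement vectors (n x 3 matrix) under a
# triclinic box: subtract rounded multiples of a3, then a2, then a1.  Valid
# for reduced boxes where each vector's off-diagonal components are at most
# half the corresponding diagonal.
.min_image_disp <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 3:1) {
    n <- round(d[, k] / box[k, k])
    if (any(n != 0)) d <- d - tcrossprod(n, box[k, ])
  }
  d
}

# squared distances between rows of X and rows of Y (no PBC); returns
# nrow(X) x nrow(Y) matrix; clamped at zero against round-off
.cross_dist2 <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

# per-pair minimum-image squared distances between rows of X and rows of Y
.cross_dist2_pbc <- function(X, Y, box) {
  if (is.null(box)) return(.cross_dist2(X, Y))
  if (.box_is_diag(box)) {
    L <- diag(box)
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(X[, k], Y[, k], "-")
      dk <- dk - L[k] * round(dk / L[k])
      d2 <- d2 + dk * dk
    }
    return(d2)
  }
  # general triclinic: reduce flattened displacement vectors
  nx <- nrow(X); ny <- nrow(Y)
  d <- cbind(rep(X[, 1], ny) - rep(Y[, 1], each = nx),
             rep(X[, 2], ny) - rep(Y[, 2], each = nx),
             rep(X[, 3], ny) - rep(Y[, 3], each = nx))
  d <- .min_image_disp(d, box)
  matrix(rowSums(d^2), nx, ny)
}

#' Fraction of frames violating the periodic-image distance check
#'
#' Quality control applied before ensemble analyses: a frame is flagged when
#' the minimum distance between any protein atom and any protein atom of a
#' neighbouring periodic image falls below `threshold`.  All 26 neighbour
#' images (the 3x3x3 cell block minus the central cell) are enumerated
#' explicitly.
#'
#' @param ensemble a [fib_ensemble].
#' @param threshold distance threshold in nm (default 0.3).
#' @return An object of class `fib_qc`: list with `fraction`, logical
#'   per-frame `flags`, `n_frames`, `n_violations`, `threshold_nm` and the
#'   per-frame minimum image distances `min_dist`.
#' @examples
#' sp <- generator_spec(seed = 1, chain_length = 10, n_frames = 5)
#' ens <- generate_ensemble(sp, ratio = 0)
#' qc <- periodic_image_violation_fraction(ens)
#' qc$fraction
#' @export
periodic_image_violation_fraction <- function(ensemble, threshold = 0.3) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  if (is.null(ensemble$box))
    .fib_err("periodic-image QC requires box vectors", "fibmod_qc_error")
  prot <- which(ensemble$topology$atoms$role == "protein")
  nf <- n_frames(ensemble)
  shifts_idx <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts_idx <- shifts_idx[rowSums(abs(shifts_idx)) > 0, , drop = FALSE]
  mind <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- matrix(ensemble$coords[prot, , f], ncol = 3L)
    box <- ensemble$box[, , f]
    S <- shifts_idx %*% box
    d2min <- Inf
    r2 <- rowSums(X^2)
    for (s in seq_len(nrow(S))) {
      Y <- sweep(X, 2, S[s, ], "+")
      d2 <- outer(r2, rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
      d2min <- min(d2min, d2)
    }
    mind[f] <- sqrt(max(d2min, 0))
  }
  flags <- mind < threshold
  structure(list(fraction = mean(flags), flags = flags, n_frames = nf,
                 n_violations = sum(flags), threshold_nm = threshold,
                 min_dist = mind),
            class = "fib_qc")
}

#' @export
print.fib_qc <- function(x, ...) {
  cat(sprintf("Periodic-image QC: %d/%d frames below %.2f nm (fraction %.4f)\n",
              x$n_violations, x$n_frames, x$threshold_nm, x$fraction))
  invisible(x)
}

#' Write a QC report as JSON
#' @param qc a `fib_qc` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_qc_json <- function(qc, file) {
  stopifnot(inherits(qc, "fib_qc"))
  jsonlite::write_json(list(n_frames = qc$n_frames,
                            n_violations = qc$n_violations,
                            fraction = qc$fraction,
                            threshold_nm = qc$threshold_nm),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Exclude QC-flagged frames from an ensemble
#'
#' Per-frame exclusion is the default downstream behaviour; set
#' `whole = TRUE` to reject the whole ensemble (error) when any frame is
#' flagged.
#'
#' @param ensemble a [fib_ensemble].
#' @param qc result of [periodic_image_violation_fraction()]; computed on the
#'   fly if `NULL`.
#' @param threshold nm, used when `qc` is `NULL`.
#' @param whole reject the whole ensemble instead of single frames.
#' @return the ensemble with flagged frames removed.
#' @export
exclude_qc_frames <- function(ensemble, qc = NULL, threshold = 0.3,
                              whole = FALSE) {
  if (is.null(qc)) qc <- periodic_image_violation_fraction(ensemble, threshold)
  if (whole && qc$n_violations > 0L)
    .fib_err("ensemble rejected: periodic-image violations present",
             "fibmod_qc_error")
  subset_frames(ensemble, !qc$flags)
}
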