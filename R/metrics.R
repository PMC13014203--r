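# Global chain metrics: radius of gyration with block-averaged errors,
# ligand radial distribution function, Flory scaling exponent and
# secondary-structure fraction aggregation.

#' Radius of gyration with block-averaged error
#'
#' Per-frame R_g over protein heavy atoms, mass-weighted by default
#' (uniform weighting suits single-bead synthetic chains); the error is the
#' standard error of the mean over `n_blocks` contiguous blocks, the standard
#' block-averaging estimate for correlated trajectories.
#'
#' @param ensemble a [fib_ensemble].
#' @param weighting `"mass"` or `"uniform"`.
#' @param n_blocks number of contiguous blocks (default 4).
#' @param breaks histogram breaks (passed to [hist()]).
#' @return object of class `fib_rg`: `series` (nm per frame), `mean`,
#'   `block_error` (`NA` with fewer frames than blocks), `histogram`
#'   data.frame (`mid, density`), `n_blocks`.
#' @export
radius_of_gyration <- function(ensemble, weighting = c("mass", "uniform"),
                               n_blocks = 4L, breaks = 30) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ensemble, "fib_ensemble"))
  top <- ensemble$topology
  prot <- which(top$atoms$role == "protein")
  w <- if (weighting == "mass") top$masses[prot] else rep(1, length(prot))
  w <- w / sum(w)
  nf <- n_frames(ensemble)
  rg <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- matrix(ensemble$coords[prot, , f], ncol = 3L)
    cm <- colSums(X * w)
    rg[f] <- sqrt(sum(w * rowSums(sweep(X, 2, cm)^2)))
  }
  block_error <- NA_real_
  if (nf >= n_blocks) {
    blk <- rep(seq_len(n_blocks), each = ceiling(nf / n_blocks))[seq_len(nf)]
    bm <- tapply(rg, blk, mean)
    block_error <- stats::sd(bm) / sqrt(n_blocks)
  } else {
    warning("fewer frames than blocks: block error unavailable")
  }
  h <- graphics::hist(rg, breaks = breaks, plot = FALSE)
  structure(list(series = rg, mean = mean(rg), block_error = block_error,
                 histogram = data.frame(mid = h$mids, density = h$density),
                 n_blocks = as.integer(n_blocks), weighting = weighting,
                 condition = ensemble$condition),
            class = "fib_rg")
}

#' @export
print.fib_rg <- function(x, ...) {
  cat(sprintf("Radius of gyration: %.3f +/- %s nm (%s-weighted, %d frames, %d blocks)\n",
              x$mean,
              if (is.na(x$block_error)) "NA" else sprintf("%.3f", x$block_error),
              x$weighting, length(x$series), x$n_blocks))
  invisible(x)
}

#' Protein-ligand radial distribution function
#'
#' g(r) between protein C-alpha atoms and ligand heavy atoms under the
#' minimum-image convention, normalised by shell volume, frame count, pair
#' count and the instantaneous box number density so that an uncorrelated
#' uniform system gives g(r) = 1.
#'
#' @param ensemble a [fib_ensemble] with box vectors and at least one ligand.
#' @param bin_width histogram bin width in nm.
#' @param r_max maximum distance in nm; must not exceed half the smallest box
#'   extent.
#' @return object of class `fib_rdf`: data.frame `profile` (`r, g`),
#'   `bin_width`, `r_max`, `selection`.
#' @export
radial_distribution <- function(ensemble, bin_width = 0.02, r_max = NULL) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  if (is.null(ensemble$box))
    .fib_err("radial distribution requires box vectors", "fibmod_range_error")
  top <- ensemble$topology
  ca <- .calpha_rows(top)
  if (anyNA(ca))
    .fib_err("every residue needs a CA atom for the RDF selection",
             "fibmod_topology_error")
  lig <- which(top$atoms$role == "ligand")
  if (!length(lig))
    .fib_err("ensemble declares no ligand molecules", "fibmod_no_ligand_error")
  half_min <- min(apply(ensemble$box, 3, function(b) min(diag(b)))) / 2
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9)
    .fib_err(sprintf("r_max (%.3g nm) exceeds half the smallest box extent (%.3g nm)",
                     r_max, half_min), "fibmod_range_error")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  nf <- n_frames(ensemble)
  nA <- length(ca); nB <- length(lig)
  for (f in seq_len(nf)) {
    box <- ensemble$box[, , f]
    V <- abs(det(box))
    d <- sqrt(.cross_dist2_pbc(matrix(ensemble$coords[ca, , f], ncol = 3L),
                               matrix(ensemble$coords[lig, , f], ncol = 3L), box))
    cnt <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)$counts
    acc <- acc + cnt * V
  }
  shell <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  g <- acc / (nf * nA * nB * shell)
  structure(list(profile = data.frame(r = (edges[-1L] + edges[-length(edges)]) / 2,
                                      g = g),
                 bin_width = bin_width, r_max = r_max,
                 selection = "protein CA vs ligand heavy atoms",
                 n_frames = nf, condition = ensemble$condition),
            class = "fib_rdf")
}

#' @export
print.fib_rdf <- function(x, ...) {
  cat(sprintf("RDF (%s): %d bins to %.2f nm, tail mean g = %.3f\n",
              x$selection, nrow(x$profile), x$r_max,
              mean(utils::tail(x$profile$g, 5))))
  invisible(x)
}

#' @export
plot.fib_rdf <- function(x, ...) {
  plot(x$profile$r, x$profile$g, type = "l", xlab = "r (nm)",
       ylab = "g(r)", main = x$selection, ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Flory scaling-exponent fit
#'
#' Root-mean-square C-alpha distances R(s) as a function of sequence
#' separation s = |i - j|, fitted to R(s) = b * s^nu with the prefactor b
#' held fixed (0.55 nm by default, the consensus literature value), so nu is
#' the single fitted parameter: least squares on
#' log(R(s)/b) = nu * log(s) over `fit_range`.  nu near 0.5 indicates
#' theta-solvent statistics, near 0.59 a good-solvent expanded coil, 1 a rod.
#'
#' @param ensemble a [fib_ensemble].
#' @param prefactor fixed prefactor in nm.
#' @param fit_range integer `(s_min, s_max)`; defaults to `(5, N-1)`, skipping
#'   local-stiffness separations.
#' @return object of class `fib_flory`: `nu`, `prefactor`, `rms`
#'   data.frame (`s, rms`), `fit_range`, `residual` (RMS of log-space fit).
#' @export
flory_fit <- function(ensemble, prefactor = 0.55, fit_range = NULL) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  ca <- .calpha_rows(ensemble$topology)
  if (anyNA(ca))
    .fib_err("every residue needs a CA atom for the Flory fit",
             "fibmod_topology_error")
  N <- length(ca)
  if (is.null(fit_range)) fit_range <- c(min(5L, N - 1L), N - 1L)
  if (N < fit_range[1] + 2L)
    .fib_err("chain too short for the requested fit range",
             "fibmod_parameter_error")
  svals <- seq_len(N - 1L)
  rms <- vapply(svals, function(s) {
    i <- seq_len(N - s)
    dd <- ensemble$coords[ca[i], , , drop = FALSE] -
          ensemble$coords[ca[i + s], , , drop = FALSE]
    sqrt(mean(dd[, 1, ]^2 + dd[, 2, ]^2 + dd[, 3, ]^2))
  }, numeric(1))
  flory_fit_profile(svals, rms, prefactor = prefactor, fit_range = fit_range)
}

#' @rdname flory_fit
#' @param s,rms a precomputed distance profile: sequence separations and the
#'   corresponding RMS distances (nm), for fitting published or synthetic
#'   profiles directly.
#' @export
flory_fit_profile <- function(s, rms, prefactor = 0.55, fit_range = NULL) {
  if (is.null(fit_range)) fit_range <- range(s)
  sel <- s >= fit_range[1] & s <= fit_range[2] & rms > 0
  if (sum(sel) < 1L)
    .fib_err("no separations inside the fit range", "fibmod_parameter_error")
  ls <- log(s[sel])
  y <- log(rms[sel] / prefactor)
  nu <- sum(ls * y) / sum(ls * ls)
  residual <- sqrt(mean((y - nu * ls)^2))
  structure(list(nu = nu, prefactor = prefactor,
                 rms = data.frame(s = s, rms = rms),
                 fit_range = fit_range, residual = residual),
            class = "fib_flory")
}

#' @export
print.fib_flory <- function(x, ...) {
  cat(sprintf("Flory fit: nu = %.3f (prefactor %.2f nm fixed, s in [%d, %d], RMS log-residual %.3g)\n",
              x$nu, x$prefactor, x$fit_range[1], x$fit_range[2], x$residual))
  invisible(x)
}

#' @export
coef.fib_flory <- function(object, ...) c(nu = object$nu)

#' @export
plot.fib_flory <- function(x, ...) {
  plot(x$rms$s, x$rms$rms, log = "xy", xlab = "sequence separation |i-j|",
       ylab = "RMS distance (nm)", pch = 16, cex = 0.6, ...)
  s <- x$rms$s
  graphics::lines(s, x$prefactor * s^x$nu, col = "#d62728")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("nu = %.3f", x$nu), text.col = "#d62728")
  invisible(x)
}

# conventional 3-state reduction of DSSP codes
.default_ss_grouping <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
                          T = "C", S = "C", C = "C", P = "C",
                          "~" = "C", "-" = "C", " " = "C", "=" = "C")

#' Aggregate per-frame secondary-structure assignments into fractions
#'
#' Consumes externally produced per-frame per-residue assignment codes (e.g.
#' DSSP letters) and reduces them to per-residue helix / sheet / coil
#' fractions under a code grouping (default: H,G,I to helix; E,B to sheet;
#' everything else coil).
#'
#' @param assignments character matrix (frames x residues) of single-letter
#'   codes, or a character vector of per-frame strings.
#' @param grouping named character vector mapping codes to `"H"`, `"E"` or
#'   `"C"`; codes absent from the grouping raise an error.
#' @param sequence_offset added to residue indices for reporting.
#' @return object of class `fib_ss`: data.frame `fractions`
#'   (`res, res_full, f_H, f_beta, f_C`), with rows summing to 1.
#' @export
ss_fractions <- function(assignments, grouping = NULL, sequence_offset = 0L) {
  if (is.null(grouping)) grouping <- .default_ss_grouping
  if (is.character(assignments) && is.null(dim(assignments))) {
    nch <- unique(nchar(assignments))
    if (length(nch) != 1L)
      .fib_err("per-frame assignment strings differ in length",
               "fibmod_format_error")
    assignments <- do.call(rbind, strsplit(assignments, ""))
  }
  codes <- unique(as.vector(assignments))
  unknown <- setdiff(codes, names(grouping))
  if (length(unknown))
    .fib_err(paste0("assignment code(s) without grouping entry: ",
                    paste(sQuote(unknown), collapse = ", ")),
             "fibmod_mapping_error")
  grp <- matrix(grouping[assignments], nrow = nrow(assignments))
  nr <- ncol(grp)
  frac <- t(vapply(seq_len(nr), function(r) {
    tab <- table(factor(grp[, r], levels = c("H", "E", "C")))
    as.numeric(tab) / nrow(grp)
  }, numeric(3)))
  structure(list(fractions = data.frame(res = seq_len(nr),
                                        res_full = seq_len(nr) + sequence_offset,
                                        f_H = frac[, 1], f_beta = frac[, 2],
                                        f_C = frac[, 3]),
                 grouping = grouping, n_frames = nrow(assignments)),
            class = "fib_ss")
}

#' @export
print.fib_ss <- function(x, ...) {
  cat(sprintf("Secondary-structure fractions: %d residues over %d frames; mean f_beta = %.3f\n",
              nrow(x$fractions), x$n_frames, mean(x$fractions$f_beta)))
  invisible(x)
}

#' Read per-frame secondary-structure assignments
#'
#' `format = "strings"`: one line per frame, one character per residue.
#' `format = "dssp"`: the classic DSSP text output (single structure; the
#' summary column at position 17), returned as a one-frame matrix.
#'
#' @param file input path.
#' @param format `"strings"` or `"dssp"`.
#' @return character matrix (frames x residues).
#' @export
read_ss_assignments <- function(file, format = c("strings", "dssp")) {
  format <- match.arg(format)
  lines <- readLines(file)
  if (format == "strings") {
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    return(do.call(rbind, strsplit(lines, "")))
  }
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr))
    .fib_err("not a DSSP output file (header row missing)",
             "fibmod_format_error")
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
  matrix(substr(body, 17, 17), nrow = 1L)
}

#' Write an R_g, RDF, Flory or secondary-structure result as annotated TSV
#' @param x a `fib_rg`, `fib_rdf`, `fib_flory` or `fib_ss` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_metric_tsv <- function(x, file) {
  if (inherits(x, "fib_rg")) {
    meta <- list(type = "radius_of_gyration", mean_nm = x$mean,
                 block_error_nm = x$block_error, n_blocks = x$n_blocks,
                 weighting = x$weighting)
    tab <- data.frame(frame = seq_along(x$series), rg = x$series)
  } else if (inherits(x, "fib_rdf")) {
    meta <- list(type = "radial_distribution", bin_width_nm = x$bin_width,
                 r_max_nm = x$r_max, selection = x$selection)
    tab <- x$profile
  } else if (inherits(x, "fib_flory")) {
    meta <- list(type = "flory_fit", nu = x$nu, prefactor_nm = x$prefactor,
                 fit_range = x$fit_range, residual = x$residual)
    tab <- x$rms
  } else if (inherits(x, "fib_ss")) {
    meta <- list(type = "ss_fractions", n_frames = x$n_frames,
                 grouping = paste0(names(x$grouping), ">", x$grouping))
    tab <- x$fractions
  } else .fib_err("unsupported object", "fibmod_format_error")
  writeLines(.header_lines(meta), file)
  suppressWarnings(
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(file)
}
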