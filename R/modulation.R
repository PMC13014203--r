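# Contact-modulation coefficients: the per-pair slope k_ij of contact
# probability against ligand:protein molar ratio, evaluated on fibril-native
# pairs.  Positive k_ij: the ligand promotes the fibril-like contact;
# negative: it suppresses it.

#' Bundle contact maps measured at several ligand ratios
#'
#' @param maps list of [compute_contact_map()] results, one per condition;
#'   all must share cutoff, separation floor and chain length, and at least
#'   two distinct ratio values are required.
#' @return object of class `fib_ratio_series`.
#' @export
ratio_series <- function(maps) {
  if (length(maps) < 2L)
    .fib_err("at least two conditions required", "fibmod_series_error")
  stopifnot(all(vapply(maps, inherits, logical(1), "fib_contact_map")))
  ratios <- vapply(maps, function(m) m$condition$ratio, numeric(1))
  if (length(unique(ratios)) < 2L)
    .fib_err("ratio values are all equal; regression undefined",
             "fibmod_series_error")
  ref <- maps[[1L]]
  same <- vapply(maps, function(m)
    m$cutoff == ref$cutoff && m$min_separation == ref$min_separation &&
      m$n_residues == ref$n_residues, logical(1))
  if (!all(same))
    .fib_err("all maps must share cutoff, min_separation and chain length",
             "fibmod_incompatible_maps_error")
  ord <- order(ratios)
  structure(list(maps = maps[ord], ratios = ratios[ord]),
            class = "fib_ratio_series")
}

#' Contact-modulation coefficients over a ligand-ratio series
#'
#' For each fibril-native residue pair, fits contact probability P_ij against
#' the numeric molar ratio by ordinary least squares; the slope k_ij
#' (probability per unit ratio) is the contact-modulation coefficient.  A
#' pair absent from a sparse map contributes P_ij = 0 at that condition --
#' absence means no frames in contact, a real observation, not missing data.
#'
#' @param series a [ratio_series()].
#' @param native a [extract_native_contacts()] result (full-length
#'   numbering); pairs outside the simulated construct's range after offset
#'   mapping are dropped with a warning.
#' @param weights `"none"` (default) for unweighted OLS or `"frames"` to
#'   weight conditions by their frame counts.
#' @return object of class `fib_modulation`: `entries` data.frame
#'   (`i, j, i_full, j_full, k, intercept, r2, n_points`), `native_source`,
#'   `ratios`, and the shared map metadata.
#' @examples
#' maps <- lapply(c(0, 1, 5, 10), function(r)
#'   contact_map(data.frame(i = 1, j = 6, p = 0.2 + 0.01 * r), n_residues = 10,
#'               condition = ligand_condition(r)))
#' native <- native_contact_set("demo", data.frame(i_full = 1, j_full = 6))
#' modulation_coefficients(ratio_series(maps), native)$entries$k  # 0.01
#' @export
modulation_coefficients <- function(series, native, weights = c("none", "frames")) {
  weights <- match.arg(weights)
  stopifnot(inherits(series, "fib_ratio_series"),
            inherits(native, "fib_native_contacts"))
  ref <- series$maps[[1L]]
  off <- ref$sequence_offset
  iL <- native$contacts$i_full - off
  jL <- native$contacts$j_full - off
  inside <- iL >= 1L & jL <= ref$n_residues
  if (!all(inside)) {
    warning(sum(!inside), " native pair(s) outside the simulated construct ",
            "range were dropped")
    iL <- iL[inside]; jL <- jL[inside]
  }
  if (!length(iL))
    .fib_err("no native pairs map into the simulated construct",
             "fibmod_modulation_error")
  P <- vapply(series$maps, .map_lookup, numeric(length(iL)), i = iL, j = jL)
  P <- matrix(P, nrow = length(iL))
  x <- series$ratios
  w <- if (weights == "frames")
    vapply(series$maps, function(m) as.numeric(m$n_frames), numeric(1))
  else rep(1, length(x))
  if (anyNA(w))
    .fib_err("frame weights unavailable for at least one map",
             "fibmod_modulation_error")
  xbar <- sum(w * x) / sum(w)
  xc <- x - xbar
  sxx <- sum(w * xc^2)
  k <- as.numeric(P %*% (w * xc)) / sxx
  ybar <- as.numeric(P %*% w) / sum(w)
  intercept <- ybar - k * xbar
  syy <- as.numeric(((P - ybar)^2) %*% w)
  r2 <- ifelse(syy > 0, k^2 * sxx / syy, NA_real_)
  entries <- data.frame(i = iL, j = jL, i_full = iL + off, j_full = jL + off,
                        k = k, intercept = intercept, r2 = r2,
                        n_points = length(x))
  structure(list(entries = entries, native_source = native$structure_id,
                 ratios = x, cutoff = ref$cutoff,
                 min_separation = ref$min_separation,
                 n_residues = ref$n_residues, sequence_offset = off,
                 weights = weights),
            class = "fib_modulation")
}

#' @export
print.fib_modulation <- function(x, ...) {
  cat(sprintf(
    "Contact modulation vs native set '%s': %d pairs over ratios {%s}\n",
    x$native_source, nrow(x$entries), paste(x$ratios, collapse = ", ")))
  k <- x$entries$k
  cat(sprintf("  k range [%.4g, %.4g]; %d positive, %d negative\n",
              min(k), max(k), sum(k > 0), sum(k < 0)))
  invisible(x)
}

#' @export
summary.fib_modulation <- function(object, ...) {
  k <- object$entries$k
  out <- list(n_pairs = nrow(object$entries),
              k_quantiles = stats::quantile(k, c(0, .25, .5, .75, 1)),
              n_promoted = sum(k > 0), n_suppressed = sum(k < 0),
              ratios = object$ratios)
  class(out) <- "summary.fib_modulation"
  out
}

#' @export
print.summary.fib_modulation <- function(x, ...) {
  cat("Contact-modulation summary:", x$n_pairs, "fibril-native pairs\n")
  cat("  k quantiles:\n"); print(signif(x$k_quantiles, 4))
  cat("  promoted (k > 0):", x$n_promoted,
      " suppressed (k < 0):", x$n_suppressed, "\n")
  invisible(x)
}

#' @export
coef.fib_modulation <- function(object, ...) {
  stats::setNames(object$entries$k,
                  paste0(object$entries$i_full, "-", object$entries$j_full))
}

#' @export
as.matrix.fib_modulation <- function(x, ...) {
  m <- matrix(NA_real_, x$n_residues, x$n_residues)
  m[cbind(x$entries$i, x$entries$j)] <- x$entries$k
  m[cbind(x$entries$j, x$entries$i)] <- x$entries$k
  full <- x$sequence_offset + seq_len(x$n_residues)
  dimnames(m) <- list(full, full)
  m
}

#' @export
plot.fib_modulation <- function(x, threshold = 0, cex = 0.8, ...) {
  e <- x$entries
  col <- ifelse(e$k > threshold, "#d62728",
                ifelse(e$k < -threshold, "#1f77b4", "grey70"))
  plot(e$i_full, e$j_full, pch = 16, col = col, cex = cex,
       xlab = "residue i", ylab = "residue j",
       main = "Contact-modulation map (red: promoted, blue: suppressed)", ...)
  invisible(x)
}

#' Classify a modulation map into promoted / suppressed / unchanged
#'
#' @param mod a [modulation_coefficients()] result.
#' @param sign_threshold magnitude below which a slope counts as unchanged
#'   (probability per unit ratio).
#' @param regions optional data.frame `name, start, end` (full numbering);
#'   per-region counts tally a pair into every region containing either of
#'   its residues.
#' @return object of class `fib_modulation_report`: `entries` with a `class`
#'   column, `counts`, optional `region_counts`, `sign_threshold`.
#' @export
modulation_map_report <- function(mod, sign_threshold = 0, regions = NULL) {
  stopifnot(inherits(mod, "fib_modulation"))
  e <- mod$entries
  e$class <- ifelse(e$k > sign_threshold, "promoted",
                    ifelse(e$k < -sign_threshold, "suppressed", "unchanged"))
  counts <- table(factor(e$class,
                         levels = c("promoted", "suppressed", "unchanged")))
  region_counts <- NULL
  if (!is.null(regions)) {
    region_counts <- do.call(rbind, lapply(seq_len(nrow(regions)), function(r) {
      inr <- (e$i_full >= regions$start[r] & e$i_full <= regions$end[r]) |
             (e$j_full >= regions$start[r] & e$j_full <= regions$end[r])
      data.frame(region = regions$name[r],
                 promoted = sum(inr & e$class == "promoted"),
                 suppressed = sum(inr & e$class == "suppressed"),
                 unchanged = sum(inr & e$class == "unchanged"))
    }))
  }
  structure(list(entries = e, counts = counts,
                 region_counts = region_counts,
                 sign_threshold = sign_threshold,
                 native_source = mod$native_source,
                 sequence_offset = mod$sequence_offset,
                 ratios = mod$ratios,
                 cutoff = mod$cutoff, min_separation = mod$min_separation),
            class = "fib_modulation_report")
}

#' @export
print.fib_modulation_report <- function(x, ...) {
  cat(sprintf("Modulation report (|k| threshold %g): %d promoted, %d suppressed, %d unchanged\n",
              x$sign_threshold, x$counts[["promoted"]],
              x$counts[["suppressed"]], x$counts[["unchanged"]]))
  if (!is.null(x$region_counts)) print(x$region_counts)
  invisible(x)
}

#' Write a modulation map or report as annotated TSV
#'
#' @param x a `fib_modulation` or `fib_modulation_report`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_modulation_tsv <- function(x, file) {
  e <- x$entries
  meta <- list(type = "modulation_map", native_source = x$native_source,
               ratios = x$ratios, cutoff_nm = x$cutoff,
               min_separation = x$min_separation)
  if (inherits(x, "fib_modulation_report"))
    meta$sign_threshold <- x$sign_threshold
  writeLines(.header_lines(meta), file)
  suppressWarnings(
    utils::write.table(e, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(file)
}
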