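# Residue-residue contact engine.  A residue pair is "in contact" in a frame
# when the minimum distance over their heavy-atom pairs is below the cutoff;
# under periodic boundaries the minimum-image distance is used.

# counts matrix (n_res x n_res, upper triangle filled) of frames in contact
.contact_counts <- function(ensemble, cutoff) {
  top <- ensemble$topology
  nres <- n_residues(top)
  nf <- n_frames(ensemble)
  res_atoms <- top$res_atoms
  one_atom <- all(lengths(res_atoms) == 1L)
  boxes <- ensemble$box
  diag_boxes <- is.null(boxes) ||
    all(apply(boxes, 3, .box_is_diag))
  counts <- matrix(0L, nres, nres)
  if (one_atom && diag_boxes) {
    rows <- unlist(res_atoms)
    L <- if (is.null(boxes)) NULL else
      rbind(boxes[1, 1, ], boxes[2, 2, ], boxes[3, 3, ])  # 3 x nf
    cut2 <- cutoff^2
    for (i in seq_len(nres - 1L)) {
      Ai <- matrix(ensemble$coords[rows[i], , ], nrow = 3L)  # 3 x nf
      for (j in seq.int(i + 1L, nres)) {
        dx <- Ai - matrix(ensemble$coords[rows[j], , ], nrow = 3L)
        if (!is.null(L)) dx <- dx - L * round(dx / L)
        counts[i, j] <- sum(colSums(dx * dx) < cut2)
      }
    }
  } else {
    M <- matrix(0, nrow(top$atoms), nres)
    for (r in seq_len(nres)) M[res_atoms[[r]], r] <- 1
    prot <- which(top$atoms$role == "protein")
    Mp <- M[prot, , drop = FALSE]
    cut2 <- cutoff^2
    for (f in seq_len(nf)) {
      X <- matrix(ensemble$coords[prot, , f], ncol = 3L)
      box <- if (is.null(boxes)) NULL else boxes[, , f]
      A <- .cross_dist2_pbc(X, X, box) < cut2
      counts <- counts + (crossprod(Mp, A %*% Mp) > 0)
    }
  }
  counts
}

#' Compute an intrachain contact-probability map
#'
#' For every residue pair (i, j) with `j - i >= min_separation`, the contact
#' probability P_ij is the fraction of frames in which any heavy atom of
#' residue i lies within `cutoff` of any heavy atom of residue j.  The
#' default cutoff of 0.45 nm and separation floor of 4 (pairs separated by at
#' least three other residues) match standard practice for disordered-protein
#' ensembles.
#'
#' @param ensemble a [fib_ensemble] with at least one frame.
#' @param cutoff heavy-atom distance cutoff in nm.
#' @param min_separation smallest sequence separation `j - i` retained.
#' @return object of class `fib_contact_map`: sparse pair table
#'   (`pairs`: data.frame `i, j, p` for pairs with P_ij > 0), plus `cutoff`,
#'   `min_separation`, `n_frames`, `n_residues`, `n_pairs_universe`,
#'   `sequence_offset` and `condition`.
#' @examples
#' sp <- generator_spec(seed = 3, chain_length = 12, n_frames = 50,
#'                      programmed_contacts = data.frame(i = 2, j = 9,
#'                        intercept = 0.5, slope = 0))
#' cm <- compute_contact_map(generate_ensemble(sp, ratio = 0))
#' cm$pairs[cm$pairs$i == 2 & cm$pairs$j == 9, ]
#' @export
compute_contact_map <- function(ensemble, cutoff = 0.45, min_separation = 4L) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  if (n_frames(ensemble) < 1L)
    .fib_err("ensemble has no frames", "fibmod_no_frames_error")
  if (any(lengths(ensemble$topology$res_atoms) == 0L))
    .fib_err("every residue needs at least one heavy atom",
             "fibmod_topology_error")
  nres <- n_residues(ensemble)
  counts <- .contact_counts(ensemble, cutoff)
  nf <- n_frames(ensemble)
  ut <- which(upper.tri(counts), arr.ind = TRUE)
  keep <- (ut[, 2] - ut[, 1]) >= min_separation
  ut <- ut[keep, , drop = FALSE]
  p <- counts[ut] / nf
  nz <- p > 0
  pairs <- data.frame(i = ut[nz, 1], j = ut[nz, 2], p = p[nz])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, cutoff = cutoff,
                 min_separation = as.integer(min_separation),
                 n_frames = nf, n_residues = nres,
                 n_pairs_universe = nrow(ut),
                 sequence_offset = ensemble$topology$sequence_offset,
                 condition = ensemble$condition),
            class = "fib_contact_map")
}

#' Build a contact map from known probabilities
#'
#' Constructor for workflows where per-pair probabilities are available
#' directly (e.g. programmed occupancies or published tables) rather than
#' computed from coordinates.
#'
#' @param pairs data.frame with columns `i`, `j` (`i < j`) and `p` in `[0,1]`.
#' @param n_residues chain length.
#' @param cutoff,min_separation,n_frames,sequence_offset,condition metadata,
#'   as in [compute_contact_map()].
#' @return a `fib_contact_map`.
#' @export
contact_map <- function(pairs, n_residues, cutoff = 0.45, min_separation = 4L,
                        n_frames = NA_integer_, sequence_offset = 0L,
                        condition = ligand_condition(0)) {
  pairs <- as.data.frame(pairs)[, c("i", "j", "p")]
  if (any(pairs$j - pairs$i < min_separation))
    .fib_err("pairs below the separation floor", "fibmod_contact_error")
  if (any(pairs$p < 0 | pairs$p > 1))
    .fib_err("probabilities must lie in [0, 1]", "fibmod_contact_error")
  pairs <- pairs[pairs$p > 0, , drop = FALSE]
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  nres <- as.integer(n_residues)
  npairs <- sum(vapply(seq_len(nres), function(i)
    max(nres - i - min_separation + 1L, 0L), integer(1)))
  if (!inherits(condition, "fib_condition")) condition <- ligand_condition(condition)
  structure(list(pairs = pairs, cutoff = cutoff,
                 min_separation = as.integer(min_separation),
                 n_frames = n_frames, n_residues = nres,
                 n_pairs_universe = npairs,
                 sequence_offset = as.integer(sequence_offset),
                 condition = condition),
            class = "fib_contact_map")
}

#' @export
print.fib_contact_map <- function(x, ...) {
  cat(sprintf(
    "Contact map: %d residues, %d/%d pairs with P > 0 (cutoff %.2f nm, |i-j| >= %d, %s frames)\n",
    x$n_residues, nrow(x$pairs), x$n_pairs_universe, x$cutoff,
    x$min_separation, as.character(x$n_frames)))
  cat("  condition:", x$condition$label, "\n")
  invisible(x)
}

#' @export
as.matrix.fib_contact_map <- function(x, ...) {
  m <- matrix(0, x$n_residues, x$n_residues)
  excl <- abs(row(m) - col(m)) < x$min_separation
  m[excl] <- NA_real_
  if (nrow(x$pairs)) {
    m[cbind(x$pairs$i, x$pairs$j)] <- x$pairs$p
    m[cbind(x$pairs$j, x$pairs$i)] <- x$pairs$p
  }
  full <- x$sequence_offset + seq_len(x$n_residues)
  dimnames(m) <- list(full, full)
  m
}

# probability for an explicit pair list, absent pairs = 0
.map_lookup <- function(map, i, j) {
  key <- paste(map$pairs$i, map$pairs$j)
  p <- map$pairs$p[match(paste(i, j), key)]
  p[is.na(p)] <- 0
  p
}

#' Contact-probability difference between two conditions
#'
#' Computes dP_ij = P_ij(with ligand) - P_ij(without) over the shared pair
#' universe; a pair absent from one sparse map contributes probability 0
#' there.
#'
#' @param map_with,map_without two [compute_contact_map()] results with
#'   identical cutoff, separation floor and chain length.
#' @return object of class `fib_contact_delta` with a `pairs` data.frame
#'   (`i, j, delta`) restricted to pairs with a non-zero value in either map.
#' @export
contact_delta <- function(map_with, map_without) {
  stopifnot(inherits(map_with, "fib_contact_map"),
            inherits(map_without, "fib_contact_map"))
  if (map_with$cutoff != map_without$cutoff ||
      map_with$min_separation != map_without$min_separation ||
      map_with$n_residues != map_without$n_residues)
    .fib_err("contact maps are incompatible (cutoff, separation or size differ)",
             "fibmod_incompatible_maps_error")
  u <- unique(rbind(map_with$pairs[, c("i", "j")],
                    map_without$pairs[, c("i", "j")]))
  u <- u[order(u$i, u$j), , drop = FALSE]
  delta <- .map_lookup(map_with, u$i, u$j) - .map_lookup(map_without, u$i, u$j)
  structure(list(pairs = data.frame(i = u$i, j = u$j, delta = delta),
                 cutoff = map_with$cutoff,
                 min_separation = map_with$min_separation,
                 n_residues = map_with$n_residues,
                 sequence_offset = map_with$sequence_offset,
                 condition_with = map_with$condition,
                 condition_without = map_without$condition),
            class = "fib_contact_delta")
}

#' @export
print.fib_contact_delta <- function(x, ...) {
  cat(sprintf("Contact delta (%s minus %s): %d pairs, range [%.3f, %.3f]\n",
              x$condition_with$label, x$condition_without$label,
              nrow(x$pairs),
              if (nrow(x$pairs)) min(x$pairs$delta) else 0,
              if (nrow(x$pairs)) max(x$pairs$delta) else 0))
  invisible(x)
}

# ---- export ----------------------------------------------------------------

# header block recording the configuration that produced a numeric output
.header_lines <- function(meta) {
  vapply(names(meta), function(k)
    sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
    character(1))
}

#' Write a contact map or delta as annotated TSV
#'
#' Long-format TSV with columns `i, j, i_full, j_full, value`, preceded by a
#' `#`-comment header block recording cutoff, separation floor, frame count
#' and condition; `format = "matrix"` writes the square-matrix CSV used for
#' map rendering instead.
#'
#' @param x a `fib_contact_map` or `fib_contact_delta`.
#' @param file output path.
#' @param format `"tsv"` (long, with header) or `"matrix"` (square CSV).
#' @return `file`, invisibly.
#' @export
write_contact_tsv <- function(x, file, format = c("tsv", "matrix")) {
  format <- match.arg(format)
  is_map <- inherits(x, "fib_contact_map")
  if (format == "matrix") {
    m <- if (is_map) as.matrix(x) else {
      cm <- contact_map(data.frame(i = x$pairs$i, j = x$pairs$j,
                                   p = abs(x$pairs$delta)),
                        x$n_residues, x$cutoff, x$min_separation,
                        sequence_offset = x$sequence_offset)
      mm <- as.matrix(cm)
      sg <- sign(x$pairs$delta)
      mm[cbind(x$pairs$i, x$pairs$j)] <- x$pairs$delta
      mm[cbind(x$pairs$j, x$pairs$i)] <- x$pairs$delta
      mm
    }
    utils::write.table(m, file, sep = ",", quote = FALSE, col.names = NA)
    return(invisible(file))
  }
  meta <- list(type = if (is_map) "contact_map" else "contact_delta",
               cutoff_nm = x$cutoff, min_separation = x$min_separation,
               n_residues = x$n_residues)
  if (is_map) {
    meta$n_frames <- x$n_frames
    meta$condition <- x$condition$label
    val <- x$pairs$p
  } else {
    meta$condition_with <- x$condition_with$label
    meta$condition_without <- x$condition_without$label
    val <- x$pairs$delta
  }
  off <- x$sequence_offset
  tab <- data.frame(i = x$pairs$i, j = x$pairs$j,
                    i_full = x$pairs$i + off, j_full = x$pairs$j + off,
                    value = val)
  writeLines(.header_lines(meta), file)
  suppressWarnings(
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(file)
}
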