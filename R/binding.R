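# Ligand-residue association analytics: occupancy profiles, ligand-mediated
# contact maps, residence times and exchange rates.

# minimum heavy-atom distance array: n_ligands x n_residues x n_frames (nm)
.ligand_residue_dist <- function(ensemble) {
  top <- ensemble$topology
  nl <- n_ligands(top); nr <- n_residues(top); nf <- n_frames(ensemble)
  if (nl == 0L)
    .fib_err("ensemble declares no ligand molecules", "fibmod_no_ligand_error")
  boxes <- ensemble$box
  diag_boxes <- is.null(boxes) || all(apply(boxes, 3, .box_is_diag))
  one_atom <- all(lengths(top$res_atoms) == 1L) &&
    all(lengths(top$lig_atoms) == 1L)
  d <- array(NA_real_, c(nl, nr, nf))
  if (one_atom && diag_boxes) {
    lrow <- unlist(top$lig_atoms); rrow <- unlist(top$res_atoms)
    L <- if (is.null(boxes)) NULL else
      rbind(boxes[1, 1, ], boxes[2, 2, ], boxes[3, 3, ])
    for (l in seq_len(nl)) {
      Xl <- matrix(ensemble$coords[lrow[l], , ], nrow = 3L)  # 3 x nf
      for (r in seq_len(nr)) {
        dx <- Xl - matrix(ensemble$coords[rrow[r], , ], nrow = 3L)
        if (!is.null(L)) dx <- dx - L * round(dx / L)
        d[l, r, ] <- sqrt(colSums(dx * dx))
      }
    }
  } else {
    for (f in seq_len(nf)) {
      box <- if (is.null(boxes)) NULL else boxes[, , f]
      for (l in seq_len(nl)) {
        Xl <- matrix(ensemble$coords[top$lig_atoms[[l]], , f], ncol = 3L)
        for (r in seq_len(nr)) {
          Xr <- matrix(ensemble$coords[top$res_atoms[[r]], , f], ncol = 3L)
          d[l, r, f] <- sqrt(min(.cross_dist2_pbc(Xl, Xr, box)))
        }
      }
    }
  }
  d
}

#' Per-residue mean ligand count
#'
#' n_ligand(i) is the mean over frames of the number of distinct ligand
#' molecules having any heavy atom within `cutoff` of any heavy atom of
#' residue i.
#'
#' @param ensemble a [fib_ensemble] declaring at least one ligand.
#' @param cutoff heavy-atom contact cutoff in nm (default 0.45).
#' @return object of class `fib_binding_profile`: data.frame `profile`
#'   (`res, res_full, n_ligand`) plus `cutoff` and `n_frames`.
#' @export
ligand_count_profile <- function(ensemble, cutoff = 0.45) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  d <- .ligand_residue_dist(ensemble)
  counts <- apply(d < cutoff, c(2, 3), sum)       # n_res x n_frames
  prof <- rowMeans(counts)
  off <- ensemble$topology$sequence_offset
  structure(list(profile = data.frame(res = seq_along(prof),
                                      res_full = seq_along(prof) + off,
                                      n_ligand = prof),
                 cutoff = cutoff, n_frames = n_frames(ensemble),
                 condition = ensemble$condition),
            class = "fib_binding_profile")
}

#' @export
print.fib_binding_profile <- function(x, ...) {
  cat(sprintf("Ligand-count profile: %d residues, mean %.3f ligands/residue (cutoff %.2f nm)\n",
              nrow(x$profile), mean(x$profile$n_ligand), x$cutoff))
  invisible(x)
}

#' Ligand-mediated contact map
#'
#' P_isj is the fraction of frames in which residues i and j are both within
#' `cutoff` of the *same* ligand molecule, i.e. the ligand bridges the pair.
#' The default 0.6 nm cutoff is looser than the direct-contact cutoff because
#' the ligand sits between the residues.  Pairs in direct contact are not
#' excluded; attribution of direct vs mediated interactions is done by
#' comparing against [compute_contact_map()] downstream.
#'
#' @param ensemble a [fib_ensemble] declaring at least one ligand.
#' @param cutoff ligand-residue heavy-atom cutoff in nm (default 0.6).
#' @param min_separation sequence-separation floor (default 4).
#' @return object of classes `fib_mediated_map` and `fib_contact_map` (same
#'   layout as [compute_contact_map()], probabilities are P_isj).
#' @export
mediated_contact_map <- function(ensemble, cutoff = 0.6, min_separation = 4L) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  d <- .ligand_residue_dist(ensemble)
  nf <- n_frames(ensemble)
  nr <- n_residues(ensemble)
  counts <- matrix(0L, nr, nr)
  for (f in seq_len(nf)) {
    B <- matrix(d[, , f] < cutoff, nrow = dim(d)[1])
    counts <- counts + (crossprod(B) > 0)
  }
  ut <- which(upper.tri(counts), arr.ind = TRUE)
  keep <- (ut[, 2] - ut[, 1]) >= min_separation
  ut <- ut[keep, , drop = FALSE]
  p <- counts[ut] / nf
  nz <- p > 0
  pairs <- data.frame(i = ut[nz, 1], j = ut[nz, 2], p = p[nz])
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, cutoff = cutoff,
                 min_separation = as.integer(min_separation),
                 n_frames = nf, n_residues = nr,
                 n_pairs_universe = nrow(ut),
                 sequence_offset = ensemble$topology$sequence_offset,
                 condition = ensemble$condition),
            class = c("fib_mediated_map", "fib_contact_map"))
}

# hysteretic bound/unbound state series for one ligand-residue distance
# series; the head defaults to unbound (a ligand starting in the dead zone
# was not "initially within r_on")
.bind_states <- function(d, r_on, r_off) {
  s <- ifelse(d < r_on, 1, ifelse(d > r_off, 0, NA))
  det <- which(!is.na(s))
  if (!length(det)) return(rep(FALSE, length(d)))
  as.logical(stats::approx(c(0L, det), c(0, s[det]), xout = seq_along(d),
                           method = "constant", f = 0, rule = 2)$y)
}

#' Ligand residence times and exchange rates
#'
#' A binding event starts when a ligand molecule comes within `r_on` of a
#' residue while previously unbound there, and ends at the first frame its
#' distance to that residue exceeds `r_off` (re-entering the dead zone
#' between the two cutoffs does not end the event).  tau_residue is the event
#' duration; tau_protein extends the same event until the ligand is beyond
#' `r_off` of *all* residues (complete dissociation from the protein
#' surface).  Events still bound at the end of the trajectory are censored:
#' they are counted but excluded from the means.  The exchange rate is the
#' number of completed dissociation events at a residue divided by the total
#' analyzed time.
#'
#' @param ensemble a [fib_ensemble] with uniform frame spacing and at least
#'   one ligand.
#' @param r_on entry cutoff, nm (default 0.45).
#' @param r_off exit cutoff, nm (default 0.6).
#' @param dt frame spacing in ns; taken from ensemble times when present.
#' @return object of class `fib_residence`: `per_residue` data.frame
#'   (`res, res_full, mean_tau_residue, mean_tau_protein, exchange_rate,
#'   n_events, n_censored`), per-event table `events`, `analyzed_time` (ns).
#' @export
residence_analysis <- function(ensemble, r_on = 0.45, r_off = 0.6, dt = NULL) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  if (r_on >= r_off)
    .fib_err("r_on must be smaller than r_off", "fibmod_parameter_error")
  if (is.null(dt)) dt <- .frame_dt(ensemble, default = 1)
  d <- .ligand_residue_dist(ensemble)
  nl <- dim(d)[1]; nr <- dim(d)[2]; nf <- dim(d)[3]
  events <- vector("list", nl * nr)
  ev_i <- 0L
  for (l in seq_len(nl)) {
    dprot <- d[l, 1L, ]                 # ligand-protein (min over residues)
    for (r in seq_len(nr)[-1L]) dprot <- pmin(dprot, d[l, r, ])
    away <- which(dprot > r_off)   # frames fully dissociated from the protein
    for (r in seq_len(nr)) {
      s <- .bind_states(d[l, r, ], r_on, r_off)
      if (!any(s)) next
      runs <- rle(s)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      bi <- which(runs$values)
      censored <- ends[bi] == nf & s[nf]
      tau_res <- ifelse(censored, NA_real_, runs$lengths[bi] * dt)
      # first fully-dissociated frame at or after each event start
      nxt <- away[findInterval(starts[bi] - 1L, away) + 1L]
      tau_prot <- ifelse(censored | is.na(nxt), NA_real_,
                         (nxt - starts[bi]) * dt)
      ev_i <- ev_i + 1L
      events[[ev_i]] <- data.frame(ligand = l, res = r,
                                   start_frame = starts[bi],
                                   tau_residue = tau_res,
                                   tau_protein = tau_prot,
                                   censored = censored)
    }
  }
  events <- if (ev_i) do.call(rbind, events[seq_len(ev_i)])
            else data.frame(ligand = integer(0), res = integer(0),
                            start_frame = integer(0), tau_residue = numeric(0),
                            tau_protein = numeric(0), censored = logical(0))
  events <- events[order(events$res, events$ligand, events$start_frame), ,
                   drop = FALSE]
  rownames(events) <- NULL
  analyzed_time <- nf * dt
  off <- ensemble$topology$sequence_offset
  per_res <- do.call(rbind, lapply(seq_len(nr), function(r) {
    er <- events[events$res == r, , drop = FALSE]
    done <- er[!er$censored, , drop = FALSE]
    data.frame(res = r, res_full = r + off,
               mean_tau_residue = if (nrow(done)) mean(done$tau_residue)
                                  else NA_real_,
               mean_tau_protein = if (any(!is.na(done$tau_protein)))
                 mean(done$tau_protein, na.rm = TRUE) else NA_real_,
               exchange_rate = nrow(done) / analyzed_time,
               n_events = nrow(done), n_censored = sum(er$censored))
  }))
  if (sum(per_res$n_censored) > sum(per_res$n_events))
    warning("censored events outnumber completed ones; ",
            "residence means may be unreliable on this trajectory length")
  structure(list(per_residue = per_res, events = events,
                 r_on = r_on, r_off = r_off, dt = dt,
                 analyzed_time = analyzed_time,
                 condition = ensemble$condition),
            class = "fib_residence")
}

#' @export
print.fib_residence <- function(x, ...) {
  cat(sprintf(
    "Residence analysis: %d completed events, %d censored over %.4g ns (r_on %.2f / r_off %.2f nm)\n",
    sum(x$per_residue$n_events), sum(x$per_residue$n_censored),
    x$analyzed_time, x$r_on, x$r_off))
  tr <- x$events$tau_residue[!x$events$censored]
  if (length(tr))
    cat(sprintf("  mean tau_residue %.4g ns, mean tau_protein %.4g ns\n",
                mean(tr), mean(x$events$tau_protein, na.rm = TRUE)))
  invisible(x)
}

#' Write binding outputs as annotated TSV
#' @param x a `fib_binding_profile` or `fib_residence`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_binding_tsv <- function(x, file) {
  if (inherits(x, "fib_binding_profile")) {
    meta <- list(type = "ligand_count_profile", cutoff_nm = x$cutoff,
                 n_frames = x$n_frames, condition = x$condition$label)
    tab <- x$profile
  } else if (inherits(x, "fib_residence")) {
    meta <- list(type = "residence_stats", r_on_nm = x$r_on,
                 r_off_nm = x$r_off, dt_ns = x$dt,
                 analyzed_time_ns = x$analyzed_time)
    tab <- x$per_residue
  } else .fib_err("unsupported object", "fibmod_format_error")
  writeLines(.header_lines(meta), file)
  suppressWarnings(
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(file)
}
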