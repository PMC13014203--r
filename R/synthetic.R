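# Synthetic-data generators with known ground truth.  They emulate the
# statistical structure the analyses assume -- programmed contact
# occupancies, telegraph ligand binding, designed fibril contact clusters,
# logistic ThT curves -- not force-field thermodynamics, so every pipeline
# stage can be validated against analytic oracles with no external data.

#' Specification for the synthetic generators
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   reproducible bit for bit.
#' @param chain_length number of residues of the bead-per-residue chain.
#' @param n_frames frames per ensemble.
#' @param frame_dt frame spacing in ns.
#' @param box cubic box edge in nm; defaults to 2.5x the maximum chain
#'   extent (never below 4 nm) so generated ensembles pass the 0.3 nm
#'   periodic-image QC by construction.
#' @param bond_length bead spacing of the random-flight chain in nm.
#' @param ligand_count number of ligand particles; defaults to the number of
#'   rows of `binding_spec`.
#' @param programmed_contacts data.frame `i, j, intercept, slope`: residue
#'   pairs whose per-frame contact state is drawn with occupancy
#'   `intercept + slope * ratio` and realised geometrically (pair distance
#'   0.40 nm in contact, 0.80 nm out of contact).  Pairs must use disjoint
#'   residues, `j - i >= 4`.
#' @param binding_spec data.frame `residue, k_on, k_off` (rates in /ns): one
#'   row per ligand following a two-state telegraph binding process to the
#'   given residue (bound: placed 0.40 nm from the residue; unbound: uniform
#'   in the box, at least 0.7 nm away from every residue).
#' @param fibril_spec named list mapping structure ids to data.frames
#'   (`i, j`) of designed contacts; see [fibril_block_design()].
#' @param tht_spec list with `time` (minutes), `F0`, `Fmax`, `k` (/min),
#'   `t_half` (min), `noise_sd`, `n_replicates`.
#' @return object of class `fib_generator_spec`.
#' @export
generator_spec <- function(seed = 1L, chain_length = 20L, n_frames = 100L,
                           frame_dt = 0.1, box = NULL, bond_length = 0.38,
                           ligand_count = NULL,
                           programmed_contacts = NULL, binding_spec = NULL,
                           fibril_spec = NULL, tht_spec = NULL) {
  if (!is.null(programmed_contacts)) {
    pc <- as.data.frame(programmed_contacts)
    if (any(pc$j - pc$i < 4L))
      .fib_err("programmed pairs need j - i >= 4", "fibmod_spec_error")
    used <- c(pc$i, pc$j)
    if (anyDuplicated(used))
      .fib_err("programmed pairs must use disjoint residues",
               "fibmod_spec_error")
  }
  if (is.null(ligand_count))
    ligand_count <- if (is.null(binding_spec)) 0L else nrow(binding_spec)
  if (is.null(box))
    box <- max(4, 2.5 * (chain_length - 1) * bond_length)
  structure(list(seed = as.integer(seed),
                 chain_length = as.integer(chain_length),
                 n_frames = as.integer(n_frames), frame_dt = frame_dt,
                 box = box, bond_length = bond_length,
                 ligand_count = as.integer(ligand_count),
                 programmed_contacts = programmed_contacts,
                 binding_spec = binding_spec, fibril_spec = fibril_spec,
                 tht_spec = tht_spec),
            class = "fib_generator_spec")
}

# random unit vectors, n x 3
.runit <- function(n) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

# alternating-dwell telegraph chain sampled every dt; returns logical states
.telegraph_states <- function(n, k_on, k_off, dt, start_bound) {
  total <- n * dt
  guess <- ceiling(total * (k_on * k_off / (k_on + k_off)) * 2) + 50L
  st <- logical(guess); dw <- numeric(guess)
  cur <- start_bound; tsum <- 0; m <- 0L
  while (tsum < total) {
    m <- m + 1L
    if (m > length(st)) { st <- c(st, logical(m)); dw <- c(dw, numeric(m)) }
    st[m] <- cur
    dw[m] <- stats::rexp(1L, if (cur) k_off else k_on)
    tsum <- tsum + dw[m]
    cur <- !cur
  }
  idx <- findInterval((seq_len(n) - 1L) * dt, cumsum(c(0, dw[seq_len(m)])))
  st[pmin(idx, m)]
}

#' Simulate a two-state (telegraph) contact trajectory
#'
#' Continuous-time two-state process with formation rate `k_on` and breaking
#' rate `k_off`, sampled every `dt`; the initial state is drawn from the
#' stationary distribution.  Its autocorrelation decays as
#' `exp(-(k_on + k_off) t)`, making it the analytic oracle for
#' [contact_relaxation_time()].
#'
#' @param n number of frames.
#' @param k_on,k_off rates in /ns.
#' @param dt frame spacing in ns.
#' @param seed RNG seed.
#' @return a [contact_state_trajectory()]-compatible `fib_contact_states`.
#' @export
simulate_telegraph_states <- function(n, k_on, k_off, dt, seed = 1L) {
  set.seed(seed)
  start <- stats::runif(1L) < k_on / (k_on + k_off)
  structure(list(states = .telegraph_states(n, k_on, k_off, dt, start),
                 r_on = 0.45, r_off = 0.6, dt = dt, pair = NULL,
                 dropped_frames = 0L),
            class = "fib_contact_states")
}

#' Generate a synthetic bead-chain ensemble
#'
#' One heavy atom (named CA) per residue.  Each frame is an independent
#' random-flight chain centred in the box; programmed contact pairs override
#' the position of their second residue to sit 0.40 nm (in contact) or
#' 0.80 nm (out of contact) from the first, with the per-frame contact state
#' drawn independently at occupancy `intercept + slope * ratio`.  Ligand
#' particles follow telegraph binding processes per `binding_spec`.
#'
#' @param spec a [generator_spec()].
#' @param ratio ligand:protein molar ratio of the condition (drives the
#'   programmed occupancies and is recorded on the ensemble).
#' @return a [fib_ensemble].
#' @export
generate_ensemble <- function(spec, ratio = 0) {
  stopifnot(inherits(spec, "fib_generator_spec"))
  pc <- spec$programmed_contacts
  if (!is.null(pc)) {
    occ <- pc$intercept + pc$slope * ratio
    if (any(occ < 0 | occ > 1))
      .fib_err(sprintf("programmed occupancy outside [0, 1] at ratio %g", ratio),
               "fibmod_spec_error")
  }
  set.seed(spec$seed)
  n <- spec$chain_length; nf <- spec$n_frames
  nlig <- spec$ligand_count
  natoms <- n + nlig
  coords <- array(NA_real_, c(natoms, 3L, nf))
  centre <- rep(spec$box / 2, 3L)
  # random-flight chain; vectorised over frames (loop over beads, not frames)
  steps <- .runit((n - 1L) * nf) * spec$bond_length   # ((n-1)*nf) x 3
  cur <- matrix(0, nf, 3L)
  csum <- cur
  pos <- vector("list", n)
  pos[[1L]] <- cur
  for (k in seq_len(n - 1L)) {
    cur <- cur + steps[seq.int((k - 1L) * nf + 1L, k * nf), , drop = FALSE]
    pos[[k + 1L]] <- cur
    csum <- csum + cur
  }
  cm <- csum / n
  for (k in seq_len(n))
    coords[k, , ] <- t(pos[[k]] - cm + rep(centre, each = nf))
  # programmed pair occupancies
  if (!is.null(pc)) {
    for (p in seq_len(nrow(pc))) {
      occ <- pc$intercept[p] + pc$slope[p] * ratio
      z <- stats::runif(nf) < occ
      u <- .runit(nf)
      d <- ifelse(z, 0.40, 0.80)
      coords[pc$j[p], , ] <- t(t(coords[pc$i[p], , , drop = TRUE]) + u * d)
    }
  }
  # ligand telegraph binding
  bs <- spec$binding_spec
  if (nlig > 0L) {
    for (l in seq_len(nlig)) {
      b <- if (!is.null(bs)) bs[((l - 1L) %% nrow(bs)) + 1L, ] else NULL
      if (is.null(b)) {
        coords[n + l, , ] <- t(matrix(stats::runif(3L * nf, 0, spec$box),
                                      nf, 3L))
        next
      }
      start <- stats::runif(1L) < b$k_on / (b$k_on + b$k_off)
      z <- .telegraph_states(nf, b$k_on, b$k_off, spec$frame_dt, start)
      u <- .runit(nf)
      pos <- matrix(NA_real_, nf, 3L)
      res_xyz <- t(coords[b$residue, , , drop = TRUE])   # nf x 3
      pos[z, ] <- res_xyz[z, , drop = FALSE] + 0.40 * u[z, , drop = FALSE]
      nu <- which(!z)
      while (length(nu)) {
        cand <- matrix(stats::runif(3L * length(nu), 0, spec$box),
                       length(nu), 3L)
        # keep candidates clearly outside every residue's exit cutoff
        ok <- rep(TRUE, length(nu))
        for (r in seq_len(n)) {
          dr <- cand - t(coords[r, , nu, drop = TRUE])
          if (length(nu) == 1L) dr <- matrix(cand - coords[r, , nu], 1L, 3L)
          ok <- ok & rowSums(dr^2) > 0.7^2
        }
        pos[nu[ok], ] <- cand[ok, , drop = FALSE]
        nu <- nu[!ok]
      }
      coords[n + l, , ] <- t(pos)
    }
  }
  atoms <- data.frame(
    atom_id = seq_len(natoms), name = c(rep("CA", n), rep("C1", nlig)),
    element = "C", role = c(rep("protein", n), rep("ligand", nlig)),
    mol = c(seq_len(n), seq_len(max(nlig, 1L))[seq_len(nlig)]),
    resname = c(rep("ALA", n), rep("LIG", nlig)),
    chain = c(rep("A", n), rep("B", nlig)))
  top <- fib_topology(atoms)
  fib_ensemble(top, coords, times = (seq_len(nf) - 1L) * spec$frame_dt,
               box = diag(rep(spec$box, 3L)),
               condition = ligand_condition(ratio))
}

#' Designed fibril contact-set layout with known cluster structure
#'
#' Nine structures on a 40-residue chain: one block of three sharing two
#' contacts, one block of two sharing one contact, and four singletons with
#' pairwise-disjoint contacts, so clustering by shared contacts must recover
#' components of sizes 3, 2, 1, 1, 1, 1.
#'
#' @return named list of data.frames (`i, j`), one per structure.
#' @export
fibril_block_design <- function() {
  s1 <- data.frame(i = c(2L, 14L), j = c(10L, 22L))
  s2 <- data.frame(i = 5L, j = 13L)
  list(
    A = rbind(s1, data.frame(i = 26L, j = 34L)),
    B = rbind(s1, data.frame(i = 27L, j = 35L)),
    C = rbind(s1, data.frame(i = 28L, j = 36L)),
    D = rbind(s2, data.frame(i = 18L, j = 26L)),
    E = rbind(s2, data.frame(i = 19L, j = 27L)),
    F = data.frame(i = c(3L, 15L), j = c(11L, 23L)),
    G = data.frame(i = 4L, j = 12L),
    H = data.frame(i = c(6L, 20L), j = c(14L, 28L)),
    I = data.frame(i = 8L, j = 16L))
}

# fold a straight backbone trace so exactly the designed pairs touch: beads
# on a 0.6 nm line, each contact's j bead moved to 0.40 nm from its i bead
.fibril_coords <- function(n_res, contacts) {
  X <- cbind(0.6 * (seq_len(n_res) - 1L), 0, 0)
  golden <- pi * (3 - sqrt(5))
  for (k in seq_len(nrow(contacts))) {
    ang <- k * golden
    X[contacts$j[k], ] <- X[contacts$i[k], ] +
      0.40 * c(0, cos(ang), sin(ang))
  }
  X
}

#' Generate a set of synthetic fibril structures as PDB files
#'
#' Each structure is a coarse C-alpha backbone trace folded so that exactly
#' the designed residue pairs fall within the 0.45 nm contact cutoff; the
#' realised contact set of every written file is verified against its design
#' and a generation error names any offending pair.
#'
#' @param spec a [generator_spec()]; `fibril_spec` holds the design
#'   ([fibril_block_design()] when `NULL`).
#' @param dir output directory (created if needed).
#' @param n_res chain length of the traces (default 40).
#' @return data.frame manifest (`file, structure_id, chain_policy,
#'   renumber_offset`); also written to `dir/manifest.tsv`.
#' @export
generate_fibril_set <- function(spec, dir, n_res = 40L) {
  stopifnot(inherits(spec, "fib_generator_spec"))
  design <- spec$fibril_spec
  if (is.null(design)) design <- fibril_block_design()
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(design))
  for (s in seq_along(design)) {
    id <- names(design)[s]
    contacts <- as.data.frame(design[[s]])
    if (any(contacts$j - contacts$i < 4L))
      .fib_err(sprintf("design '%s' has pairs below the separation floor", id),
               "fibmod_generation_error")
    X <- .fibril_coords(n_res, contacts)
    f <- file.path(dir, paste0(id, ".pdb"))
    bio3d::write.pdb(file = f, xyz = as.vector(t(X)) * 10, type = "ATOM",
                     resno = seq_len(n_res),
                     resid = rep("ALA", n_res), eleno = seq_len(n_res),
                     elety = rep("CA", n_res), chain = rep("A", n_res),
                     elesy = rep("C", n_res))
    realized <- extract_native_contacts(
      load_fibril_structure(f, chain_policy = "first", structure_id = id))
    want <- paste(contacts$i, contacts$j)
    got <- paste(realized$contacts$i_full, realized$contacts$j_full)
    if (!setequal(want, got)) {
      bad <- c(setdiff(want, got), setdiff(got, want))
      .fib_err(sprintf("design '%s' not geometrically realised; offending pair(s): %s",
                       id, paste(bad, collapse = "; ")),
               "fibmod_generation_error")
    }
    files[s] <- f
  }
  manifest <- data.frame(file = basename(files),
                         structure_id = names(design),
                         chain_policy = "first", renumber_offset = 0L)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

#' Generate synthetic ThT kinetics with known logistic parameters
#'
#' Logistic curves plus seeded Gaussian noise, `n_replicates` per condition.
#'
#' @param spec a [generator_spec()] whose `tht_spec` lists `time`, `F0`,
#'   `Fmax`, `k`, `t_half`, `noise_sd` and `n_replicates` (each of
#'   `F0, Fmax, k, t_half` may be a vector over conditions, with `ratio`
#'   giving the condition ratios).
#' @return a [tht_dataset()] for a single condition, or a list of them.
#' @export
generate_tht_curves <- function(spec) {
  stopifnot(inherits(spec, "fib_generator_spec"))
  ts <- spec$tht_spec
  if (is.null(ts))
    .fib_err("generator spec has no tht_spec", "fibmod_spec_error")
  defaults <- list(time = seq(0, 700, by = 7), F0 = 0.1, Fmax = 1.0,
                   k = 0.05, t_half = 300, noise_sd = 0.02,
                   n_replicates = 3L, ratio = 0)
  ts <- utils::modifyList(defaults, ts)
  if (ts$noise_sd < 0)
    .fib_err("noise_sd must be non-negative", "fibmod_spec_error")
  ncond <- max(lengths(ts[c("F0", "Fmax", "k", "t_half", "ratio")]))
  par <- lapply(ts[c("F0", "Fmax", "k", "t_half", "ratio")], rep_len, ncond)
  set.seed(spec$seed)
  out <- lapply(seq_len(ncond), function(cc) {
    clean <- .logistic(ts$time, par$F0[cc], par$Fmax[cc], par$k[cc],
                       par$t_half[cc])
    reps <- vapply(seq_len(ts$n_replicates), function(r)
      clean + stats::rnorm(length(clean), 0, ts$noise_sd),
      numeric(length(clean)))
    tht_dataset(ts$time, reps, condition = paste0("1:", par$ratio[cc]),
                ratio = par$ratio[cc])
  })
  if (ncond == 1L) out[[1L]] else out
}
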