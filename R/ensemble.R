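#' Ligand condition label
#'
#' @param ratio dimensionless ligand:protein molar ratio (>= 0).
#' @param label optional display label; defaults to `"1:<ratio>"`.
#' @return list of class `fib_condition`.
#' @export
ligand_condition <- function(ratio = 0, label = NULL) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio < 0)
    .fib_err("ligand ratio must be a single non-negative number",
             "fibmod_condition_error")
  structure(list(ratio = as.numeric(ratio),
                 label = if (is.null(label)) paste0("1:", ratio) else label),
            class = "fib_condition")
}

#' Construct a conformational ensemble
#'
#' An ensemble bundles a topology with per-frame coordinates (nm), optional
#' frame times (ns), optional triclinic box vectors and the ligand condition
#' it was simulated at.
#'
#' @param topology a [fib_topology].
#' @param coords numeric array `n_atoms x 3 x n_frames` in nm.
#' @param times numeric vector of frame times in ns (non-decreasing), or NULL.
#' @param box `3 x 3` matrix (rows = box vectors, nm) applied to every frame,
#'   a `3 x 3 x n_frames` array, or NULL for no periodic boundaries.
#' @param condition a [ligand_condition()].
#' @return object of class `fib_ensemble`.
#' @export
fib_ensemble <- function(topology, coords, times = NULL, box = NULL,
                         condition = ligand_condition(0)) {
  stopifnot(inherits(topology, "fib_topology"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    .fib_err("coords must be an n_atoms x 3 x n_frames array",
             "fibmod_ensemble_error")
  if (dim(coords)[1] != nrow(topology$atoms))
    .fib_err(sprintf("coordinate rows (%d) do not match topology atoms (%d)",
                     dim(coords)[1], nrow(topology$atoms)),
             "fibmod_topology_error")
  nf <- dim(coords)[3]
  if (!is.null(times)) {
    if (length(times) != nf)
      .fib_err("times length must equal frame count", "fibmod_ensemble_error")
    if (is.unsorted(times))
      .fib_err("frame times must be non-decreasing", "fibmod_ensemble_error")
  }
  if (!is.null(box)) {
    if (length(dim(box)) == 2L) box <- array(box, c(3L, 3L, nf))
    if (!all(dim(box) == c(3L, 3L, nf)))
      .fib_err("box must be 3x3 or 3x3xn_frames", "fibmod_ensemble_error")
  }
  if (!inherits(condition, "fib_condition")) condition <- ligand_condition(condition)
  structure(list(topology = topology, coords = coords, times = times,
                 box = box, condition = condition),
            class = "fib_ensemble")
}

#' Number of frames in an ensemble
#' @param ensemble a [fib_ensemble].
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Keep a subset of frames
#' @param ensemble a [fib_ensemble].
#' @param keep logical or integer frame index.
#' @return the subsetted ensemble.
#' @export
subset_frames <- function(ensemble, keep) {
  ensemble$coords <- ensemble$coords[, , keep, drop = FALSE]
  if (!is.null(ensemble$times)) ensemble$times <- ensemble$times[keep]
  if (!is.null(ensemble$box)) ensemble$box <- ensemble$box[, , keep, drop = FALSE]
  ensemble
}

#' @export
print.fib_ensemble <- function(x, ...) {
  cat("Conformational ensemble:", n_frames(x), "frames,",
      n_residues(x), "residues,", n_ligands(x), "ligand(s),",
      if (is.null(x$box)) "no box" else "periodic box", "\n")
  cat("  condition:", x$condition$label, "(ratio", x$condition$ratio, ")\n")
  invisible(x)
}

# frame spacing in ns; falls back to `default` when times are absent
.frame_dt <- function(ensemble, default = 1) {
  tt <- ensemble$times
  if (is.null(tt) || length(tt) < 2L) return(default)
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-6 * max(dt, 1e-12))
    warning("frame spacing is not uniform; using the mean")
  mean(dt)
}

# ---- readers ---------------------------------------------------------------

.parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  f <- cl[1L]
  num <- function(a, b) suppressWarnings(as.numeric(substr(f, a, b)))
  abc <- c(num(7, 15), num(16, 24), num(25, 33)) / 10  # Angstrom -> nm
  ang <- c(num(34, 40), num(41, 47), num(48, 54)) * pi / 180
  if (anyNA(abc) || anyNA(ang)) return(NULL)
  if (all(abs(abc) < 1e-9)) return(NULL)
  .cell_to_box(abc, ang)
}

# cell lengths (nm) + angles (rad) -> lower-triangular box vector rows
.cell_to_box <- function(abc, ang) {
  a <- abc[1]; b <- abc[2]; cc <- abc[3]
  al <- ang[1]; be <- ang[2]; ga <- ang[3]
  bx <- b * cos(ga); by <- b * sin(ga)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  zap <- function(v) ifelse(abs(v) < 1e-10, 0, v)
  rbind(c(a, 0, 0), zap(c(bx, by, 0)), zap(c(cx, cy, cz)))
}

#' Load a conformational ensemble from disk
#'
#' Reads a topology (PDB/mmCIF, or a JSON sidecar written by
#' [write_topology_json()]) and a trajectory (multi-model PDB or DCD, both in
#' Angstrom and converted to nm on read, or the plain-TSV dialect with columns
#' `frame, atom_id, x, y, z` already in nm).  Hydrogens are dropped; the
#' first `skip_frames` frames (equilibration) are discarded.
#'
#' @param topology_file path to `.json`, `.pdb` or `.cif`.
#' @param trajectory_file path to `.pdb`, `.dcd`, or `.tsv`.
#' @param condition a [ligand_condition()].
#' @param skip_frames number of leading frames to discard (a count, not a
#'   time; callers convert from the equilibration time they discard).
#' @param frame_dt optional frame spacing in ns used to synthesise times when
#'   the format carries none.
#' @return a [fib_ensemble].
#' @examples
#' sp <- generator_spec(seed = 7, chain_length = 8, n_frames = 6)
#' ens <- generate_ensemble(sp, ratio = 0)
#' d <- tempfile(); dir.create(d)
#' write_ensemble(ens, file.path(d, "traj.pdb"), file.path(d, "top.json"))
#' ens2 <- load_ensemble(file.path(d, "top.json"), file.path(d, "traj.pdb"),
#'                       condition = ligand_condition(0), skip_frames = 2)
#' n_frames(ens2)
#' @export
load_ensemble <- function(topology_file, trajectory_file,
                          condition = ligand_condition(0),
                          skip_frames = 0L, frame_dt = NULL) {
  for (f in c(topology_file, trajectory_file))
    if (!file.exists(f))
      .fib_err(paste0("file not found: ", f), "fibmod_io_error")
  topology <- switch(tolower(tools::file_ext(topology_file)),
    json = read_topology_json(topology_file),
    pdb = , ent = .topology_from_pdb(bio3d::read.pdb(topology_file))$topology,
    cif = .topology_from_pdb(bio3d::read.cif(topology_file))$topology,
    .fib_err("unsupported topology format", "fibmod_format_error"))

  ext <- tolower(tools::file_ext(trajectory_file))
  box <- NULL; times <- NULL
  if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(trajectory_file, multi = TRUE)
    sel <- match(topology$atoms$atom_id, pdb$atom$eleno)
    if (anyNA(sel))
      .fib_err("topology atom ids missing from trajectory (atom-count mismatch)",
               "fibmod_topology_error")
    nf <- nrow(pdb$xyz)
    coords <- array(NA_real_, c(nrow(topology$atoms), 3L, nf))
    for (f in seq_len(nf)) {
      X <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
      coords[, , f] <- X[sel, , drop = FALSE] / 10
    }
    b1 <- .parse_cryst1(readLines(trajectory_file, n = 500L))
    if (!is.null(b1)) box <- array(b1, c(3L, 3L, nf))
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(trajectory_file, verbose = FALSE)
    nf <- nrow(xyz)
    natom <- ncol(xyz) / 3L
    if (natom < nrow(topology$atoms))
      .fib_err("trajectory atom count smaller than topology (atom-count mismatch)",
               "fibmod_topology_error")
    sel <- match(topology$atoms$atom_id, seq_len(natom))
    coords <- array(NA_real_, c(nrow(topology$atoms), 3L, nf))
    for (f in seq_len(nf)) {
      X <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
      coords[, , f] <- X[sel, , drop = FALSE] / 10
    }
  } else if (ext %in% c("tsv", "txt", "dat")) {
    tab <- utils::read.table(trajectory_file, header = TRUE, sep = "\t",
                             comment.char = "#")
    need <- c("frame", "atom_id", "x", "y", "z")
    if (!all(need %in% names(tab)))
      .fib_err("TSV trajectory must have columns frame, atom_id, x, y, z",
               "fibmod_format_error")
    frames <- sort(unique(tab$frame))
    nf <- length(frames)
    coords <- array(NA_real_, c(nrow(topology$atoms), 3L, nf))
    for (f in seq_len(nf)) {
      sub <- tab[tab$frame == frames[f], , drop = FALSE]
      sel <- match(topology$atoms$atom_id, sub$atom_id)
      if (anyNA(sel))
        .fib_err("TSV trajectory missing atom ids declared by the topology",
                 "fibmod_topology_error")
      coords[, , f] <- as.matrix(sub[sel, c("x", "y", "z")])
    }
  } else {
    .fib_err(paste0("unsupported trajectory format: .", ext),
             "fibmod_format_error")
  }
  if (anyNA(coords))
    .fib_err("trajectory contains missing coordinates", "fibmod_format_error")
  nf <- dim(coords)[3]
  if (!is.null(frame_dt)) times <- (seq_len(nf) - 1L) * frame_dt
  ens <- fib_ensemble(topology, coords, times = times, box = box,
                      condition = condition)
  if (skip_frames > 0L) {
    if (skip_frames >= nf)
      .fib_err("skip_frames leaves no frames", "fibmod_ensemble_error")
    ens <- subset_frames(ens, seq.int(skip_frames + 1L, nf))
  }
  ens
}

# ---- writers ---------------------------------------------------------------

#' Write an ensemble to disk
#'
#' Multi-model PDB (coordinates converted to Angstrom, CRYST1 record when a
#' box is present) or the plain-TSV dialect (nm).  A JSON topology sidecar is
#' written alongside when `topology_file` is given.
#'
#' @param ensemble a [fib_ensemble].
#' @param trajectory_file output path (`.pdb` or `.tsv`).
#' @param topology_file optional path for the JSON topology sidecar.
#' @return `trajectory_file`, invisibly.
#' @export
write_ensemble <- function(ensemble, trajectory_file, topology_file = NULL) {
  stopifnot(inherits(ensemble, "fib_ensemble"))
  ext <- tolower(tools::file_ext(trajectory_file))
  a <- ensemble$topology$atoms
  off <- ensemble$topology$sequence_offset
  if (ext == "pdb") {
    nf <- n_frames(ensemble)
    nres <- n_residues(ensemble$topology)
    resno <- ifelse(a$role == "protein", a$mol + off, a$mol + off + nres)
    xyz <- matrix(NA_real_, nf, 3L * nrow(a))
    for (f in seq_len(nf))
      xyz[f, ] <- as.vector(t(ensemble$coords[, , f])) * 10
    if (!is.null(ensemble$box)) {
      b <- ensemble$box[, , 1] * 10
      la <- sqrt(rowSums(b^2))
      ang <- c(acos(sum(b[2, ] * b[3, ]) / (la[2] * la[3])),
               acos(sum(b[1, ] * b[3, ]) / (la[1] * la[3])),
               acos(sum(b[1, ] * b[2, ]) / (la[1] * la[2]))) * 180 / pi
      writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                         la[1], la[2], la[3], ang[1], ang[2], ang[3]),
                 trajectory_file)
      append <- TRUE
    } else append <- FALSE
    bio3d::write.pdb(file = trajectory_file, xyz = xyz, type = "ATOM",
                     resno = resno, resid = a$resname, eleno = a$atom_id,
                     elety = a$name, chain = a$chain, elesy = a$element,
                     append = append)
  } else if (ext %in% c("tsv", "txt")) {
    nf <- n_frames(ensemble)
    out <- do.call(rbind, lapply(seq_len(nf), function(f)
      data.frame(frame = f, atom_id = a$atom_id,
                 x = ensemble$coords[, 1, f], y = ensemble$coords[, 2, f],
                 z = ensemble$coords[, 3, f])))
    utils::write.table(out, trajectory_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    .fib_err("unsupported output trajectory format", "fibmod_format_error")
  }
  if (!is.null(topology_file))
    write_topology_json(ensemble$topology, topology_file)
  invisible(trajectory_file)
}
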