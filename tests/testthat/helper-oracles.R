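# Independent brute-force oracles and fixture builders.  The oracles use
# plain nested loops over atoms/frames/images on purpose: they must stay
# independent of the package's vectorised code paths.

# bead topology with n single-atom residues and optional single-atom ligands
make_bead_topology <- function(n, nlig = 0L, offset = 0L) {
  atoms <- data.frame(
    atom_id = seq_len(n + nlig),
    name = c(rep("CA", n), rep("C1", nlig)),
    element = "C",
    role = c(rep("protein", n), rep("ligand", nlig)),
    mol = c(seq_len(n), seq_len(max(nlig, 1L))[seq_len(nlig)]),
    resname = c(rep("ALA", n), rep("LIG", nlig)),
    chain = "A")
  fib_topology(atoms, sequence_offset = offset)
}

# topology with a variable number of heavy atoms per residue/ligand
make_multiatom_topology <- function(atoms_per_res, atoms_per_lig = integer(0)) {
  n <- length(atoms_per_res); nl <- length(atoms_per_lig)
  atoms <- data.frame(
    atom_id = seq_len(sum(atoms_per_res) + sum(atoms_per_lig)),
    name = "X",
    element = "C",
    role = c(rep("protein", sum(atoms_per_res)),
             rep("ligand", sum(atoms_per_lig))),
    mol = c(rep(seq_len(n), atoms_per_res), rep(seq_len(max(nl, 1L))[seq_len(nl)],
                                                atoms_per_lig)),
    resname = "ALA", chain = "A")
  fib_topology(atoms)
}

# a random ensemble: residues as loose atom clusters inside a box
random_ensemble <- function(seed, n_res, max_atoms = 5L, n_frames = 20L,
                            nlig = 0L, box_edge = NULL) {
  set.seed(seed)
  apr <- sample.int(max_atoms, n_res, replace = TRUE)
  apl <- if (nlig > 0L) sample.int(max_atoms, nlig, replace = TRUE)
         else integer(0)
  top <- make_multiatom_topology(apr, apl)
  na <- nrow(top$atoms)
  edge <- if (is.null(box_edge)) 3 else box_edge
  coords <- array(stats::runif(na * 3L * n_frames, 0, edge),
                  c(na, 3L, n_frames))
  box <- if (is.null(box_edge)) NULL else diag(rep(box_edge, 3L))
  fib_ensemble(top, coords, times = seq_len(n_frames) - 1, box = box)
}

# scalar minimum-image distance (orthorhombic), written out longhand
oracle_min_image_dist <- function(a, b, L) {
  if (is.null(L)) return(sqrt(sum((a - b)^2)))
  d <- a - b
  for (k in 1:3) d[k] <- d[k] - L[k] * round(d[k] / L[k])
  sqrt(sum(d^2))
}

# brute-force contact map: loops over frames, residue pairs, atom pairs
oracle_contact_map <- function(ensemble, cutoff = 0.45, min_separation = 4L) {
  top <- ensemble$topology
  nres <- length(top$res_atoms)
  nf <- dim(ensemble$coords)[3]
  L <- if (is.null(ensemble$box)) NULL else diag(ensemble$box[, , 1])
  P <- matrix(0, nres, nres)
  for (f in seq_len(nf)) {
    for (i in seq_len(nres - 1L)) for (j in seq.int(i + 1L, nres)) {
      if (j - i < min_separation) next
      hit <- FALSE
      for (ai in top$res_atoms[[i]]) {
        for (aj in top$res_atoms[[j]]) {
          if (oracle_min_image_dist(ensemble$coords[ai, , f],
                                    ensemble$coords[aj, , f], L) < cutoff) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (hit) P[i, j] <- P[i, j] + 1
    }
  }
  P / nf
}

# dense matrix view of a sparse contact map, zeros for absent pairs
map_as_dense <- function(map) {
  m <- matrix(0, map$n_residues, map$n_residues)
  if (nrow(map$pairs)) m[cbind(map$pairs$i, map$pairs$j)] <- map$pairs$p
  m
}

# brute-force periodic-image violation flags over the 26 neighbour images
oracle_image_flags <- function(ensemble, threshold = 0.3) {
  prot <- which(ensemble$topology$atoms$role == "protein")
  nf <- dim(ensemble$coords)[3]
  flags <- logical(nf)
  for (f in seq_len(nf)) {
    X <- matrix(ensemble$coords[prot, , f], ncol = 3L)
    box <- ensemble$box[, , f]
    dmin <- Inf
    for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
      if (n1 == 0 && n2 == 0 && n3 == 0) next
      s <- n1 * box[1, ] + n2 * box[2, ] + n3 * box[3, ]
      for (a in seq_len(nrow(X))) for (b in seq_len(nrow(X))) {
        d <- sqrt(sum((X[a, ] - X[b, ] - s)^2))
        if (d < dmin) dmin <- d
      }
    }
    flags[f] <- dmin < threshold
  }
  flags
}

# brute-force per-frame ligand-residue contact counts (triple loop)
oracle_ligand_counts <- function(ensemble, cutoff = 0.45) {
  top <- ensemble$topology
  nres <- length(top$res_atoms); nlig <- length(top$lig_atoms)
  nf <- dim(ensemble$coords)[3]
  L <- if (is.null(ensemble$box)) NULL else diag(ensemble$box[, , 1])
  out <- matrix(0, nres, nf)
  for (f in seq_len(nf)) for (r in seq_len(nres)) for (l in seq_len(nlig)) {
    hit <- FALSE
    for (ar in top$res_atoms[[r]]) for (al in top$lig_atoms[[l]]) {
      if (oracle_min_image_dist(ensemble$coords[ar, , f],
                                ensemble$coords[al, , f], L) < cutoff)
        hit <- TRUE
    }
    if (hit) out[r, f] <- out[r, f] + 1
  }
  out
}

# brute-force ligand-mediated contact probabilities over (i, ligand, j)
oracle_mediated <- function(ensemble, cutoff = 0.6, min_separation = 4L) {
  top <- ensemble$topology
  nres <- length(top$res_atoms); nlig <- length(top$lig_atoms)
  nf <- dim(ensemble$coords)[3]
  L <- if (is.null(ensemble$box)) NULL else diag(ensemble$box[, , 1])
  near <- function(r, l, f) {
    for (ar in top$res_atoms[[r]]) for (al in top$lig_atoms[[l]])
      if (oracle_min_image_dist(ensemble$coords[ar, , f],
                                ensemble$coords[al, , f], L) < cutoff)
        return(TRUE)
    FALSE
  }
  P <- matrix(0, nres, nres)
  for (f in seq_len(nf)) {
    for (i in seq_len(nres - 1L)) for (j in seq.int(i + 1L, nres)) {
      if (j - i < min_separation) next
      for (l in seq_len(nlig)) {
        if (near(i, l, f) && near(j, l, f)) {
          P[i, j] <- P[i, j] + 1
          break
        }
      }
    }
  }
  P / nf
}

# static-coordinate ensemble builder (same coords every frame unless given)
make_ensemble_from_coords <- function(coords, n_frames = 1L, nlig = 0L,
                                      box = NULL, times = NULL) {
  n <- nrow(coords) - nlig
  top <- make_bead_topology(n, nlig)
  arr <- array(rep(as.numeric(coords), n_frames),
               c(nrow(coords), 3L, n_frames))
  fib_ensemble(top, arr, times = times, box = box)
}

# minimal mmCIF rendering of a CA trace (synthetic test fixture)
write_cif_trace <- function(X_nm, file, resno = seq_len(nrow(X_nm))) {
  hdr <- c("data_synthetic", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  A <- X_nm * 10
  rows <- sprintf(
    "ATOM %d C CA . ALA A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA A CA 1",
    seq_len(nrow(A)), resno, A[, 1], A[, 2], A[, 3], resno)
  writeLines(c(hdr, rows, "#"), file)
  invisible(file)
}

# long-hand OLS slope used as the regression oracle
oracle_ols <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}
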