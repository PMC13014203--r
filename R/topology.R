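#' Construct a topology
#'
#' A topology declares the heavy atoms of a protein chain and of any ligand
#' molecules, and carries the residue-numbering convention.  Local residue
#' indices are 1-based and contiguous; `sequence_offset` maps a local index to
#' full-length isoform numbering (e.g. the K18 Tau fragment uses local 1..129
#' with offset 243 so that reported residue numbers run 244--372).
#'
#' @param atoms data.frame with one row per heavy atom and columns
#'   `atom_id` (unique integer), `name` (atom name, e.g. `"CA"`),
#'   `element` (element symbol), `role` (`"protein"` or `"ligand"`),
#'   `mol` (1-based residue index for protein atoms; 1-based ligand molecule
#'   index for ligand atoms), `resname`, `chain`.
#' @param sequence_offset integer added to local residue indices for reporting.
#' @return An object of class `fib_topology`.
#' @examples
#' atoms <- data.frame(atom_id = 1:3, name = "CA", element = "C",
#'                     role = "protein", mol = 1:3, resname = "GLY",
#'                     chain = "A")
#' top <- fib_topology(atoms, sequence_offset = 243L)
#' n_residues(top)
#' @export
fib_topology <- function(atoms, sequence_offset = 0L) {
  need <- c("atom_id", "name", "element", "role", "mol", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    .fib_err(paste0("topology atoms missing column(s): ",
                    paste(miss, collapse = ", ")), "fibmod_topology_error")
  atoms <- as.data.frame(atoms)[, need]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$mol <- as.integer(atoms$mol)
  if (anyDuplicated(atoms$atom_id))
    .fib_err("atom ids must be unique across residues and ligands",
             "fibmod_topology_error")
  if (!all(atoms$role %in% c("protein", "ligand")))
    .fib_err("atom role must be 'protein' or 'ligand'", "fibmod_topology_error")
  # drop hydrogens: analyses use heavy atoms only
  is_h <- atoms$element %in% c("H", "D") | grepl("^[0-9]*H", atoms$name)
  if (any(is_h)) atoms <- atoms[!is_h, , drop = FALSE]
  prot <- atoms[atoms$role == "protein", , drop = FALSE]
  if (nrow(prot) == 0L)
    .fib_err("topology declares no protein atoms", "fibmod_topology_error")
  res_ids <- sort(unique(prot$mol))
  if (!identical(res_ids, seq_along(res_ids)))
    .fib_err("protein residue indices must be 1-based and contiguous",
             "fibmod_topology_error")
  lig <- atoms[atoms$role == "ligand", , drop = FALSE]
  lig_ids <- sort(unique(lig$mol))
  if (nrow(lig) && !identical(lig_ids, seq_along(lig_ids)))
    .fib_err("ligand indices must be 1-based and contiguous",
             "fibmod_topology_error")
  rownames(atoms) <- NULL
  out <- structure(list(atoms = atoms,
                        sequence_offset = as.integer(sequence_offset)),
                   class = "fib_topology")
  # cache row-index groups; every distance routine uses them
  row_of <- seq_len(nrow(atoms))
  out$res_atoms <- split(row_of[atoms$role == "protein"],
                         atoms$mol[atoms$role == "protein"])
  out$lig_atoms <- if (nrow(lig))
    split(row_of[atoms$role == "ligand"], atoms$mol[atoms$role == "ligand"])
  else list()
  out$masses <- .element_mass(atoms$element)
  out
}

#' @export
print.fib_topology <- function(x, ...) {
  cat("Topology:", n_residues(x), "protein residues,",
      length(x$lig_atoms), "ligand molecule(s),",
      nrow(x$atoms), "heavy atoms\n")
  cat("  residue numbering: local 1..", n_residues(x), " + offset ",
      x$sequence_offset, " (full ", x$sequence_offset + 1L, "..",
      x$sequence_offset + n_residues(x), ")\n", sep = "")
  invisible(x)
}

#' Number of protein residues in a topology or ensemble
#' @param x a `fib_topology` or `fib_ensemble`.
#' @return integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "fib_ensemble")) x <- x$topology
  length(x$res_atoms)
}

#' Number of ligand molecules in a topology or ensemble
#' @param x a `fib_topology` or `fib_ensemble`.
#' @return integer ligand count.
#' @export
n_ligands <- function(x) {
  if (inherits(x, "fib_ensemble")) x <- x$topology
  length(x$lig_atoms)
}

# standard atomic masses for Rg weighting; unknown elements fall back to carbon
.element_mass <- function(element) {
  tab <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
           SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, NA. = 22.990,
           CL = 35.45, K = 39.098, CA = 40.078, H = 1.008)
  m <- tab[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

# local residue index of the CA atom rows, NA when a residue has no CA
.calpha_rows <- function(topology) {
  a <- topology$atoms
  vapply(topology$res_atoms, function(ix) {
    ca <- ix[a$name[ix] == "CA"]
    if (length(ca)) ca[1L] else NA_integer_
  }, integer(1))
}

#' Read or write a topology JSON sidecar
#'
#' The sidecar is a JSON rendering of the atom table plus the sequence
#' offset, used alongside plain-TSV or PDB trajectories.
#'
#' @param file path to a JSON file.
#' @param topology a `fib_topology` (for writing).
#' @return `read_topology_json()` returns a `fib_topology`;
#'   `write_topology_json()` returns `file` invisibly.
#' @export
read_topology_json <- function(file) {
  if (!file.exists(file))
    .fib_err(paste0("topology file not found: ", file), "fibmod_io_error")
  j <- jsonlite::fromJSON(file)
  fib_topology(as.data.frame(j$atoms),
               sequence_offset = if (is.null(j$sequence_offset)) 0L
                                 else as.integer(j$sequence_offset))
}

#' @rdname read_topology_json
#' @export
write_topology_json <- function(topology, file) {
  stopifnot(inherits(topology, "fib_topology"))
  jsonlite::write_json(list(atoms = topology$atoms,
                            sequence_offset = topology$sequence_offset),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

# Build a topology from a bio3d pdb object.  Protein = amino-acid residues;
# everything else except water/ions becomes a ligand molecule (one molecule
# per distinct residue instance).
.topology_from_pdb <- function(pdb, sequence_offset = NULL,
                               ligand_resnames = NULL) {
  a <- pdb$atom
  aa3 <- bio3d::aa.table$aa3
  skip <- c("HOH", "WAT", "SOL", "NA", "CL", "K", "MG", "ZN", "CA2", "IOD")
  is_prot <- a$resid %in% aa3
  is_lig <- if (is.null(ligand_resnames)) !is_prot & !(a$resid %in% skip)
            else a$resid %in% ligand_resnames
  keep <- is_prot | is_lig
  a <- a[keep, , drop = FALSE]
  is_prot <- is_prot[keep]
  # residue instances in order of appearance
  rkey <- paste(a$chain, a$resno, a$insert, sep = "|")
  prot_keys <- unique(rkey[is_prot])
  lig_keys <- unique(rkey[!is_prot])
  mol <- integer(nrow(a))
  mol[is_prot] <- match(rkey[is_prot], prot_keys)
  mol[!is_prot] <- match(rkey[!is_prot], lig_keys)
  if (is.null(sequence_offset)) {
    first_resno <- a$resno[is_prot][1L]
    sequence_offset <- if (length(first_resno)) first_resno - 1L else 0L
  }
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("^[0-9]+", "", a$elety), 1L, 1L)
  atoms <- data.frame(atom_id = a$eleno, name = a$elety, element = elem,
                      role = ifelse(is_prot, "protein", "ligand"),
                      mol = mol, resname = a$resid, chain = a$chain,
                      stringsAsFactors = FALSE)
  list(topology = fib_topology(atoms, sequence_offset = sequence_offset),
       kept_eleno = a$eleno)
}
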