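# Fibril reference structures: parse deposited fibril models, pull one
# monomer, extract its intrachain native contacts and cluster polymorphs by
# shared contacts.

#' Load one monomer from a fibril structure
#'
#' Reads a PDB or mmCIF atomic model of an amyloid filament and extracts a
#' single protein chain as the representative monomer.  Under
#' `chain_policy = "central"` the chain whose centroid lies nearest the
#' assembly centroid is chosen (an interior protofilament layer, avoiding
#' stack-edge effects); `"first"` takes the first protein chain;
#' `"explicit"` requires `chain_id`.  Hydrogens are dropped and coordinates
#' converted to nm.  `renumber_offset` is added to author residue numbers to
#' express contacts in full-length isoform numbering.
#'
#' @param file PDB or mmCIF path.
#' @param chain_policy `"central"`, `"first"` or `"explicit"`.
#' @param chain_id chain identifier, for `chain_policy = "explicit"`.
#' @param renumber_offset integer added to author residue numbers.
#' @param structure_id identifier; defaults to the file base name.
#' @return object of class `fib_fibril`: residue table, heavy-atom
#'   coordinates (nm), per-residue atom groups, `full_resno`,
#'   `source_chain`, `resolved_range`.
#' @export
load_fibril_structure <- function(file,
                                  chain_policy = c("central", "first",
                                                   "explicit"),
                                  chain_id = NULL, renumber_offset = 0L,
                                  structure_id = NULL) {
  chain_policy <- match.arg(chain_policy)
  if (!file.exists(file))
    .fib_err(paste0("file not found: ", file), "fibmod_io_error")
  if (is.null(structure_id))
    structure_id <- tools::file_path_sans_ext(basename(file))
  ext <- tolower(tools::file_ext(file))
  pdb <- switch(ext,
    pdb = , ent = bio3d::read.pdb(file),
    cif = suppressWarnings(bio3d::read.cif(file)),
    .fib_err("unsupported structure format", "fibmod_format_error"))
  a <- pdb$atom
  aa3 <- bio3d::aa.table$aa3
  a <- a[a$resid %in% aa3 & a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  is_h <- (!is.na(a$elesy) & a$elesy %in% c("H", "D")) |
    grepl("^[0-9]*H", a$elety)
  a <- a[!is_h, , drop = FALSE]
  if (!nrow(a))
    .fib_err("no protein chain found in structure", "fibmod_empty_structure_error")
  chains <- unique(a$chain)
  chain <- switch(chain_policy,
    first = chains[1L],
    explicit = {
      if (is.null(chain_id) || !(chain_id %in% chains))
        .fib_err(paste0("chain '", chain_id, "' not present in structure"),
                 "fibmod_empty_structure_error")
      chain_id
    },
    central = {
      all_xyz <- cbind(a$x, a$y, a$z)
      gc <- colMeans(all_xyz)
      d <- vapply(chains, function(ch) {
        cm <- colMeans(all_xyz[a$chain == ch, , drop = FALSE])
        sum((cm - gc)^2)
      }, numeric(1))
      chains[which.min(d)]
    })
  a <- a[a$chain == chain, , drop = FALSE]
  ord <- order(a$resno)
  a <- a[ord, , drop = FALSE]
  coords <- cbind(a$x, a$y, a$z) / 10
  resno <- unique(a$resno)
  res_atoms <- split(seq_len(nrow(a)), match(a$resno, resno))
  full_resno <- resno + as.integer(renumber_offset)
  residues <- data.frame(resno_full = full_resno,
                         resname = a$resid[match(resno, a$resno)])
  structure(list(structure_id = structure_id, residues = residues,
                 coords = coords, res_atoms = res_atoms,
                 full_resno = full_resno, source_chain = chain,
                 resolved_range = range(full_resno)),
            class = "fib_fibril")
}

#' @export
print.fib_fibril <- function(x, ...) {
  cat(sprintf("Fibril monomer %s: chain %s, residues %d-%d (%d resolved, %d heavy atoms)\n",
              x$structure_id, x$source_chain, x$resolved_range[1],
              x$resolved_range[2], nrow(x$residues), nrow(x$coords)))
  invisible(x)
}

#' Extract fibril-native intrachain contacts from a monomer
#'
#' Applies the same residue-residue rule as [compute_contact_map()] (minimum
#' heavy-atom distance below `cutoff`, sequence separation in full-length
#' numbering at least `min_separation`) to the single monomer conformation,
#' so fibril-native pairs and ensemble pairs live in one universe.
#'
#' @param structure a [load_fibril_structure()] result.
#' @param cutoff nm; default 0.45 matches the ensemble contact definition.
#' @param min_separation sequence-separation floor; default 4.
#' @return object of class `fib_native_contacts`: `contacts` data.frame
#'   (`i_full, j_full`), `structure_id`, `cutoff`, `min_separation`,
#'   `resolved_range`.
#' @export
extract_native_contacts <- function(structure, cutoff = 0.45,
                                    min_separation = 4L) {
  stopifnot(inherits(structure, "fib_fibril"))
  nres <- length(structure$res_atoms)
  if (!nres)
    .fib_err("empty structure", "fibmod_empty_structure_error")
  M <- matrix(0, nrow(structure$coords), nres)
  for (r in seq_len(nres)) M[structure$res_atoms[[r]], r] <- 1
  A <- .cross_dist2(structure$coords, structure$coords) < cutoff^2
  cmat <- crossprod(M, A %*% M) > 0
  ut <- which(upper.tri(cmat) & cmat, arr.ind = TRUE)
  fi <- structure$full_resno[ut[, 1]]
  fj <- structure$full_resno[ut[, 2]]
  keep <- (fj - fi) >= min_separation
  contacts <- data.frame(i_full = fi[keep], j_full = fj[keep])
  contacts <- contacts[order(contacts$i_full, contacts$j_full), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(structure_id = structure$structure_id, contacts = contacts,
                 cutoff = cutoff, min_separation = as.integer(min_separation),
                 resolved_range = structure$resolved_range),
            class = "fib_native_contacts")
}

#' Build a native contact set from an explicit pair list
#' @param structure_id identifier.
#' @param pairs data.frame or 2-column matrix of residue pairs
#'   (full numbering, `i < j`).
#' @param cutoff,min_separation metadata, as in [extract_native_contacts()].
#' @return a `fib_native_contacts`.
#' @export
native_contact_set <- function(structure_id, pairs, cutoff = 0.45,
                               min_separation = 4L) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("i_full", "j_full")
  if (any(pairs$j_full - pairs$i_full < min_separation))
    .fib_err("native pairs below the separation floor", "fibmod_contact_error")
  pairs <- pairs[order(pairs$i_full, pairs$j_full), 1:2, drop = FALSE]
  rownames(pairs) <- NULL
  rng <- if (nrow(pairs)) range(c(pairs$i_full, pairs$j_full)) else c(NA, NA)
  structure(list(structure_id = structure_id, contacts = pairs,
                 cutoff = cutoff, min_separation = as.integer(min_separation),
                 resolved_range = rng),
            class = "fib_native_contacts")
}

#' @export
print.fib_native_contacts <- function(x, ...) {
  cat(sprintf("Native contacts %s: %d pairs (cutoff %.2f nm, |i-j| >= %d)\n",
              x$structure_id, nrow(x$contacts), x$cutoff, x$min_separation))
  invisible(x)
}

.pair_keys <- function(set) paste(set$contacts$i_full, set$contacts$j_full)

#' Cluster fibril structures by shared intrachain contacts
#'
#' Builds a graph with one node per structure and an edge whenever a pair of
#' structures shares at least `min_shared` native contacts (or reaches
#' `min_jaccard` on the Jaccard index of their contact sets, if given);
#' clusters are the connected components.  Structures sharing no contact with
#' any other under the default rule come out as singletons, matching the
#' notion of unique polymorphs.
#'
#' @param sets list of [extract_native_contacts()] results in a common
#'   residue numbering.
#' @param min_shared minimum shared-contact count for an edge (default 1).
#' @param min_jaccard optional Jaccard threshold overriding `min_shared`.
#' @return object of class `fib_clustering`: `clusters` (list of member-id
#'   vectors, largest first), `membership` (named integer), `similarity`
#'   (data.frame `id_a, id_b, shared, jaccard`), `edge_rule`, `n_structures`.
#' @export
cluster_fibrils <- function(sets, min_shared = 1L, min_jaccard = NULL) {
  if (!length(sets))
    .fib_err("at least one contact set required", "fibmod_cluster_error")
  ids <- vapply(sets, function(s) s$structure_id, character(1))
  if (anyDuplicated(ids))
    .fib_err("structure ids must be unique", "fibmod_cluster_error")
  keys <- lapply(sets, .pair_keys)
  n <- length(sets)
  pairs <- if (n > 1L) utils::combn(n, 2L) else matrix(integer(0), 2L, 0L)
  sim <- data.frame(id_a = character(0), id_b = character(0),
                    shared = integer(0), jaccard = numeric(0))
  if (ncol(pairs)) {
    shared <- integer(ncol(pairs)); jac <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      a <- keys[[pairs[1, k]]]; b <- keys[[pairs[2, k]]]
      s <- length(intersect(a, b)); u <- length(union(a, b))
      shared[k] <- s
      jac[k] <- if (u) s / u else 0
    }
    sim <- data.frame(id_a = ids[pairs[1, ]], id_b = ids[pairs[2, ]],
                      shared = shared, jaccard = jac)
  }
  if (n > 1L && all(sim$shared == 0L))
    warning("no shared contacts between any pair of structures; ",
            "all clusters will be singletons (disjoint numbering ranges?)")
  edge <- if (is.null(min_jaccard)) sim$shared >= min_shared
          else sim$jaccard >= min_jaccard
  g <- igraph::graph_from_data_frame(sim[edge, c("id_a", "id_b"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  membership <- comp$membership[ids]
  clusters <- split(ids, membership)
  clusters <- lapply(clusters, function(x) sort(x))
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1L))
  clusters <- unname(clusters[ord])
  membership <- stats::setNames(rep(seq_along(clusters), lengths(clusters)),
                                unlist(clusters))[ids]
  edge_rule <- if (is.null(min_jaccard))
    sprintf("min_shared >= %d", min_shared)
  else sprintf("min_jaccard >= %g", min_jaccard)
  structure(list(clusters = clusters, membership = membership,
                 similarity = sim, edge_rule = edge_rule,
                 n_structures = n),
            class = "fib_clustering")
}

#' @export
print.fib_clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("Fibril clustering: %d structures -> %d clusters (%s); sizes: %s\n",
              x$n_structures, length(x$clusters), x$edge_rule,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Consensus contacts within a cluster
#'
#' Contacts present in at least `min_frac` of the cluster members.
#'
#' @param clustering a [cluster_fibrils()] result.
#' @param sets the contact sets that were clustered.
#' @param cluster index of the cluster.
#' @param min_frac minimum member fraction (default 0.5).
#' @return data.frame `i_full, j_full, frac`.
#' @export
consensus_contacts <- function(clustering, sets, cluster, min_frac = 0.5) {
  ids <- vapply(sets, function(s) s$structure_id, character(1))
  members <- clustering$clusters[[cluster]]
  keys <- unlist(lapply(sets[match(members, ids)], .pair_keys))
  tab <- table(keys) / length(members)
  keep <- tab >= min_frac
  if (!any(keep)) return(data.frame(i_full = integer(0), j_full = integer(0),
                                    frac = numeric(0)))
  ij <- do.call(rbind, strsplit(names(tab)[keep], " "))
  out <- data.frame(i_full = as.integer(ij[, 1]), j_full = as.integer(ij[, 2]),
                    frac = as.numeric(tab[keep]))
  out[order(out$i_full, out$j_full), ]
}

#' Read a fibril manifest and load/cluster its structures
#'
#' The manifest is a TSV with columns `file, structure_id, chain_policy,
#' renumber_offset` (paths relative to the manifest location).
#'
#' @param manifest path to the manifest TSV.
#' @param cutoff,min_separation contact extraction parameters.
#' @return list with `structures`, `contact_sets` and `clustering`.
#' @export
load_fibril_manifest <- function(manifest, cutoff = 0.45, min_separation = 4L) {
  tab <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("file", "structure_id", "chain_policy", "renumber_offset")
  if (!all(need %in% names(tab)))
    .fib_err("fibril manifest needs columns file, structure_id, chain_policy, renumber_offset",
             "fibmod_format_error")
  base <- dirname(manifest)
  structures <- lapply(seq_len(nrow(tab)), function(r) {
    f <- tab$file[r]
    if (!file.exists(f)) f <- file.path(base, tab$file[r])
    load_fibril_structure(f, chain_policy = tab$chain_policy[r],
                          renumber_offset = tab$renumber_offset[r],
                          structure_id = tab$structure_id[r])
  })
  sets <- lapply(structures, extract_native_contacts, cutoff = cutoff,
                 min_separation = min_separation)
  list(structures = structures, contact_sets = sets,
       clustering = cluster_fibrils(sets))
}

#' Write clustering results as JSON
#' @param clustering a [cluster_fibrils()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_clustering_json <- function(clustering, file) {
  jsonlite::write_json(list(clusters = clustering$clusters,
                            similarity = clustering$similarity,
                            edge_rule = clustering$edge_rule,
                            n_structures = clustering$n_structures),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
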