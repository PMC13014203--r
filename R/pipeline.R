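# Manifest-driven pipeline: QC -> contact maps -> deltas -> modulation ->
# binding -> chain metrics -> ThT fits, with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis protocol with the standard
#' defaults: 0.45 nm heavy-atom contact cutoff, 0.6 nm ligand-mediated
#' cutoff, 0.45/0.6 nm twin cutoffs for hysteretic contact and binding
#' events, 0.3 nm periodic-image QC threshold, sequence-separation floor 4,
#' four averaging blocks and a fixed 0.55 nm Flory prefactor.
#'
#' @param contact_cutoff,mediated_cutoff,r_on,r_off,qc_threshold distances
#'   in nm.
#' @param min_separation sequence-separation floor.
#' @param n_blocks block count for R_g error estimation.
#' @param flory_prefactor nm; `flory_fit_range` optional `(s_min, s_max)`.
#' @param regions optional data.frame `name, start, end` of sequence-region
#'   annotations (full numbering) for modulation reports.
#' @param sign_threshold modulation classification threshold.
#' @param n_boot,seed bootstrap settings for ThT fits.
#' @param output_dir where [run_pipeline()] writes its reports.
#' @return object of class `fib_run_config`.
#' @export
run_config <- function(contact_cutoff = 0.45, mediated_cutoff = 0.6,
                       r_on = 0.45, r_off = 0.6, qc_threshold = 0.3,
                       min_separation = 4L, n_blocks = 4L,
                       flory_prefactor = 0.55, flory_fit_range = NULL,
                       regions = NULL, sign_threshold = 0,
                       n_boot = 1000L, seed = 1L,
                       output_dir = "fibmod_out") {
  structure(list(contact_cutoff = contact_cutoff,
                 mediated_cutoff = mediated_cutoff,
                 r_on = r_on, r_off = r_off, qc_threshold = qc_threshold,
                 min_separation = as.integer(min_separation),
                 n_blocks = as.integer(n_blocks),
                 flory_prefactor = flory_prefactor,
                 flory_fit_range = flory_fit_range,
                 regions = regions, sign_threshold = sign_threshold,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "fib_run_config")
}

#' Run the full analysis pipeline from a condition manifest
#'
#' The manifest is a TSV with columns `condition_label, ratio, topology,
#' trajectory, skip_frames` (paths relative to the manifest).  Per
#' condition: load, periodic-image QC (frames flagged below the threshold
#' are excluded), contact map, radius of gyration, Flory fit, and -- when
#' ligands are declared -- binding profile and mediated contact map.  Across
#' conditions: contact deltas against the lowest-ratio condition and, when a
#' fibril manifest is given, contact-modulation maps per fibril structure
#' plus the polymorph clustering.  A kinetics CSV adds ThT logistic fits and
#' a dose-response table.  All reports land in `config$output_dir` together
#' with a JSON run manifest recording the resolved configuration and input
#' MD5 hashes.
#'
#' @param config a [run_config()].
#' @param manifest path to the condition manifest TSV.
#' @param fibril_manifest optional fibril manifest TSV (see
#'   [load_fibril_manifest()]).
#' @param kinetics_csv optional plate-reader CSV (see [read_tht_csv()]).
#' @return (invisibly) a list with the in-memory results: `maps`, `deltas`,
#'   `qc`, `rg`, `flory`, `binding`, `mediated`, `modulation`, `clustering`,
#'   `tht`, `output_dir`.
#' @export
run_pipeline <- function(config, manifest, fibril_manifest = NULL,
                         kinetics_csv = NULL) {
  stopifnot(inherits(config, "fib_run_config"))
  if (!file.exists(manifest))
    .fib_err(paste0("manifest not found: ", manifest), "fibmod_io_error")
  tab <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("condition_label", "ratio", "topology", "trajectory",
            "skip_frames")
  if (!all(need %in% names(tab)) || nrow(tab) == 0L)
    .fib_err("manifest must be non-empty with columns condition_label, ratio, topology, trajectory, skip_frames",
             "fibmod_validation_error")
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  tab$topology <- resolve(tab$topology)
  tab$trajectory <- resolve(tab$trajectory)
  inputs <- c(tab$topology, tab$trajectory, fibril_manifest, kinetics_csv)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    .fib_err(paste0("missing input file(s): ", paste(missing, collapse = ", ")),
             "fibmod_validation_error")

  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  res <- list(maps = list(), deltas = list(), qc = list(), rg = list(),
              flory = list(), binding = list(), mediated = list(),
              modulation = list(), clustering = NULL, tht = NULL,
              output_dir = out)

  for (r in seq_len(nrow(tab))) {
    lab <- tab$condition_label[r]
    ens <- load_ensemble(tab$topology[r], tab$trajectory[r],
                         condition = ligand_condition(tab$ratio[r], lab),
                         skip_frames = tab$skip_frames[r])
    if (!is.null(ens$box)) {
      qc <- periodic_image_violation_fraction(ens, config$qc_threshold)
      write_qc_json(qc, file.path(out, paste0("qc_", lab, ".json")))
      res$qc[[lab]] <- qc
      ens <- subset_frames(ens, !qc$flags)
    }
    message(sprintf("[%s] %d frames, %d residues, %d ligand(s)",
                    lab, n_frames(ens), n_residues(ens), n_ligands(ens)))
    cm <- compute_contact_map(ens, config$contact_cutoff,
                              config$min_separation)
    write_contact_tsv(cm, file.path(out, paste0("contacts_", lab, ".tsv")))
    res$maps[[lab]] <- cm
    rg <- radius_of_gyration(ens, n_blocks = config$n_blocks)
    write_metric_tsv(rg, file.path(out, paste0("rg_", lab, ".tsv")))
    res$rg[[lab]] <- rg
    fl <- flory_fit(ens, prefactor = config$flory_prefactor,
                    fit_range = config$flory_fit_range)
    write_metric_tsv(fl, file.path(out, paste0("flory_", lab, ".tsv")))
    res$flory[[lab]] <- fl
    if (n_ligands(ens) > 0L) {
      bp <- ligand_count_profile(ens, config$contact_cutoff)
      write_binding_tsv(bp, file.path(out, paste0("nligand_", lab, ".tsv")))
      res$binding[[lab]] <- bp
      mm <- mediated_contact_map(ens, config$mediated_cutoff,
                                 config$min_separation)
      write_contact_tsv(mm, file.path(out, paste0("mediated_", lab, ".tsv")))
      res$mediated[[lab]] <- mm
    }
  }

  ratios <- vapply(res$maps, function(m) m$condition$ratio, numeric(1))
  ref <- which.min(ratios)
  for (lab in names(res$maps)[-ref]) {
    dl <- contact_delta(res$maps[[lab]], res$maps[[ref]])
    write_contact_tsv(dl, file.path(out, paste0("delta_", lab, "_vs_",
                                                names(res$maps)[ref], ".tsv")))
    res$deltas[[lab]] <- dl
  }

  if (!is.null(fibril_manifest)) {
    fib <- load_fibril_manifest(fibril_manifest,
                                cutoff = config$contact_cutoff,
                                min_separation = config$min_separation)
    res$clustering <- fib$clustering
    write_clustering_json(fib$clustering, file.path(out, "clustering.json"))
    if (length(unique(ratios)) >= 2L) {
      series <- ratio_series(res$maps)
      for (ns in fib$contact_sets) {
        mod <- tryCatch(modulation_coefficients(series, ns),
                        error = function(e) NULL)
        if (is.null(mod)) next
        rep_ <- modulation_map_report(mod, config$sign_threshold,
                                      config$regions)
        write_modulation_tsv(rep_, file.path(out,
          paste0("modulation_", ns$structure_id, ".tsv")))
        res$modulation[[ns$structure_id]] <- rep_
      }
    }
  }

  if (!is.null(kinetics_csv)) {
    datasets <- read_tht_csv(kinetics_csv)
    fits <- lapply(datasets, fit_logistic, n_boot = config$n_boot,
                   seed = config$seed)
    summ <- dose_response_summary(fits)
    utils::write.table(summ, file.path(out, "tht_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$tht <- list(fits = fits, summary = summ)
  }

  cfg <- unclass(config)
  cfg$regions <- NULL
  jsonlite::write_json(
    list(config = cfg,
         inputs = as.list(tools::md5sum(inputs)),
         conditions = tab$condition_label,
         outputs = list.files(out)),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
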