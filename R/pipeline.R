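## End-to-end pipeline: input (or simulation) -> QC -> foreground ->
## ordering -> segmentation and/or double-pulse speed estimation, with
## one master seed and per-stage TSV/BED artifacts.

.pipeline_keys <- c("seed", "input", "simulate", "qc", "order", "segment",
                    "speed", "out_dir")

#' Default pipeline configuration
#'
#' Returns the full configuration list with default parameters; fields
#' mirror the stage functions' arguments.  Either \code{input} (a
#' molecule-table path plus a chrom.sizes path) or \code{simulate}
#' (cohort settings) must be supplied by the caller.
#'
#' @return named list.
#' @export
pipelineConfig <- function() {
  list(
    seed = 1L,
    input = NULL,     # list(path=, chrom_sizes=, one_based=FALSE)
    simulate = list(n_cells = 12, n_forks = 60, gap = 60,
                    labeling = "double", speed_mu = 1, speed_sigma = 0.1,
                    sampling_rate = 0.3, background_rate = 0.002,
                    chrom_length = 3e7, n_chrom = 2),
    qc = list(enabled = TRUE, dispersion_threshold = 0.1),
    order = list(enabled = TRUE, n_runs = 100, spearman_cutoff = 0.85,
                 cluster_gap = 0.1, cluster_frac = 0.8),
    segment = list(enabled = TRUE, min_reads = 2),
    speed = list(enabled = TRUE, delta_t = NULL, bootstrap = 0),
    out_dir = "replifork_out")
}

.merge_config <- function(base, user) {
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      bad2 <- setdiff(names(user[[k]]), names(base[[k]]))
      if (length(bad2))
        stop("unknown key(s) in '", k, "': ", paste(bad2, collapse = ", "))
      base[[k]][names(user[[k]])] <- user[[k]]
    } else base[[k]] <- user[[k]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Deterministic given the configured seed.  Stages: load or simulate a
#' molecule table; per-cell QC; foreground selection; S-phase ordering;
#' HSMM track segmentation with fork counts (single-pulse or always
#' when enabled); pair-correlation speed estimation (double-pulse
#' cells).  Artifacts (TSV/BED) and the resolved configuration are
#' written to \code{out_dir}.
#'
#' @param config a (partial) configuration list merged onto
#'   [pipelineConfig()], or a YAML file path.
#' @return invisibly, a list of in-memory results
#'   (\code{molecules}, \code{qc}, \code{ordering}, \code{tracks},
#'   \code{fork_counts}, \code{speeds}).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(pipelineConfig(), config)
  if (!is.null(cfg$speed$delta_t) && cfg$speed$delta_t <= 0)
    stop("speed$delta_t must be > 0")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  ## --- input -------------------------------------------------------
  if (!is.null(cfg$input)) {
    layout <- readChromSizes(cfg$input$chrom_sizes)
    mol <- readMoleculeTable(cfg$input$path, layout,
                             one_based = isTRUE(cfg$input$one_based))
  } else {
    s <- cfg$simulate
    layout <- genomeLayout(paste0("chr", seq_len(s$n_chrom)),
                           rep(s$chrom_length, s$n_chrom))
    scheme <- if (s$labeling == "double") pulseScheme(s$gap) else "single"
    coh <- simulateCohort(layout,
                          stages = seq(0.05, 0.95, length.out = s$n_cells),
                          timing = gradientTiming(layout),
                          n_forks = s$n_forks, speed_mu = s$speed_mu,
                          speed_sigma = s$speed_sigma, scheme = scheme,
                          sampling_rate = s$sampling_rate,
                          background_rate = s$background_rate, seed = seed)
    mol <- coh$molecules
  }
  writeMoleculeTable(mol, file.path(cfg$out_dir, "molecules.tsv"))

  ## --- qc ----------------------------------------------------------
  qc <- NULL
  if (isTRUE(cfg$qc$enabled)) {
    qc <- computeQC(mol, dispersion_threshold = cfg$qc$dispersion_threshold)
    data.table::fwrite(qc, file.path(cfg$out_dir, "qc.tsv"), sep = "\t")
    mol <- applyQC(mol, qc)
    if (nReads(mol) == 0) stop("no cells passed QC")
  }
  fg <- suppressWarnings(selectForegroundReads(mol))
  molf <- filterForeground(mol, fg)
  writeMoleculeTable(molf, file.path(cfg$out_dir, "foreground.tsv"))

  ## --- ordering ----------------------------------------------------
  ord <- NULL
  if (isTRUE(cfg$order$enabled) && length(cells(molf)) >= 10) {
    prof <- smoothProfiles(molf)
    D <- cellDistanceMatrix(prof)
    ord <- tryCatch(
      embedOrder(D, n_runs = cfg$order$n_runs, seed = seed,
                 spearman_cutoff = cfg$order$spearman_cutoff,
                 cluster_gap = cfg$order$cluster_gap,
                 cluster_frac = cfg$order$cluster_frac),
      error = function(e) {
        warning("ordering stage failed (", conditionMessage(e),
                "); downstream stages run without S-phase positions")
        NULL
      })
    if (!is.null(ord))
      data.table::fwrite(orderingTable(ord),
                         file.path(cfg$out_dir, "ordering.tsv"), sep = "\t")
  }

  ## --- segmentation ------------------------------------------------
  tracks <- NULL; fc <- NULL
  if (isTRUE(cfg$segment$enabled)) {
    trl <- lapply(cells(molf), function(cid)
      tryCatch(suppressWarnings(segmentCell(molf, cid)),
               error = function(e) NULL))
    trl <- trl[!vapply(trl, is.null, TRUE)]
    if (length(trl)) {
      tracks <- do.call(c, trl)
      writeTracksBED(tracks, file.path(cfg$out_dir, "tracks.bed"))
      fc <- countForks(tracks, cfg$segment$min_reads)
      data.table::fwrite(fc$summary,
                         file.path(cfg$out_dir, "fork_counts.tsv"), sep = "\t")
    }
  }

  ## --- speed (double-pulse cells) ----------------------------------
  speeds <- NULL
  if (isTRUE(cfg$speed$enabled)) {
    dbl <- mol@data[labeling == "double", unique(cell)]
    if (length(dbl)) {
      sub <- new("MoleculeTable", data = mol@data[cell %in% dbl],
                 layout = mol@layout)
      speeds <- suppressWarnings(
        estimateCellSpeeds(sub, delta_t = cfg$speed$delta_t,
                           bootstrap = cfg$speed$bootstrap,
                           order = ord, seed = seed))
      data.table::fwrite(speeds, file.path(cfg$out_dir, "speeds.tsv"),
                         sep = "\t")
    }
  }
  ## resolved config for reproducibility
  writeLines(yaml::as.yaml(cfg), file.path(cfg$out_dir, "config.yaml"))
  invisible(list(molecules = mol, qc = qc, ordering = ord,
                 tracks = tracks, fork_counts = fc, speeds = speeds))
}
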