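#' Pipeline run configuration
#'
#' @param consensus_mode assigner consensus mode (see [consensus_helices()]).
#' @param redundancy_level identity level for redundancy removal, or NULL.
#' @param flank flank width in residues (default 32).
#' @param class_filter protein class to keep, or NULL for all.
#' @param test univariate scan test, \code{"t"} or \code{"ks"}.
#' @param min_instances smallest ensemble (instances per helix length)
#'   analysed.
#' @param signal_thresholds inverse-CV classification thresholds.
#' @param manova_alpha,manova_cutoff filter parameters for the MANOVA stage.
#' @param seed integer seed recorded in the manifest.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(consensus_mode = "pdb-dssp-stride",
                       redundancy_level = NULL,
                       flank = 32,
                       class_filter = NULL,
                       test = c("t", "ks"),
                       min_instances = 5,
                       signal_thresholds = c(0.1, 1.0),
                       manova_alpha = 0.05,
                       manova_cutoff = 0.9,
                       seed = 1L) {
  stopifnot(flank >= 0, all(signal_thresholds > 0),
            manova_alpha > 0, manova_alpha < 1,
            manova_cutoff > 0, manova_cutoff <= 1)
  structure(list(consensus_mode = consensus_mode,
                 redundancy_level = redundancy_level,
                 flank = as.integer(flank),
                 class_filter = class_filter,
                 test = match.arg(test),
                 min_instances = as.integer(min_instances),
                 signal_thresholds = signal_thresholds,
                 manova_alpha = manova_alpha,
                 manova_cutoff = manova_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

ensemble_residue_table <- function(ensemble) {
  hc <- helix_columns(ensemble)
  ok <- !ensemble$gap
  X <- do.call(cbind, lapply(ensemble$descriptor_names, function(d) {
    v <- ensemble$values[, , d, drop = FALSE]
    dim(v) <- dim(ensemble$gap)
    v[ok]
  }))
  colnames(X) <- ensemble$descriptor_names
  inside <- matrix(FALSE, nrow(ensemble$gap), ncol(ensemble$gap))
  inside[, hc] <- TRUE
  list(X = as.data.frame(X), inside = inside[ok])
}

#' Run the full helix-nanoenvironment pipeline
#'
#' Executes the stages in their canonical order — class filter, redundancy
#' removal, assigner consensus, grouping by helix length, positional
#' alignment, then statistics (profiles, window scan, inverse-CV census,
#' filtered MANOVA) per length — and optionally writes every artifact plus a
#' manifest with checksums to an output directory.
#'
#' @param cohort a \code{helix_cohort} (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config a [run_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @return list of class \code{pipeline_result}: \code{datamart},
#'   \code{lengths} (per analysed length: \code{ensemble}, \code{profiles},
#'   \code{scan}, \code{census}, \code{manova} or the skip reason),
#'   \code{config}, \code{log} (per-stage record counts) and, when written,
#'   \code{manifest}.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- sprintf(...)
    message(sprintf("[%s] %s", stage, log[[stage]]))
  }
  dm <- build_datamart(cohort$chains, config$class_filter,
                       config$consensus_mode, config$redundancy_level)
  note("datamart", "%d chains in, %d helices kept, %d chains dropped",
       length(cohort$chains), nrow(dm$instances), length(dm$dropped))
  lengths_out <- list()
  lens <- dm$counts$length[dm$counts$n_total >= config$min_instances]
  if (length(lens) == 0)
    note("align", "no ensembles: no helix length has >= %d instances",
         config$min_instances)
  for (L in lens) {
    inst <- dm$instances[dm$instances$length == L, , drop = FALSE]
    ens <- align_ensemble(inst, cohort$descriptors, cohort$chains,
                          flank = config$flank)
    profiles <- lapply(ens$descriptor_names, function(d)
      position_profile(ens, d))
    names(profiles) <- ens$descriptor_names
    scans <- lapply(profiles, function(pr)
      sliding_window_scan(pr$mean, w = L, test = config$test,
                          positions = ens$positions))
    census <- signal_census(ens, thresholds = config$signal_thresholds)
    rt <- ensemble_residue_table(ens)
    manova <- tryCatch({
      filt <- apply_descriptor_filters(rt$X, rt$inside,
                                       config$manova_alpha,
                                       config$manova_cutoff)
      if (length(filt$retained) == 0) "no descriptors survived filtering"
      else manova_inside_outside(rt$X[, filt$retained, drop = FALSE],
                                 rt$inside, filt)
    }, error = function(e) conditionMessage(e))
    lengths_out[[as.character(L)]] <- list(
      L = L, ensemble = ens, profiles = profiles, scans = scans,
      census = census, manova = manova)
    note(paste0("length_", L), "%d instances aligned over %d positions",
         nrow(inst), length(ens$positions))
  }
  result <- structure(list(datamart = dm, lengths = lengths_out,
                           config = config, log = log),
                      class = "pipeline_result")
  if (!is.null(out_dir)) result <- write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_datamart_tsv(result$datamart, file.path(out_dir, "datamart.tsv"))
  for (L in names(result$lengths)) {
    lr <- result$lengths[[L]]
    for (d in names(lr$profiles))
      write_tsv(lr$profiles[[d]],
                file.path(out_dir, sprintf("profile_L%s_%s.tsv", L, d)))
    scan_tab <- do.call(rbind, lapply(names(lr$scans), function(d)
      cbind(descriptor = d, as.data.frame(lr$scans[[d]]))))
    write_tsv(scan_tab, file.path(out_dir, sprintf("scan_L%s.tsv", L)))
    write_tsv(lr$census$table, file.path(out_dir,
                                         sprintf("census_L%s.tsv", L)))
    if (inherits(lr$manova, "manova_report"))
      write_tsv(lr$manova$stats,
                file.path(out_dir, sprintf("manova_L%s.tsv", L)))
  }
  files <- setdiff(list.files(out_dir), "manifest.json")
  cfg <- result$config
  class(cfg) <- NULL
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("helixenv")),
    seed = result$config$seed,
    config = cfg,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = data.frame(
      name = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  result$manifest <- manifest
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d helix length(s) analysed\n",
              length(x$lengths)))
  print(x$datamart)
  invisible(x)
}
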