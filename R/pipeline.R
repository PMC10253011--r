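# End-to-end run orchestration: phantom generation or NIfTI preprocessing,
# VAE training, latent encoding, boundary calibration, per-lesion scoring,
# and a manifest with config echo and content hashes so a run can be
# reproduced and audited.

#' Configure an end-to-end run
#'
#' Exactly one input mode is active: `phantoms` (a list of [phantom_spec()]s,
#' optionally named by lesion id) or `volumes` (a list with one entry per
#' lesion: `t1`, `t2`, `ute`, `mask` NIfTI paths).
#'
#' @param out_dir Output directory.
#' @param phantoms List of [phantom_spec()]s (phantom mode).
#' @param volumes List of per-lesion NIfTI path sets (real-volume mode).
#' @param vae A [vae_config()].
#' @param boundaries A [class_boundaries()], or `"calibrate"` to fit them on
#'   a labelled subset (phantom mode only; default).
#' @param calibration_fraction Fraction of labelled slices used for
#'   calibration, default 0.5 (the rest is held out in the manifest's
#'   agreement figure).
#' @param seed Run seed (propagated to phantom generation and training
#'   unless their own configs set one).
#' @param log_level `"info"` (stage banners) or `"debug"` (adds per-epoch
#'   losses); `"quiet"` silences both.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, phantoms = NULL, volumes = NULL,
                       vae = vae_config(), boundaries = "calibrate",
                       calibration_fraction = 0.5, seed = 1,
                       log_level = c("info", "debug", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(phantoms) == is.null(volumes))
    stop("exactly one of `phantoms` or `volumes` must be given", call. = FALSE)
  if (!is.null(phantoms))
    stopifnot(all(vapply(phantoms, inherits, logical(1), "phantom_spec")))
  stopifnot(inherits(vae, "vae_config"),
            calibration_fraction > 0, calibration_fraction < 1)
  if (!identical(boundaries, "calibrate") &&
      !inherits(boundaries, "class_boundaries"))
    stop("`boundaries` must be \"calibrate\" or a class_boundaries object",
         call. = FALSE)
  if (is.null(phantoms) && identical(boundaries, "calibrate"))
    stop("calibration needs labelled phantoms; give explicit boundaries ",
         "for real volumes", call. = FALSE)
  structure(list(out_dir = out_dir, phantoms = phantoms, volumes = volumes,
                 vae = vae, boundaries = boundaries,
                 calibration_fraction = calibration_fraction,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Field-by-field validated YAML equivalent of [run_config()]; see the
#' package's `inst/extdata/example_run.yaml` for the layout.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (field in c("out_dir")) {
    if (is.null(y[[field]])) stop("config is missing `", field, "`",
                                  call. = FALSE)
  }
  phantoms <- NULL
  if (!is.null(y$phantoms)) {
    phantoms <- lapply(y$phantoms, function(ph) {
      do.call(phantom_spec, ph[intersect(names(ph),
        names(formals(phantom_spec)))])
    })
    if (!is.null(names(y$phantoms))) names(phantoms) <- names(y$phantoms)
  }
  vae <- do.call(vae_config, if (is.null(y$vae)) list() else
    y$vae[intersect(names(y$vae), names(formals(vae_config)))])
  boundaries <- if (is.null(y$boundaries) ||
                    identical(y$boundaries, "calibrate")) "calibrate"
                else class_boundaries(y$boundaries$x_threshold,
                                      y$boundaries$y_threshold)
  run_config(out_dir = y$out_dir, phantoms = phantoms, volumes = y$volumes,
             vae = vae, boundaries = boundaries,
             calibration_fraction = y$calibration_fraction %||% 0.5,
             seed = y$seed %||% 1,
             log_level = y$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_log <- function(config, level, fmt, ...) {
  ranks <- c(quiet = 0, info = 1, debug = 2)
  if (ranks[[config$log_level]] >= ranks[[level]])
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

# Load and preprocess the configured inputs into labelled/unlabelled stacks.
gather_stacks <- function(config) {
  if (!is.null(config$phantoms)) {
    ids <- names(config$phantoms) %||%
      sprintf("lesion%02d", seq_along(config$phantoms))
    if (is.null(names(config$phantoms)))
      names(config$phantoms) <- ids
    stacks <- lapply(seq_along(config$phantoms), function(i) {
      stack <- generate_phantom(config$phantoms[[i]], lesion_id = ids[i])
      # phantoms go through the same per-slice standardization as real data
      stack$slices <- lapply(stack$slices, standardize_slice,
                             side = config$vae$image_side)
      stack
    })
    return(stacks)
  }
  vols <- lapply(config$volumes, function(v) {
    list(t1 = read_contrast_volume(v$t1, "T1w", v$lesion_id %||% "lesion"),
         t2 = read_contrast_volume(v$t2, "T2w", v$lesion_id %||% "lesion"),
         ute = read_contrast_volume(v$ute, "UTE", v$lesion_id %||% "lesion"),
         mask = read_roi_mask(v$mask, v$lesion_id %||% "lesion"))
  })
  normed <- normalize_cohort(unlist(lapply(vols, function(v)
    v[c("t1", "t2", "ute")]), recursive = FALSE))
  lapply(seq_along(vols), function(i) {
    fused <- fuse_contrasts(normed[[3 * i - 2]], normed[[3 * i - 1]],
                            normed[[3 * i]])
    preprocess_lesion(fused, vols[[i]]$mask, side = config$vae$image_side)
  })
}

#' Run the full pipeline
#'
#' Executes input preparation (phantom generation or NIfTI preprocessing),
#' VAE training on all slices, deterministic latent encoding, boundary
#' calibration or application, per-lesion scoring and cohort summary, and
#' writes every artifact (slice PNGs, model checkpoint, loss CSV, latent
#' scatter, lesion report JSONs, cohort CSV) plus `manifest.json` recording
#' the config echo, seed, package version and MD5 hashes of all outputs.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` (invisibly also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    run_log(config, "info", "stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  stacks <- stage("input", gather_stacks(config))
  slice_dir <- file.path(config$out_dir, "slices")
  for (stack in stacks) write_stack(stack, slice_dir)

  all_slices <- unlist(lapply(stacks, `[[`, "slices"), recursive = FALSE)
  run_log(config, "info", "%d slices from %d lesions", length(all_slices),
          length(stacks))

  vae_cfg <- config$vae
  model <- stage("train", train_vae(all_slices, vae_cfg,
                                    verbose = config$log_level == "debug"))
  save_vae(model, file.path(config$out_dir, "vae"))

  emb <- stage("encode", {
    purrr::map_dfr(stacks, function(stack) {
      e <- vae_encode(model, stack)
      e$lesion_id <- stack$lesion_id
      e
    })
  })

  calibration <- NULL
  boundaries <- config$boundaries
  if (identical(boundaries, "calibrate")) {
    boundaries <- stage("calibrate", {
      labelled <- emb[!is.na(emb$label), ]
      # stratified split so every class is represented in the calibration set
      cal_idx <- withr::with_seed(config$seed, {
        unlist(lapply(split(seq_len(nrow(labelled)), labelled$label),
                      function(ix) {
                        n_c <- max(1L, ceiling(config$calibration_fraction *
                                                 length(ix)))
                        ix[sample.int(length(ix), n_c)]
                      }), use.names = FALSE)
      })
      n_cal <- length(cal_idx)
      b <- calibrate_boundaries(labelled[cal_idx, ])
      holdout <- labelled[-cal_idx, ]
      holdout_cls <- classify_points(holdout, b)
      calibration <- list(
        n_calibration = n_cal,
        n_holdout = nrow(holdout),
        calibration_agreement = attr(b, "agreement"),
        holdout_agreement = if (nrow(holdout) > 0)
          mean(holdout_cls$class == holdout_cls$label) else NA_real_)
      b
    })
  }

  reports <- stage("classify", {
    lapply(stacks, function(stack) {
      pts <- emb[emb$lesion_id == stack$lesion_id, ]
      score_lesion(classify_points(pts, boundaries)$class,
                   lesion_id = stack$lesion_id)
    })
  })

  files <- stage("report", {
    cohort <- dplyr::bind_rows(lapply(reports, tidy))
    cohort_csv <- file.path(config$out_dir, "cohort.csv")
    utils::write.csv(cohort, cohort_csv, row.names = FALSE)
    summary_csv <- file.path(config$out_dir, "cohort_summary.csv")
    utils::write.csv(summarize_cohort(cohort), summary_csv, row.names = FALSE)
    for (rep in reports)
      jsonlite::write_json(unclass(rep),
        file.path(config$out_dir, paste0(rep$lesion_id, "_report.json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    scatter <- file.path(config$out_dir, "latent_space.png")
    grDevices::png(scatter, width = 900, height = 700, res = 120)
    print(plot_latent_space(classify_points(emb, boundaries), boundaries))
    grDevices::dev.off()
    c(cohort_csv, summary_csv, scatter,
      file.path(config$out_dir, paste0(vapply(reports, `[[`, character(1),
                                              "lesion_id"), "_report.json")),
      file.path(config$out_dir, c("vae.rds", "vae_config.json",
                                  "vae_loss.csv")),
      list.files(slice_dir, full.names = TRUE))
  })

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("plaquevae")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = serialize_config(config),
    boundaries = list(x_threshold = boundaries$x_threshold,
                      y_threshold = boundaries$y_threshold,
                      class_map = as.list(boundaries$class_map)),
    calibration = calibration,
    lesions = lapply(reports, function(r)
      list(lesion_id = r$lesion_id, n_slices = r$n_slices,
           average_tissue_score = r$average_tissue_score)),
    files = {
      h <- tools::md5sum(files)
      purrr::map2(names(h), unname(h), function(f, m)
        list(file = f, md5 = m))
    }), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_log(config, "info", "run complete: %d lesions, %d artifacts",
          length(reports), length(files))
  invisible(manifest)
}

serialize_config <- function(config) {
  list(out_dir = config$out_dir,
       mode = if (is.null(config$phantoms)) "volumes" else "phantom",
       phantoms = lapply(config$phantoms, unclass),
       volumes = config$volumes,
       vae = unclass(config$vae),
       boundaries = if (identical(config$boundaries, "calibrate")) "calibrate"
                    else unclass(config$boundaries),
       calibration_fraction = config$calibration_fraction,
       seed = config$seed, log_level = config$log_level)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d lesions, %d files, seed %d\n",
              length(x$lesions), length(x$files), x$seed))
  for (l in x$lesions)
    cat(sprintf("  %s: %d slices, average tissue score %.2f\n",
                l$lesion_id, l$n_slices, l$average_tissue_score))
  if (!is.null(x$calibration))
    cat(sprintf("  holdout agreement: %.1f%%\n",
                100 * x$calibration$holdout_agreement))
  invisible(x)
}
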