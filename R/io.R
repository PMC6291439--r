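#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return The image as an array (an `RNifti` `niftiImage`, which carries
#'   voxel size and orientation metadata).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such volume: %s", path))
  RNifti::readNifti(path)
}

#' Write a NIfTI volume
#'
#' @param vol 3D or 4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm per-axis voxel size for the first three dimensions.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size_mm = c(4, 4.7, 4.7)) {
  img <- RNifti::asNifti(structure(vol + 0, class = NULL))
  pd <- as.numeric(voxel_size_mm)
  if (length(dim(vol)) == 4) pd <- c(pd, 1)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

# geometry compatibility check between two volumes
.check_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a)[seq_len(3)], dim(b)[seq_len(3)])) {
    stop(sprintf("geometry mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

#' Read a study configuration file
#'
#' A single human-editable YAML file describing a study: the acquisition
#' `protocol`, either a `phantom` section (synthetic study) or an `inputs`
#' section with paths to measured volumes (`pwi`, `m0`, `mask`), optional
#' `fit` and `segmentation` settings, a `scenario`, and a `seed`. Exactly
#' one of `phantom` / `inputs` must be present.
#'
#' @param path YAML file path.
#' @return Validated config list (class `study_config`).
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg)
}

#' @rdname read_study_config
#' @param cfg a config list (as from YAML).
#' @export
validate_study_config <- function(cfg) {
  has_phantom <- !is.null(cfg$phantom)
  has_inputs <- !is.null(cfg$inputs)
  if (has_phantom == has_inputs) {
    stop("config must contain exactly one of 'phantom' or 'inputs'")
  }
  if (has_inputs) {
    for (k in c("pwi", "m0", "mask")) {
      if (is.null(cfg$inputs[[k]])) {
        stop(sprintf("config inputs section is missing '%s'", k))
      }
      if (!file.exists(cfg$inputs[[k]])) {
        stop(sprintf("input path does not exist: %s", cfg$inputs[[k]]))
      }
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$scenario)) {
    cfg$scenario <- if (has_phantom) "repeatability" else "single"
  }
  structure(cfg, class = "study_config")
}

.protocol_from_config <- function(cfg) {
  p <- cfg$protocol
  if (is.null(p)) return(asl_protocol())
  do.call(asl_protocol, p)
}

.phantom_spec_from_config <- function(cfg) {
  ph <- cfg$phantom
  args <- list()
  for (k in c("grid_shape", "voxel_size_mm", "cortex_depth", "noise_sd",
              "n_averages")) {
    if (!is.null(ph[[k]])) args[[k]] <- ph[[k]]
  }
  if (!is.null(ph$tissue)) args$tissue <- as.data.frame(ph$tissue)
  args$seed <- cfg$seed
  do.call(phantom_spec, args)
}

.fit_settings_from_config <- function(cfg) {
  if (is.null(cfg$fit)) return(fit_settings())
  do.call(fit_settings, cfg$fit)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full quantification pipeline
#'
#' Orchestrates simulate/ingest, PWI construction, voxel-wise fitting,
#' segmentation, region summaries and the scan-agreement statistics, and
#' writes all artifacts (parametric maps and masks as NIfTI, tables as CSV,
#' a provenance log) to `out_dir`. Deterministic under a fixed config seed.
#'
#' @param config a config list or path to a YAML config
#'   (see [read_study_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the per-scan summaries, agreement results
#'   and output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  t_start <- proc.time()[["elapsed"]]
  cfg <- if (is.character(config)) read_study_config(config)
         else validate_study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  protocol <- .stage("config", .protocol_from_config(cfg))
  settings <- .stage("config", .fit_settings_from_config(cfg))

  # --- acquire: synthetic scenario or measured inputs ------------------
  scans <- .stage("acquire", {
    if (!is.null(cfg$phantom)) {
      spec <- .phantom_spec_from_config(cfg)
      if (cfg$scenario %in% c("repeatability", "gtn_challenge")) {
        sc <- make_study_scenario(spec, cfg$scenario,
                                  protocol = protocol, seed = cfg$seed)
        lapply(sc$timepoints, function(tp) {
          list(pwi = as_pwi(tp$acquisition), mask = tp$truth$masks$whole,
               truth = tp$truth, bp = sc$bp)
        })
      } else {
        truth <- make_phantom(spec)
        acq <- simulate_acquisition(truth, spec, protocol)
        list(list(pwi = as_pwi(acq), mask = truth$masks$whole,
                  truth = truth, bp = NULL))
      }
    } else {
      dm <- read_volume(cfg$inputs$pwi)
      m0 <- read_volume(cfg$inputs$m0)
      mask <- read_volume(cfg$inputs$mask)
      .check_geometry(dm, m0, "PWI and M0")
      .check_geometry(dm, mask, "PWI and mask")
      if (dim(dm)[4] != length(protocol$ti)) {
        stop(sprintf("PWI has %d frames but the protocol lists %d TIs",
                     dim(dm)[4], length(protocol$ti)))
      }
      pwi <- structure(list(dm = structure(dm + 0, class = NULL),
                            m0 = structure(m0 + 0, class = NULL),
                            protocol = protocol,
                            voxel_size_mm = RNifti::pixdim(dm)[1:3]),
                       class = "pwi_series")
      list(list(pwi = pwi, mask = mask != 0, truth = NULL, bp = NULL))
    }
  })

  seg_cfg <- cfg$segmentation
  keep <- if (!is.null(seg_cfg$central_slices)) seg_cfg$central_slices else NULL
  method <- if (!is.null(seg_cfg$method)) seg_cfg$method else "outer"
  depth <- if (!is.null(seg_cfg$depth)) seg_cfg$depth else 3

  summaries <- list()
  vox <- scans[[1]]$pwi$voxel_size_mm
  for (i in seq_along(scans)) {
    scan_id <- sprintf("scan%d", i)
    fit <- .stage("fit", fit_gkm_volume(scans[[i]]$pwi, scans[[i]]$mask,
                                        settings))
    seg <- .stage("segment", {
      m <- scans[[i]]$mask
      if (!is.null(keep)) m <- central_slices(m, keep)
      if (method == "t1") {
        thr <- if (!is.null(seg_cfg$threshold)) seg_cfg$threshold else "auto"
        cortex_by_t1_threshold(fit$t1_map, m, threshold = thr)
      } else {
        cortex_by_erosion(m, depth)
      }
    })
    summaries[[i]] <- .stage("summarize",
      summarize_regions(fit, seg, subject = "s01", scan = scan_id))
    .stage("write", {
      write_volume(fit$f_map, file.path(out_dir, paste0(scan_id, "_f.nii.gz")), vox)
      write_volume(fit$bat_map, file.path(out_dir, paste0(scan_id, "_bat.nii.gz")), vox)
      write_volume(fit$t1_map, file.path(out_dir, paste0(scan_id, "_t1.nii.gz")), vox)
      write_volume(fit$single_ti_f_map,
                   file.path(out_dir, paste0(scan_id, "_single_ti_f.nii.gz")), vox)
      lab <- array(0L, dim = dim(seg$whole))
      lab[seg$medulla] <- 2L; lab[seg$cortex] <- 1L
      write_volume(lab, file.path(out_dir, paste0(scan_id, "_labels.nii.gz")), vox)
    })
  }
  summary_df <- do.call(rbind, summaries)
  utils::write.csv(summary_df, file.path(out_dir, "region_summaries.csv"),
                   row.names = FALSE)

  # --- stats stage -----------------------------------------------------
  agreement <- .stage("stats", {
    res <- list()
    multi <- summary_df[summary_df$method == "multi_ti", ]
    single <- summary_df[summary_df$method == "single_ti", ]
    ord <- order(multi$scan, multi$region)
    ba <- bland_altman(single$mean_f[order(single$scan, single$region)],
                       multi$mean_f[ord])
    res$method_bias <- ba
    if (length(scans) >= 2) {
      s1 <- multi[multi$scan == "scan1", ]
      s2 <- multi[multi$scan == "scan2", ]
      m <- merge(s1, s2, by = "region")
      res$interscan <- ma_regression(m$mean_f.x, m$mean_f.y)
    }
    res
  })
  stats_rows <- data.frame(
    quantity = c("single_vs_multi_bias", "single_vs_multi_loa_lower",
                 "single_vs_multi_loa_upper",
                 if (!is.null(agreement$interscan))
                   c("interscan_r_squared", "interscan_ma_slope")),
    value = c(agreement$method_bias$bias, agreement$method_bias$loa,
              if (!is.null(agreement$interscan))
                c(agreement$interscan$r_squared, agreement$interscan$slope))
  )
  utils::write.csv(stats_rows, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)
  if (!is.null(scans[[1]]$bp)) {
    utils::write.csv(scans[[1]]$bp, file.path(out_dir, "blood_pressure.csv"),
                     row.names = FALSE)
  }

  # --- provenance ------------------------------------------------------
  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  prov <- c(
    sprintf("package: renalasl %s",
            as.character(utils::packageVersion("renalasl"))),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("seed: %s", cfg$seed),
    sprintf("scans: %d", length(scans)),
    sprintf("runtime_s: %.1f", proc.time()[["elapsed"]] - t_start)
  )
  writeLines(prov, file.path(out_dir, "provenance.txt"))

  invisible(list(summaries = summary_df, agreement = agreement,
                 out_dir = out_dir))
}
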