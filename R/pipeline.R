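#' Pipeline configuration
#'
#' Collects every tunable of the segmentation pipeline with the package
#' defaults, validating each against its owning operation's preconditions.
#' A configuration file (JSON or YAML) may supply values; explicit arguments
#' win on conflict.
#'
#' @param er Branch margin (default 0.07).
#' @param n1,n2 Initial-value divisors (defaults 3, 3).
#' @param bins Histogram bins (default 256).
#' @param n_thresholds Whole-cell threshold family size (default 10).
#' @param min_area_frac Minimum object area fraction (default 0.005).
#' @param mode \code{"average"}, \code{"slic"} or \code{"watershed"}.
#' @param n_segments,compactness SLIC parameters.
#' @param min_separation Watershed marker separation (NULL = automatic).
#' @param seed Seed for any stochastic step.
#' @param config_file Optional JSON/YAML file of defaults.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(er = 0.07, n1 = 3, n2 = 3, bins = 256,
                            n_thresholds = 10, min_area_frac = 0.005,
                            mode = c("average", "slic", "watershed"),
                            n_segments = 100, compactness = 10,
                            min_separation = NULL, seed = 1,
                            config_file = NULL) {
  cfg <- list(er = er, n1 = n1, n2 = n2, bins = bins,
              n_thresholds = n_thresholds, min_area_frac = min_area_frac,
              mode = match.arg(mode), n_segments = n_segments,
              compactness = compactness, min_separation = min_separation,
              seed = seed)
  if (!is.null(config_file)) {
    file_cfg <- if (grepl("\\.ya?ml$", config_file)) {
      if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required for YAML configs")
      yaml::read_yaml(config_file)
    } else {
      jsonlite::read_json(config_file, simplifyVector = TRUE)
    }
    supplied <- names(as.list(match.call()))   # explicit arguments win
    for (nm in names(file_cfg)) {
      if (nm %in% names(cfg) && !(nm %in% supplied)) cfg[[nm]] <- file_cfg[[nm]]
    }
  }
  if (cfg$er <= 0) stop("er must be positive")
  if (cfg$n1 < 1 || cfg$n2 < 1) stop("n1 and n2 must be >= 1")
  if (cfg$bins < 8) stop("bins must be >= 8")
  if (cfg$n_thresholds < 2) stop("n_thresholds must be >= 2")
  if (cfg$n_segments < 4) stop("n_segments must be >= 4")
  structure(cfg, class = "pipeline_config")
}

#' Segment one image end to end
#'
#' Nucleus, whole cell and cytoplasm for a single image, under a
#' configuration. For the average mode a sanity rule warns (suggesting the
#' slic/watershed fallbacks) when the cell mask touches the image border or
#' exceeds 60 percent of the image area, both symptoms of red cells fused
#' to the cell.
#'
#' @param image Gray matrix, color array, or a path readable by
#'   \code{\link{read_image}}.
#' @param config A \code{pipeline_config}.
#' @return List with \code{nucleus}, \code{wbc}, \code{cytoplasm},
#'   \code{estimate}, \code{otsu_t} (average mode only), \code{timings}.
#' @export
segment_cell <- function(image, config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  raw <- if (is.character(image)) .read_raw(image) else image
  gray <- if (length(dim(raw)) == 3L) .luminance(raw) else raw
  nuc <- segment_nucleus(gray, er = config$er, n1 = config$n1, n2 = config$n2,
                         nbins = config$bins, min_area_frac = config$min_area_frac)
  t1 <- proc.time()[["elapsed"]]
  otsu_t <- NA_real_
  if (config$mode == "average") {
    res <- segment_wbc(gray, nuc$mask, n_thresholds = config$n_thresholds,
                       T_nc0 = nuc$estimate$T_nc0,
                       min_area_frac = config$min_area_frac)
    wbc <- res$wbc; otsu_t <- res$otsu_t
    border <- sum(wbc[1, ]) + sum(wbc[nrow(wbc), ]) + sum(wbc[, 1]) + sum(wbc[, ncol(wbc)])
    if (border > 0 || sum(wbc) > 0.6 * length(wbc)) {
      warning("cell mask touches the border or is implausibly large; ",
              "red cells may be fused to it - consider mode 'slic' or 'watershed'")
    }
  } else if (config$mode == "watershed") {
    set.seed(config$seed)
    wbc <- segment_wbc_watershed(gray, nuc$mask,
                                 min_separation = config$min_separation,
                                 min_area_frac = config$min_area_frac)
  } else {
    set.seed(config$seed)
    wbc <- segment_wbc_slic(raw, nuc$mask, n_segments = config$n_segments,
                            compactness = config$compactness,
                            min_area_frac = config$min_area_frac)
  }
  cyto <- suppressWarnings(compute_cytoplasm(wbc, nuc$mask))
  t2 <- proc.time()[["elapsed"]]
  list(nucleus = nuc$mask, wbc = wbc, cytoplasm = cyto,
       estimate = nuc$estimate, otsu_t = otsu_t,
       timings = c(nucleus = t1 - t0, wbc = t2 - t1))
}

#' Run the segmentation pipeline over a batch of images
#'
#' Per input image, writes the nucleus, whole-cell and cytoplasm masks and
#' an audit JSON (threshold record, branch, Otsu threshold, timings) next to
#' the requested output prefix. Per-image failures are logged and skipped;
#' the call errors only when every image fails.
#'
#' @param config A \code{pipeline_config}.
#' @param inputs Character vector of image paths.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a data frame of per-image audit records.
#' @export
run_pipeline <- function(config, inputs, out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (path in inputs) {
    stem <- sub("\\.[^.]+$", "", basename(path))
    res <- tryCatch(segment_cell(path, config), error = function(e) {
      message("FAILED ", path, ": ", conditionMessage(e)); NULL
    })
    if (is.null(res)) next
    write_mask(res$nucleus, file.path(out_dir, paste0(stem, "_nucleus.png")))
    write_mask(res$wbc, file.path(out_dir, paste0(stem, "_wbc.png")))
    write_mask(res$cytoplasm, file.path(out_dir, paste0(stem, "_cytoplasm.png")))
    audit <- c(res$estimate[c("T_nc0", "x_c", "x_c1", "Er", "epsilon_t", "branch", "n1", "n2")],
               list(otsu_t = res$otsu_t, mode = config$mode,
                    timings = as.list(res$timings)))
    jsonlite::write_json(audit, file.path(out_dir, paste0(stem, "_audit.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    message(sprintf("%s: epsilon_t = %.4f (branch %s)", stem,
                    res$estimate$epsilon_t, res$estimate$branch))
    rows[[length(rows) + 1L]] <- data.frame(
      image = stem, epsilon_t = res$estimate$epsilon_t,
      branch = res$estimate$branch, otsu_t = res$otsu_t,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("all inputs failed")
  invisible(do.call(rbind, rows))
}

#' Evaluate predicted masks against ground-truth masks on disk
#'
#' Matches each tri-level truth mask \code{<stem>_mask.png} (or
#' \code{<stem>.png}) in \code{truth_dir} with predictions
#' \code{<stem>_nucleus.png} / \code{<stem>_wbc.png} in \code{pred_dir} and
#' scores them.
#'
#' @param pred_dir Directory of predicted masks.
#' @param truth_dir Directory of tri-level ground-truth masks.
#' @return Data frame of per-image metrics.
#' @export
evaluate_directories <- function(pred_dir, truth_dir) {
  truths <- list.files(truth_dir, pattern = "_mask\\.png$", full.names = TRUE)
  if (!length(truths)) truths <- list.files(truth_dir, pattern = "\\.png$", full.names = TRUE)
  rows <- list()
  for (tp in truths) {
    stem <- sub("_mask$", "", sub("\\.png$", "", basename(tp)))
    np <- file.path(pred_dir, paste0(stem, "_nucleus.png"))
    wp <- file.path(pred_dir, paste0(stem, "_wbc.png"))
    if (!file.exists(np) || !file.exists(wp)) next
    truth <- read_trilevel_mask(tp)
    nuc <- matrix(as.integer(read_trilevel_mask(np) == 255), nrow(truth), ncol(truth))
    wbc <- matrix(as.integer(read_trilevel_mask(wp) == 255), nrow(truth), ncol(truth))
    ev <- evaluate_against_truth(nuc, wbc, truth)
    rows[[length(rows) + 1L]] <- data.frame(
      image = stem,
      nucleus_ji = ev$nucleus$ji, nucleus_dsc = ev$nucleus$dsc,
      wbc_ji = ev$wbc$ji, wbc_dsc = ev$wbc$dsc,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no matching prediction/truth pairs found")
  do.call(rbind, rows)
}
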