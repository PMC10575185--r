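#' Run the binning / training / evaluation pipeline on a dataset
#'
#' End-to-end driver: for every acquisition mode present in the manifest it
#' builds train and score feature tables with the mode's default binning
#' scheme, runs the gradient-boosted-tree trial grid, and evaluates each
#' trial. When both modes are present, the per-trial Youden indices of the
#' digested and intact conditions are compared (mean J, J ratio, Welch
#' test). Results are returned, and optionally written to a results
#' directory as a per-trial CSV, a summary JSON, and an ROC scatter figure
#' with trial multiplicities.
#'
#' @param manifest a `spot_manifest`, or the path of a manifest CSV, or a
#'   `sim_dataset` from [render_dataset()].
#' @param encoding `"binary"` or `"intensity"`.
#' @param grid `"full24"`, `"paper12"`, `"single"`, or a list of
#'   [gbt_config()]s.
#' @param seed base seed for the trial grid.
#' @param alpha significance level of the condition comparison.
#' @param out_dir optional results directory; an existing directory is
#'   never silently overwritten - a version suffix is appended instead.
#' @param schemes named list of custom [bin_scheme()]s per mode; defaults
#'   to [default_scheme()].
#' @return List of class `pipeline_result` with `trials` (named list of
#'   `trial_grid_result` per mode), `comparison` (digested vs intact, or
#'   `NULL`), `encoding`, `alpha`, `out_dir`.
#' @export
run_pipeline <- function(manifest, encoding = c("binary", "intensity"),
                         grid = "full24", seed = 1L, alpha = 0.05,
                         out_dir = NULL, schemes = NULL) {
  encoding <- match.arg(encoding)
  peaklists <- NULL
  if (inherits(manifest, "sim_dataset")) {
    peaklists <- manifest$peaklists
    manifest <- manifest$manifest
  } else if (is.character(manifest)) {
    manifest <- read_manifest(manifest)
  }
  stopifnot(inherits(manifest, "spot_manifest"))
  if (is.character(grid)) grid <- default_grid(grid, seed = seed)
  modes <- intersect(c("intact", "digested"), unique(manifest$mode))
  trials <- list()
  for (mode in modes) {
    scheme <- if (!is.null(schemes) && !is.null(schemes[[mode]])) {
      schemes[[mode]]
    } else {
      default_scheme(mode)
    }
    have_roles <- unique(manifest$role[manifest$mode == mode])
    if (!all(c("train", "score") %in% have_roles)) {
      warning("mode '", mode, "': missing train or score spots; skipped")
      next
    }
    message(sprintf("mode %s: %d bins, building feature tables (%s)",
                    mode, n_bins(scheme), encoding))
    train_ft <- build_feature_table(manifest, "train", scheme, encoding,
                                    mode = mode, peaklists = peaklists)
    score_ft <- build_feature_table(manifest, "score", scheme, encoding,
                                    mode = mode, peaklists = peaklists)
    message(sprintf("mode %s: %d train / %d score spots, %d trials",
                    mode, nrow(train_ft$x), nrow(score_ft$x), length(grid)))
    trials[[mode]] <- run_grid(train_ft, score_ft, grid)
  }
  comparison <- NULL
  if (all(c("intact", "digested") %in% names(trials))) {
    j_dig <- trials$digested$J[!is.na(trials$digested$J)]
    j_int <- trials$intact$J[!is.na(trials$intact$J)]
    if (length(j_dig) >= 2 && length(j_int) >= 2) {
      comparison <- compare_conditions(j_dig, j_int, alpha = alpha,
                                       names = c("digested", "intact"))
    }
  }
  result <- structure(list(trials = trials, comparison = comparison,
                           encoding = encoding, alpha = alpha,
                           out_dir = out_dir),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    result$out_dir <- write_pipeline_report(result, out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s encoding\n", x$encoding))
  for (mode in names(x$trials)) {
    t <- x$trials[[mode]]
    ok <- !is.na(t$J)
    cat(sprintf("  %s: %d/%d trials ok, mean J %.3f, max J %.3f\n",
                mode, sum(ok), nrow(t),
                if (any(ok)) mean(t$J[ok]) else NA,
                if (any(ok)) max(t$J[ok]) else NA))
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

# next free versioned directory: dir, dir.1, dir.2, ...
.versioned_dir <- function(dir) {
  candidate <- dir
  v <- 0
  while (dir.exists(candidate)) {
    v <- v + 1
    candidate <- sprintf("%s.%d", dir, v)
  }
  candidate
}

#' Write a pipeline report to disk
#'
#' Emits `trials_<mode>.csv` per mode, `summary.json` (per-mode mean/max J,
#' comparison ratio and Welch p, test name, alpha), and `roc_scatter.png`.
#' An existing directory is kept and a versioned sibling is used instead.
#'
#' @param result a `pipeline_result`.
#' @param dir requested results directory.
#' @return The directory actually written, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir <- .versioned_dir(dir)
  dir.create(dir, recursive = TRUE)
  for (mode in names(result$trials)) {
    utils::write.csv(as.data.frame(result$trials[[mode]]),
                     file.path(dir, paste0("trials_", mode, ".csv")),
                     row.names = FALSE)
  }
  summarize <- function(t) {
    ok <- !is.na(t$J)
    list(n_trials = nrow(t), n_ok = sum(ok),
         mean_J = if (any(ok)) mean(t$J[ok]) else NA,
         max_J = if (any(ok)) max(t$J[ok]) else NA,
         mean_sens = if (any(ok)) mean(t$sens[ok]) else NA,
         mean_spc = if (any(ok)) mean(t$spc[ok]) else NA)
  }
  summary <- list(encoding = result$encoding,
                  package_version = as.character(
                    utils::packageVersion("maldisort")),
                  modes = lapply(result$trials, summarize))
  if (!is.null(result$comparison)) {
    cmp <- result$comparison
    summary$comparison <- list(
      conditions = cmp$conditions, mean_J_digested = cmp$mean_J_a,
      mean_J_intact = cmp$mean_J_b, J_ratio = cmp$ratio,
      p_value = cmp$p_value, significant = cmp$significant,
      alpha = cmp$alpha, test = cmp$test)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  grDevices::png(file.path(dir, "roc_scatter.png"), width = 600,
                 height = 600)
  cols <- c(intact = "forestgreen", digested = "royalblue")
  first <- TRUE
  for (mode in names(result$trials)) {
    t <- result$trials[[mode]]
    t <- t[!is.na(t$J), , drop = FALSE]
    if (!nrow(t)) next
    plot_roc_scatter(roc_scatter(t), col = cols[[mode]], add = !first)
    first <- FALSE
  }
  if (length(result$trials)) {
    graphics::legend("bottomright", legend = names(result$trials),
                     col = cols[names(result$trials)], pch = 19, bty = "n")
  }
  grDevices::dev.off()
  invisible(dir)
}
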