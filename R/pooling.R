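#' Pool validation statistics across imputed datasets
#'
#' For each (domain, timepoint, metric) group of `m` per-imputation values,
#' reports the mean, sample SD (divisor m - 1), median and quartiles.
#' Quartiles default to Tukey hinges (the median-of-halves convention);
#' `quartile = "type7"` switches to the common linear-interpolation
#' definition. A group containing an undefined (NA) metric, or run with
#' m = 1 (where the SD does not exist), is flagged via the `undefined`
#' column and summarized with NAs where the summary does not exist.
#'
#' @param metrics Long data frame with columns `domain`, `timepoint`,
#'   `imputation`, `metric`, `value` (one row per imputation and metric, as
#'   from [metrics_long()]).
#' @param quartile `"tukey"` (default) or `"type7"`.
#' @return Data frame of class `promval_pooled`: `domain`, `timepoint`,
#'   `metric`, `m`, `mean`, `sd`, `median`, `q1`, `q3`, `undefined`.
#' @export
pool_metrics <- function(metrics, quartile = c("tukey", "type7")) {
  quartile <- match.arg(quartile)
  need <- c("domain", "timepoint", "imputation", "metric", "value")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols)) {
    stop(sprintf("metrics table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(metrics$domain, metrics$timepoint, metrics$metric,
                     drop = TRUE, sep = "|")
  counts <- table(key)
  m <- max(counts)
  ragged <- names(counts)[counts != m]
  if (length(ragged)) {
    stop(sprintf("ragged metric groups (expected %d values): %s", m,
                 paste(sprintf("%s (n=%d)", ragged, counts[ragged]), collapse = ", ")),
         call. = FALSE)
  }
  groups <- split(metrics, key)
  rows <- lapply(groups, function(g) {
    v <- g$value
    bad <- anyNA(v)
    qs <- if (bad) c(NA_real_, NA_real_, NA_real_) else if (quartile == "tukey") {
      stats::fivenum(v)[c(2, 3, 4)]
    } else {
      stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    }
    data.frame(domain = g$domain[1], timepoint = g$timepoint[1],
               metric = g$metric[1], m = length(v),
               mean = if (bad) NA_real_ else mean(v),
               sd = if (bad || length(v) < 2) NA_real_ else stats::sd(v),
               median = qs[2], q1 = qs[1], q3 = qs[3],
               undefined = bad || length(v) < 2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$domain, out$timepoint, out$metric), ]
  rownames(out) <- NULL
  class(out) <- c("promval_pooled", "data.frame")
  out
}

#' Locally weighted calibration curve
#'
#' Loess (local linear regression, tricube weights) of observed on
#' predicted scores over a grid spanning the predictions, with a pointwise
#' 95 percent band (`fit +- 1.96 * SE`). This is the smooth drawn over the
#' predicted-versus-observed scatter in a calibration plot; the diagonal is
#' the line of perfect prediction.
#'
#' @param p A [paired_scores()] object.
#' @param span Loess span in (0, 1\]; default 0.75.
#' @param grid_n Number of grid points (default 80).
#' @return Object of class `promval_calibration_curve`: `grid`, `fit`,
#'   `lower`, `upper`, `raw` (the paired scores), `span`.
#' @export
calibration_curve <- function(p, span = 0.75, grid_n = 80) {
  p <- as_paired(p)
  if (!is.numeric(span) || span <= 0 || span > 1) {
    stop_config("span", "must lie in (0, 1]")
  }
  if (p$n < 10) stop("need at least 10 pairs for a calibration curve", call. = FALSE)
  df <- data.frame(y = p$y, yhat = p$yhat)
  fit <- stats::loess(y ~ yhat, data = df, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(p$yhat), max(p$yhat), length.out = grid_n)
  pred <- stats::predict(fit, newdata = data.frame(yhat = grid), se = TRUE)
  structure(list(grid = grid, fit = as.numeric(pred$fit),
                 lower = as.numeric(pred$fit - 1.96 * pred$se.fit),
                 upper = as.numeric(pred$fit + 1.96 * pred$se.fit),
                 raw = p, span = span),
            class = "promval_calibration_curve")
}

#' @export
plot.promval_calibration_curve <- function(x, main = "Calibration", ...) {
  rng <- range(0, 100, x$raw$yhat, x$raw$y)
  graphics::plot(x$raw$yhat, x$raw$y, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.55), xlim = rng, ylim = rng,
                 xlab = "Predicted score", ylab = "Observed score",
                 main = main, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::lines(x$grid, x$fit, col = "blue", lwd = 2)
  graphics::lines(x$grid, x$lower, col = "blue", lty = 2)
  graphics::lines(x$grid, x$upper, col = "blue", lty = 2)
  invisible(x)
}

#' Write / read pooled metrics as CSV
#'
#' Numeric cells are written with 17 significant digits so the CSV
#' round-trips to an identical pooled table and is byte-stable across
#' identical runs.
#'
#' @param pooled A `promval_pooled` table.
#' @param path CSV path.
#' @export
write_pooled_metrics <- function(pooled, path) {
  out <- pooled
  for (cn in c("mean", "sd", "median", "q1", "q3")) {
    out[[cn]] <- format_full(out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pooled_metrics
#' @export
read_pooled_metrics <- function(path) {
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         colClasses = c(domain = "character",
                                        timepoint = "character",
                                        metric = "character"))
  for (cn in c("mean", "sd", "median", "q1", "q3")) {
    raw[[cn]] <- as.numeric(raw[[cn]])
  }
  raw$undefined <- as.logical(raw$undefined)
  class(raw) <- c("promval_pooled", "data.frame")
  raw
}

fmt_cell <- function(mean, sd) {
  if (is.na(mean)) return("--")
  if (is.na(sd)) sprintf("%.2f", mean) else sprintf("%.2f (%.2f)", mean, sd)
}

#' Render a validation report bundle
#'
#' Writes `pooled_metrics.csv` (full precision), a Markdown report with a
#' mean (SD) summary table per domain and timepoint plus the assembly flow,
#' and one calibration-plot PNG per supplied curve with the line of perfect
#' prediction overlaid. With no curves, the report contains tables only and
#' a warning is logged.
#'
#' @param pooled A `promval_pooled` table.
#' @param curves Named list of [calibration_curve()] objects (names like
#'   `"sexual.12m"`), or `NULL`.
#' @param flow Optional [assembly_flow()] data frame.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(pooled, curves = NULL, flow = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  csv_path <- file.path(dir, "pooled_metrics.csv")
  write_pooled_metrics(pooled, csv_path)
  paths <- c(paths, csv_path)

  metrics <- c("R2", "CL", "CS", "MAE", "RMSE", "c_index")
  lines <- c("# External validation report", "",
             sprintf("Pooled over m = %d imputed datasets; cells are mean (SD).",
                     max(pooled$m)), "",
             paste("| Domain | Timepoint |", paste(metrics, collapse = " | "), "|"),
             paste(c("|---|---|", rep("---|", length(metrics))), collapse = ""))
  cells <- unique(pooled[c("domain", "timepoint")])
  for (i in seq_len(nrow(cells))) {
    d <- cells$domain[i]; tp <- cells$timepoint[i]
    row <- vapply(metrics, function(mname) {
      g <- pooled[pooled$domain == d & pooled$timepoint == tp & pooled$metric == mname, ]
      if (!nrow(g)) "--" else fmt_cell(g$mean, g$sd)
    }, character(1))
    lines <- c(lines, paste("|", d, "|", tp, "|", paste(row, collapse = " | "), "|"))
  }
  if (!is.null(flow)) {
    lines <- c(lines, "", "## Cohort flow", "",
               paste("| Domain | Timepoint | Included | No in-window visit | Missing baseline | Missing outcome |"),
               "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(flow))) {
      lines <- c(lines, sprintf("| %s | %s | %d | %d | %d | %d |",
                                flow$domain[i], flow$timepoint[i], flow$included[i],
                                flow$no_window_visit[i], flow$missing_baseline[i],
                                flow$missing_outcome[i]))
    }
  }
  if (is.null(curves) || !length(curves)) {
    warning("no calibration curves supplied; report contains tables only",
            call. = FALSE)
  } else {
    lines <- c(lines, "", "## Calibration plots", "")
    for (nm in names(curves)) {
      if (is.null(curves[[nm]])) {
        warning(sprintf("missing calibration panel '%s'; skipped", nm), call. = FALSE)
        next
      }
      png_path <- file.path(dir, paste0("calibration_", gsub("[^A-Za-z0-9_]", "_", nm), ".png"))
      grDevices::png(png_path, width = 640, height = 640)
      plot(curves[[nm]], main = nm)
      grDevices::dev.off()
      paths <- c(paths, png_path)
      lines <- c(lines, sprintf("![%s](%s)", nm, basename(png_path)))
    }
    lines <- c(lines,
               "", "Smooths are local linear (tricube) fits; bands are pointwise 95% intervals.")
  }
  md_path <- file.path(dir, "report.md")
  writeLines(lines, md_path)
  paths <- c(paths, md_path)
  invisible(paths)
}
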