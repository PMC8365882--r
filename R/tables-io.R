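# CSV/JSON exchange for centerlines, waveforms, cohort tables and
# comparison reports. All outputs are deterministic (no timestamps) and
# stamped with a config hash, seed and units.

#' Write / read a centerline point set as CSV
#'
#' Columns `x_mm, y_mm, z_mm, s_mm` (cumulative polyline arc length).
#' @param x n x 3 matrix or a [ParametricCurve-class].
#' @param path CSV path.
#' @return `writeCenterlineCSV`: the path, invisibly.
#' @export
writeCenterlineCSV <- function(x, path) {
  if (is(x, "ParametricCurve")) {
    pts <- x@points; s <- x@s
  } else {
    pts <- as.matrix(x)
    s <- c(0, cumsum(rowNorm(diff(pts))))
  }
  df <- data.frame(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3], s_mm = s)
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCenterlineCSV
#' @return `readCenterlineCSV`: n x 3 numeric matrix (the `s_mm` column,
#'   if present, is dropped; arc length is recomputed downstream).
#' @export
readCenterlineCSV <- function(path) {
  if (!file.exists(path)) stopFormat("centerline file missing: %s", path)
  df <- read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stopFormat("%s: expected columns x_mm, y_mm, z_mm", path)
  as.matrix(df[, need])
}

#' Write / read an inflow waveform as CSV
#'
#' Columns `t_s, q_m3s`; the period is carried on a `# period_s=` header
#' comment line.
#' @param waveform a [FlowWaveform-class].
#' @param path CSV path.
#' @return `writeWaveformCSV`: the path invisibly; `readWaveformCSV`: a
#'   [FlowWaveform-class].
#' @export
writeWaveformCSV <- function(waveform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%s", fmtNum(waveform@period)), con)
  writeLines("t_s,q_m3s", con)
  writeLines(paste(fmtNum(waveform@t), fmtNum(waveform@q), sep = ","), con)
  invisible(path)
}

#' @rdname writeWaveformCSV
#' @export
readWaveformCSV <- function(path) {
  if (!file.exists(path)) stopFormat("waveform file missing: %s", path)
  first <- readLines(path, n = 1)
  period <- NA_real_
  if (grepl("^#\\s*period_s=", first))
    period <- as.numeric(sub("^#\\s*period_s=", "", first))
  df <- read.csv(path, comment.char = "#")
  if (!all(c("t_s", "q_m3s") %in% names(df)))
    stopFormat("%s: expected columns t_s, q_m3s", path)
  if (!is.finite(period)) period <- max(df$t_s)
  flowWaveform(df$t_s, df$q_m3s, period = period)
}

#' Write / read a cohort descriptor table as CSV
#' @param table the descriptor data.frame.
#' @param path CSV path.
#' @return `writeCohortCSV`: the path invisibly; `readCohortCSV`: the
#'   data.frame.
#' @export
writeCohortCSV <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  if (!file.exists(path)) stopFormat("cohort table missing: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write the full analysis report to a directory
#'
#' Deterministic file set: `descriptor_table.csv`, `comparison.csv`,
#' `comparison.json`, `boxplot_long.csv` (long format for external
#' plotting), `h2_tawss.csv`, and `run_info.json` carrying the config
#' hash, seed and units. Re-running with the same inputs reproduces the
#' files byte for byte.
#'
#' @param results list with `table` (descriptor data.frame) and
#'   optionally `comparison` (a [ComparisonReport-class]) and `h2_tawss`
#'   (from [exportH2Tawss()]).
#' @param dir output directory (created).
#' @param config configuration object hashed into the stamp.
#' @param seed seed recorded in the stamp.
#' @return character vector of files written, invisibly.
#' @export
writeReport <- function(results, dir, config = NULL, seed = NULL) {
  if (is.null(results$table) || nrow(results$table) == 0)
    stopInput("empty results: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  w <- function(f) { written <<- c(written, f); f }

  writeCohortCSV(results$table, w(file.path(dir, "descriptor_table.csv")))

  long <- stats::reshape(
    results$table,
    varying = intersect(descriptorNames(), names(results$table)),
    v.names = "value", timevar = "descriptor",
    times = intersect(descriptorNames(), names(results$table)),
    idvar = "vessel_id", direction = "long")
  rownames(long) <- NULL
  write.csv(long[, c("vessel_id", "species", "vessel_type", "descriptor", "value")],
            w(file.path(dir, "boxplot_long.csv")), row.names = FALSE)

  if (!is.null(results$comparison)) {
    rep <- results$comparison
    write.csv(reportTable(rep), w(file.path(dir, "comparison.csv")), row.names = FALSE)
    jsonlite::write_json(
      list(alpha = rep@alpha, note = rep@note, results = reportTable(rep)),
      w(file.path(dir, "comparison.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(results$h2_tawss)) {
    write.csv(results$h2_tawss$pairs, w(file.path(dir, "h2_tawss.csv")), row.names = FALSE)
  }
  info <- list(config_hash = configHash(config), seed = seed,
               units = list(geometry = "mm", wss = "Pa", velocity = "m/s",
                            helicity = "m/s^2", flow = "m^3/s",
                            curvature = "1/mm", torsion = "1/mm"))
  jsonlite::write_json(info, w(file.path(dir, "run_info.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(written)
}
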