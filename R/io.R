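# CSV dialect: comma separator, '.' decimal, '#'-prefixed metadata lines of
# the form "# key: v1,v2,...". Titration tables have a wavelength_nm first
# column; remaining column headers are quencher concentrations in mol/L.

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    kv <- regmatches(body, regexpr(":", body), invert = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    meta[[key]] <- vals
  }
  meta
}

#' Read a titration table from CSV
#'
#' Expected layout: optional `#`-prefixed metadata lines (`excitation_nm`,
#' `temperature_K`, and per-column `a_ex` / `a_em` schedules), then a header
#' row `wavelength_nm,<conc1>,<conc2>,...` where the concentration headers are
#' quencher concentrations in mol/L, then one row per emission wavelength.
#' Columns may appear in any order; the series is re-sorted by ascending
#' concentration. A column at concentration 0 (the F0 reference) is required.
#'
#' @param path Path to the CSV file.
#' @param metadata Optional named list overriding/providing `excitation_nm`,
#'   `temperature_K`, `a_ex`, `a_em` (the schedules are in file column order).
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path, metadata = list()) {
  if (!file.exists(path)) precondition_error(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(trimws(lines), "#")
  meta <- parse_meta_lines(lines[is_meta])
  for (k in names(metadata)) meta[[k]] <- metadata[[k]]
  if (is.null(meta$excitation_nm) || is.null(meta$temperature_K)) {
    format_error("metadata excitation_nm and temperature_K are required")
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"),
                        check.names = FALSE)
  if (ncol(df) < 3L) format_error("need a wavelength column and >= 2 concentration columns")
  wl <- as.numeric(df[[1]])
  if (anyNA(wl) || !is_strictly_increasing(wl)) {
    format_error("wavelength column must be numeric and strictly increasing")
  }
  conc <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(conc)) format_error("concentration column headers must be numeric (mol/L)")
  if (!any(conc == 0)) format_error("no F0 reference: a column at concentration 0 is required")
  intens <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(intens) || any(!is.finite(intens))) {
    format_error("intensity values must be finite (no NaN/NA)")
  }
  a_ex <- if (!is.null(meta$a_ex)) as.numeric(meta$a_ex) else rep(0, length(conc))
  a_em <- if (!is.null(meta$a_em)) as.numeric(meta$a_em) else rep(0, length(conc))
  if (length(a_ex) != length(conc) || length(a_em) != length(conc)) {
    format_error("a_ex/a_em schedules must have one value per concentration column")
  }
  ord <- order(conc)
  spectra <- lapply(ord, function(j) {
    emission_spectrum(
      wavelengths_nm = wl,
      intensities_au = intens[, j],
      excitation_nm = as.numeric(meta$excitation_nm[1]),
      temperature_K = as.numeric(meta$temperature_K[1]),
      quencher_conc_M = conc[j],
      a_ex = a_ex[j],
      a_em = a_em[j]
    )
  })
  titration_series(spectra)
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_table()]; numeric fields are written at 17
#' significant digits so a read-back reproduces them exactly.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  sp <- series$spectra
  a_ex <- vapply(sp, function(s) if (is.null(s$a_ex)) 0 else s$a_ex, numeric(1))
  a_em <- vapply(sp, function(s) if (is.null(s$a_em)) 0 else s$a_em, numeric(1))
  hdr <- c(
    paste0("# excitation_nm: ", num_to_text(series$excitation_nm)),
    paste0("# temperature_K: ", num_to_text(series$temperature_K)),
    paste0("# a_ex: ", paste(num_to_text(a_ex), collapse = ",")),
    paste0("# a_em: ", paste(num_to_text(a_em), collapse = ","))
  )
  mat <- vapply(sp, `[[`, numeric(length(series$wavelengths_nm)), "intensities_au")
  body <- c(
    paste(c("wavelength_nm", num_to_text(series$quencher_conc_M)), collapse = ","),
    apply(cbind(series$wavelengths_nm, mat), 1L,
          function(r) paste(num_to_text(r), collapse = ","))
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a dose-response table from CSV
#'
#' Expects columns `conc_ug_ml`, `a0`, `a1`; `#` lines are ignored. Rows are
#' sorted by ascending concentration.
#'
#' @param path Path to the CSV file.
#' @return A [dose_response_table()].
#' @export
read_dose_response_table <- function(path) {
  if (!file.exists(path)) precondition_error(paste("file not found:", path))
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("conc_ug_ml", "a0", "a1")
  if (!all(need %in% names(df))) {
    format_error("columns conc_ug_ml, a0, a1 are required")
  }
  dose_response_table(df$conc_ug_ml, df$a0, df$a1)
}

#' Write a dose-response table to CSV
#' @param table A [dose_response_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_response_table <- function(table, path) {
  stopifnot(inherits(table, "dose_response_table"))
  lines <- c(
    "conc_ug_ml,a0,a1",
    apply(table, 1L, function(r) paste(num_to_text(as.numeric(r)), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

# Strip classes/attributes so jsonlite serializes fits as plain lists.
as_report_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    out <- lapply(x, as_report_list)
    attributes(out) <- list(names = names(x))
    out
  } else if (is.data.frame(x)) {
    as.data.frame(lapply(x, function(col) col), stringsAsFactors = FALSE)
  } else if (is.matrix(x)) {
    unclass(x)
  } else {
    attrs <- attributes(x)
    if (!is.null(attrs)) attributes(x) <- attrs["names"]
    # named atomic vectors must become JSON objects, not nameless arrays
    if (!is.null(names(x)) && length(x) > 1L) as.list(x) else x
  }
}

#' Write a consolidated analysis report
#'
#' Emits `report.json` (full-precision JSON of every numeric field) plus one
#' flat CSV per tabular stage (`quench_table.csv`, `inhibition_curve.csv`,
#' `eem_peaks.csv`, `thermo.csv` — whichever are present in `results`).
#' Re-reading `report.json` with [read_report()] reproduces all numeric
#' fields to full double precision.
#'
#' @param results Named list of stage results (possibly empty); recognised
#'   names include `stern_volmer`, `double_log`, `thermo`, `inhibition`,
#'   `quench_table`, `shifts`, `residue_comparison`, `eem_peaks`, `config`.
#' @param path Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) qb_stop(paste("cannot create directory:", path),
                                          "quenchbind_io_error")
  }
  if (file.access(path, mode = 2L) != 0L) {
    qb_stop(paste("directory not writable:", path), "quenchbind_io_error")
  }
  files <- character(0)
  json_path <- file.path(path, "report.json")
  payload <- as_report_list(results)
  if (length(payload) == 0L) payload <- structure(list(), names = character(0))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  files <- c(files, json_path)

  write_table <- function(df, fname) {
    p <- file.path(path, fname)
    txt <- vapply(df, function(col) {
      if (is.numeric(col)) num_to_text(col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) txt <- matrix(txt, nrow = 1L)
    lines <- c(paste(names(df), collapse = ","),
               apply(txt, 1L, paste, collapse = ","))
    writeLines(lines, p)
    p
  }
  if (!is.null(results$quench_table)) {
    files <- c(files, write_table(as.data.frame(unclass(results$quench_table)),
                                  "quench_table.csv"))
  }
  if (!is.null(results$inhibition) && !is.null(results$inhibition$rows)) {
    files <- c(files, write_table(results$inhibition$rows, "inhibition_curve.csv"))
  }
  if (!is.null(results$eem_peaks) && NROW(results$eem_peaks) > 0) {
    files <- c(files, write_table(as.data.frame(results$eem_peaks), "eem_peaks.csv"))
  }
  if (!is.null(results$thermo)) {
    th <- results$thermo
    df <- data.frame(
      temperature_K = as.numeric(names(th$delta_g_by_T)),
      delta_g_J_mol = as.numeric(th$delta_g_by_T),
      delta_h_J_mol = th$delta_h_J_mol,
      delta_s_J_molK = th$delta_s_J_molK
    )
    files <- c(files, write_table(df, "thermo.csv"))
  }
  invisible(files)
}

#' Read back a report written by [write_report()]
#' @param path Report directory or path to `report.json`.
#' @return The deserialized report list.
#' @export
read_report <- function(path) {
  p <- if (dir.exists(path)) file.path(path, "report.json") else path
  if (!file.exists(p)) precondition_error(paste("report not found at", p))
  jsonlite::read_json(p, simplifyVector = TRUE)
}
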