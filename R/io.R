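#' Read an emission-spectra series from a long-format CSV file
#'
#' The long CSV dialect is one row per wavelength: UTF-8, comma separated,
#' '.' decimal separator, lines starting with '#' ignored, and the exact
#' header
#' `sample_id,lipid,assembly,replicate,scan,temperature_C,wavelength_nm,intensity`.
#' Rows are grouped into one spectrum per (sample, replicate, scan,
#' temperature) combination, with temperatures compared at 0.01 degC
#' resolution.
#'
#' @param path path to the CSV file.
#' @param format file dialect; only `"long_csv"` is supported.
#' @return A list of [emission_spectrum()] objects, sorted by sample,
#'   replicate, scan and temperature. An empty file (header only) yields an
#'   empty list.
#' @export
read_spectra <- function(path, format = "long_csv") {
  format <- match.arg(format, "long_csv")
  if (!file.exists(path))
    ld_stop(sprintf("file not found: %s", path), "laurdan_io_error")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    ld_stop("file has no header line", "laurdan_format_error")

  expected <- c("sample_id", "lipid", "assembly", "replicate", "scan",
                "temperature_C", "wavelength_nm", "intensity")
  header <- trimws(strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]])
  missing <- setdiff(expected, header)
  if (length(missing) > 0L)
    ld_stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
            "laurdan_format_error")
  if (!identical(header, expected))
    ld_stop(sprintf("header must be exactly '%s'",
                    paste(expected, collapse = ",")),
            "laurdan_format_error")

  body <- lines[-1L]
  body_no <- line_no[-1L]
  if (length(body) == 0L) return(list())

  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(expected)))
    ld_stop(sprintf("line %d: expected %d comma-separated fields, found %d",
                    body_no[which(nf != length(expected))[1L]],
                    length(expected), nf[nf != length(expected)][1L]),
            "laurdan_format_error")
  m <- matrix(trimws(unlist(fields)), ncol = length(expected), byrow = TRUE)
  colnames(m) <- expected

  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      ld_stop(sprintf("line %d: non-numeric %s '%s'", body_no[bad[1L]], col,
                      m[bad[1L], col]),
              "laurdan_parse_error")
    v
  }
  replicate <- num("replicate")
  temperature <- num("temperature_C")
  wavelength <- num("wavelength_nm")
  intensity <- num("intensity")
  neg <- which(intensity < 0)
  if (length(neg) > 0L)
    ld_stop(sprintf("line %d: negative intensity %g", body_no[neg[1L]],
                    intensity[neg[1L]]),
            "laurdan_validation_error")
  scan <- m[, "scan"]
  bad_scan <- which(scan != "averaged" &
                      is.na(suppressWarnings(as.integer(scan))))
  if (length(bad_scan) > 0L)
    ld_stop(sprintf("line %d: scan must be a positive integer or 'averaged', got '%s'",
                    body_no[bad_scan[1L]], scan[bad_scan[1L]]),
            "laurdan_parse_error")

  key <- paste(m[, "sample_id"], replicate, scan, .temp_key(temperature),
               sep = "\r")
  dup <- duplicated(paste(key, wavelength, sep = "\r"))
  if (any(dup))
    ld_stop(sprintf("line %d: duplicated (sample, replicate, scan, temperature, wavelength) row",
                    body_no[which(dup)[1L]]),
            "laurdan_format_error")

  groups <- split(seq_along(key), key)
  spectra <- lapply(groups, function(idx) {
    idx <- idx[order(wavelength[idx])]
    lip <- unique(m[idx, "lipid"])
    asm <- unique(m[idx, "assembly"])
    if (length(lip) > 1L || length(asm) > 1L)
      ld_stop(sprintf("inconsistent lipid/assembly labels within spectrum group of sample '%s'",
                      m[idx[1L], "sample_id"]),
              "laurdan_validation_error")
    sc <- m[idx[1L], "scan"]
    if (sc != "averaged") sc <- as.integer(sc)
    emission_spectrum(wavelength[idx], intensity[idx],
                      temperature[idx[1L]],
                      sample_id = m[idx[1L], "sample_id"], lipid = lip,
                      assembly = asm, replicate = replicate[idx[1L]],
                      scan = sc)
  })
  ord <- order(vapply(spectra, `[[`, character(1), "sample_id"),
               vapply(spectra, `[[`, integer(1), "replicate"),
               vapply(spectra, function(s) as.character(s$scan), character(1)),
               vapply(spectra, `[[`, numeric(1), "temperature_C"))
  unname(spectra[ord])
}

#' Write emission spectra to a long-format CSV file
#'
#' Inverse of [read_spectra()]; used by [simulate_experiment()] to emit
#' synthetic datasets. Output is byte-reproducible for identical input.
#'
#' @param spectra list of [emission_spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "emission_spectrum")) spectra <- list(spectra)
  if (length(spectra) < 1L)
    ld_stop("no spectra to write", "laurdan_validation_error")
  df <- do.call(rbind, lapply(spectra, as.data.frame))
  con <- tryCatch(file(path, "w"), error = function(e)
    ld_stop(sprintf("cannot open '%s' for writing", path), "laurdan_io_error"))
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write GP-versus-temperature curves to a TSV table
#'
#' One row per (sample, temperature): tab-separated with header columns
#' `sample_id, lipid, assembly, temperature_C, gp_mean, gp_sd,
#' n_replicates`. Missing standard deviations (single-replicate curves) are
#' written as `NA`. Numeric fields round-trip through [read_gp_table()]
#' within 1e-6 relative tolerance.
#'
#' @param curves list of [gp_curve()] objects (non-empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gp_table <- function(curves, path) {
  if (inherits(curves, "gp_curve")) curves <- list(curves)
  if (length(curves) < 1L)
    ld_stop("no GP curves to write", "laurdan_validation_error")
  stopifnot(all(vapply(curves, inherits, logical(1), "gp_curve")))
  df <- do.call(rbind, lapply(curves, as.data.frame))
  con <- tryCatch(file(path, "w"), error = function(e)
    ld_stop(sprintf("cannot open '%s' for writing", path), "laurdan_io_error"))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a GP table written by [write_gp_table()]
#'
#' @param path TSV path.
#' @return A list of [gp_curve()] objects, one per sample_id.
#' @export
read_gp_table <- function(path) {
  if (!file.exists(path))
    ld_stop(sprintf("file not found: %s", path), "laurdan_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  expected <- c("sample_id", "lipid", "assembly", "temperature_C",
                "gp_mean", "gp_sd", "n_replicates")
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0L)
    ld_stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
            "laurdan_format_error")
  out <- lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$temperature_C), ]
    gp_curve(temperature_C = d$temperature_C, gp_mean = d$gp_mean,
             gp_sd = d$gp_sd, n_replicates = d$n_replicates,
             sample_id = d$sample_id[1L], lipid = d$lipid[1L],
             assembly = d$assembly[1L])
  })
  unname(out)
}

.summary_keys <- c("tm_C", "fwhm_C", "auc_gp", "gp_low", "gp_high",
                   "transition_detected", "delta_tm_C", "reference_id")

#' Write melting summaries as JSON
#'
#' Emits one JSON object per sample, keyed by sample_id, each with fields
#' `tm_C, fwhm_C, auc_gp, gp_low, gp_high, transition_detected, delta_tm_C,
#' reference_id` (missing values become JSON `null`).
#'
#' @param summaries non-empty list of [fit_melting()] results (or their
#'   [summary.melting_fit()] lists).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_melting_summary <- function(summaries, path) {
  if (inherits(summaries, "melting_fit")) summaries <- list(summaries)
  if (length(summaries) < 1L)
    ld_stop("no melting summaries to write", "laurdan_validation_error")
  objs <- lapply(summaries, function(s) {
    if (inherits(s, "melting_fit")) s <- summary(s)
    s[.summary_keys]
  })
  ids <- vapply(summaries, function(s)
    if (inherits(s, "melting_fit")) s$sample_id else s$sample_id, character(1))
  names(objs) <- ids
  ok <- tryCatch({
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    ld_stop(sprintf("cannot write '%s'", path), "laurdan_io_error")
  invisible(path)
}

#' Read melting summaries written by [write_melting_summary()]
#'
#' @param path JSON path.
#' @return Named list (by sample_id) of summary lists; JSON `null` fields
#'   are restored as `NA`.
#' @export
read_melting_summary <- function(path) {
  if (!file.exists(path))
    ld_stop(sprintf("file not found: %s", path), "laurdan_io_error")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) {
    out <- lapply(.summary_keys, function(k)
      if (is.null(s[[k]])) NA else s[[k]])
    names(out) <- .summary_keys
    out
  })
}
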