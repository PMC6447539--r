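# Reduced-data containers and plain-text I/O.

#' Reduced 1D scattering curve
#'
#' @param q momentum transfer, 1/A, strictly increasing and positive.
#' @param I intensity (1/cm on absolute scale, else arbitrary-but-consistent).
#' @param sigma optional 1-sigma uncertainties, positive.
#' @param radiation "neutron" or "xray".
#' @param temperature degrees Celsius.
#' @param absolute_scale logical flag.
#' @return object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, I, sigma = NULL,
                             radiation = c("neutron", "xray"),
                             temperature = NA_real_, absolute_scale = FALSE) {
  radiation <- match.arg(radiation)
  stopifnot(length(q) == length(I), all(is.finite(q)), all(is.finite(I)),
            all(q > 0), all(diff(q) > 0))
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q), all(is.finite(sigma)), all(sigma > 0))
  }
  structure(list(q = q, I = I, sigma = sigma, radiation = radiation,
                 temperature = temperature, absolute_scale = absolute_scale),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf(
    "<scattering_curve> %d points, q in [%.4g, %.4g] 1/A, %s, T = %s degC%s%s\n",
    length(x$q), min(x$q), max(x$q), x$radiation, format(x$temperature),
    if (is.null(x$sigma)) ", no uncertainties" else "",
    if (isTRUE(x$absolute_scale)) ", absolute scale (1/cm)" else ""))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, I = x$I)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' Read a reduced scattering curve from 2- or 3-column ASCII
#'
#' Whitespace- or comma-delimited columns q, I and optionally sigma. Lines
#' starting with `#` or `;` (and blank lines) are skipped; a missing third
#' column leaves the uncertainties absent rather than fabricated. Rows are
#' sorted by ascending q with a warning if the file was descending.
#'
#' @param path file path.
#' @param radiation,temperature,absolute_scale metadata passed through to
#'   [scattering_curve()].
#' @return a [scattering_curve()].
#' @export
read_scattering <- function(path, radiation = c("neutron", "xray"),
                            temperature = NA_real_, absolute_scale = FALSE) {
  radiation <- match.arg(radiation)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#;]|$)", lines)
  body <- lines[keep]
  if (!length(body)) stop("no data rows in ", path)
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "[,[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      stop("non-numeric data at line ", which(keep)[i], " of ", path)
    }
    v
  })
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L || !ncol %in% 2:3) {
    stop("expected 2 or 3 numeric columns in ", path)
  }
  m <- do.call(rbind, rows)
  if (is.unsorted(m[, 1])) {
    warning("q column not ascending; sorting")
    m <- m[order(m[, 1]), , drop = FALSE]
  }
  scattering_curve(m[, 1], m[, 2],
                   sigma = if (ncol == 3) m[, 3] else NULL,
                   radiation = radiation, temperature = temperature,
                   absolute_scale = absolute_scale)
}

#' Write a scattering curve as 3-column (or 2-column) ASCII
#'
#' @param curve a [scattering_curve()].
#' @param path output file.
#' @param comment optional header comment (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_scattering <- function(curve, path, comment = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(paste("# q[1/A] I", if (!is.null(curve$sigma)) "sigma" else ""), con)
  d <- as.data.frame(curve)
  write.table(format(d, digits = 17, scientific = TRUE, trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DSC thermogram from CSV
#'
#' Two columns, temperature (degC) and mass-normalized heat-capacity signal,
#' with or without a header line.
#'
#' @param path file path.
#' @param scan_rate scan rate in degC/min (metadata).
#' @param composition optional [membrane_composition()].
#' @return a [thermogram()].
#' @export
read_thermogram <- function(path, scan_rate = 0.5, composition = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  header <- anyNA(suppressWarnings(as.numeric(strsplit(first, ",")[[1]])))
  d <- read.table(path, sep = ",", header = header)
  thermogram(d[[1]], d[[2]], scan_rate = scan_rate, composition = composition)
}

#' Write an analysis report to JSON or CSV
#'
#' JSON reports are schema-versioned and keep 17 significant digits so that a
#' write/read round trip is lossless. Fit results flag fixed parameters and
#' emit no uncertainty for them; CSV output flattens the numeric fields.
#'
#' @param results a named list, `sas_fit`, or data frame.
#' @param path output file.
#' @param format "json" or "csv".
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  payload <- report_payload(results)
  if (format == "json") {
    jsonlite::write_json(c(list(schema = "memscatter-report-1"), payload),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    flat <- unlist(payload)
    if (is.null(flat)) flat <- setNames(numeric(0), character(0))
    d <- data.frame(field = names(flat), value = as.character(flat))
    write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

report_payload <- function(results) {
  if (inherits(results, "sas_fit")) {
    list(
      model = results$model,
      params = as.list(results$params),
      se = as.list(results$se),
      fixed = as.list(results$fixed),
      chi2_reduced = results$chi2_reduced,
      q_window = results$q_window,
      converged = results$converged
    )
  } else if (is.data.frame(results)) {
    as.list(results)
  } else {
    as.list(results)
  }
}
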