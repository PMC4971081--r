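#' Write a sampled series as tabular text
#'
#' Plain-text interchange format: `#`-prefixed metadata header (sampling
#' interval plus any extra fields), then a header line and one row per
#' sample with a leading time column.
#'
#' @param x samples x channels matrix.
#' @param path output file.
#' @param dt sampling interval (seconds or ms; recorded verbatim).
#' @param meta named list of extra metadata strings.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, dt, meta = list()) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%s", format(dt, digits = 17)), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, meta[[nm]]), con)
  cn <- colnames(x)
  if (is.null(cn)) cn <- sprintf("ch%03d", seq_len(ncol(x)))
  writeLines(paste(c("time", cn), collapse = "\t"), con)
  if (nrow(x)) {
    t <- (seq_len(nrow(x)) - 1) * as.numeric(dt)
    utils::write.table(cbind(t, x), con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a series written by [write_series()]
#'
#' @param path input file.
#' @return matrix with attributes `dt` and `meta`; parse errors report the
#'   offending line number.
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !grepl("^# dt=", lines[1]))
    stop("malformed series header at line 1: expected '# dt=...'")
  meta <- list()
  for (i in hdr) {
    kv <- sub("^# ", "", lines[i])
    key <- sub("=.*", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  dt <- suppressWarnings(as.numeric(meta$dt))
  if (is.na(dt)) stop("malformed series header at line 1: bad dt value")
  body <- lines[-hdr]
  if (!length(body)) stop("malformed series file: missing column header")
  cols <- strsplit(body[1], "\t")[[1]]
  if (cols[1] != "time")
    stop("malformed series file at line ", length(hdr) + 1,
         ": first column must be 'time'")
  if (length(body) == 1) {
    out <- matrix(numeric(0), 0, length(cols) - 1,
                  dimnames = list(NULL, cols[-1]))
  } else {
    vals <- utils::read.table(text = body[-1], sep = "\t", header = FALSE)
    if (ncol(vals) != length(cols))
      stop("malformed series file at line ", length(hdr) + 2,
           ": column count mismatch")
    out <- as.matrix(vals[, -1, drop = FALSE])
    colnames(out) <- cols[-1]
  }
  attr(out, "dt") <- dt
  meta$dt <- NULL
  attr(out, "meta") <- meta
  out
}

#' Write recordings to a directory of series files
#'
#' Each recorded summary (module means and maxima, host-node activity,
#' response-module units, ROI integrated synaptic activity) becomes one
#' tabular text file; channel naming is `<module|node>/<unit>`.
#'
#' @param rec a `recordings` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_recordings <- function(rec, dir) {
  stopifnot(inherits(rec, "recordings"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt_s <- rec$dt / 1000
  if (!is.null(rec$mod_mean))
    write_series(rec$mod_mean, file.path(dir, "module_mean_E.tsv"), dt_s)
  if (!is.null(rec$mod_max))
    write_series(rec$mod_max, file.path(dir, "module_max_E.tsv"), dt_s)
  if (!is.null(rec$host_E))
    write_series(rec$host_E, file.path(dir, "host_E.tsv"), dt_s)
  if (!is.null(rec$fr_E)) {
    fr <- rec$fr_E
    colnames(fr) <- sprintf("FR/%02d", seq_len(ncol(fr)))
    write_series(fr, file.path(dir, "fr_units_E.tsv"), dt_s)
  }
  if (!is.null(rec$isa))
    write_series(rec$isa, file.path(dir, "isa.tsv"),
                 rec$isa_window_ms / 1000,
                 meta = list(kind = "integrated_synaptic_activity"))
  invisible(dir)
}

#' Read recordings written by [write_recordings()]
#'
#' @param dir directory written by [write_recordings()].
#' @return a `recordings` object holding the summaries found on disk.
#' @export
read_recordings <- function(dir) {
  grab <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_series(p) else NULL
  }
  mm <- grab("module_mean_E.tsv")
  if (is.null(mm)) stop("no recordings found in ", dir)
  out <- list(
    dt = attr(mm, "dt") * 1000,
    n_steps = nrow(mm),
    modules = colnames(mm),
    mod_mean = unclass_series(mm),
    mod_max = unclass_series(grab("module_max_E.tsv")),
    host_E = unclass_series(grab("host_E.tsv")),
    fr_E = unclass_series(grab("fr_units_E.tsv")))
  isa <- grab("isa.tsv")
  if (!is.null(isa)) {
    out$isa <- unclass_series(isa)
    out$isa_window_ms <- attr(isa, "dt") * 1000
  }
  structure(out, class = "recordings")
}

unclass_series <- function(x) {
  if (is.null(x)) return(NULL)
  attr(x, "dt") <- NULL
  attr(x, "meta") <- NULL
  x
}
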