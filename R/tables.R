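#' Sampled physiological trace
#'
#' A regularly sampled physiological recording (pulse oximeter, respiratory
#' belt, or expired CO2), with its sampling rate and acquisition-aligned
#' start time. The sampling rate is not stored in the TSV exchange format
#' and must be supplied when reading.
#'
#' @param samples Numeric vector of samples.
#' @param fs_hz Positive sampling rate in Hz.
#' @param kind One of `"pulse"`, `"respiratory"`, `"co2"`.
#' @param t0_s Acquisition-aligned start time in seconds (default 0).
#' @return An object of class `physio_trace`.
#' @export
physio_trace <- function(samples, fs_hz, kind = c("pulse", "respiratory", "co2"),
                         t0_s = 0) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  if (!is.finite(fs_hz) || fs_hz <= 0)
    stop("`fs_hz` must be positive", call. = FALSE)
  if (length(samples) < 2 * fs_hz)
    stop("trace must be at least 2 s long", call. = FALSE)
  structure(list(samples = samples, fs_hz = fs_hz, kind = kind,
                 t0_s = as.numeric(t0_s)),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("<physio_trace> %s, %d samples at %g Hz (%.1f s)\n",
              x$kind, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz))
  invisible(x)
}

#' Sample times of a physiological trace
#' @param trace A [physio_trace()].
#' @return Numeric vector of times in seconds.
#' @export
physio_times <- function(trace) {
  trace$t0_s + (seq_along(trace$samples) - 1) / trace$fs_hz
}

#' Read a physiological trace from TSV
#'
#' Expects a tab-delimited file with a header row and one numeric column
#' (the first column is used).
#'
#' @param path Path to the TSV file.
#' @param fs_hz Sampling rate in Hz (not recoverable from the file).
#' @param kind Trace kind; see [physio_trace()].
#' @param t0_s Acquisition-aligned start time, default 0.
#' @return A [physio_trace()].
#' @export
read_physio <- function(path, fs_hz, kind = c("pulse", "respiratory", "co2"),
                        t0_s = 0) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE)
  col <- tab[[1]]
  if (!is.numeric(col))
    stop("physio TSV column is not numeric", call. = FALSE)
  physio_trace(col, fs_hz = fs_hz, kind = kind, t0_s = t0_s)
}

#' Write a physiological trace to TSV
#' @param trace A [physio_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physio <- function(trace, path) {
  stopifnot(inherits(trace, "physio_trace"))
  df <- stats::setNames(data.frame(trace$samples), trace$kind)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

REGRESSOR_GROUPS <- c("task", "motion", "csf", "retro", "pca", "other")

#' Named, grouped regressor columns
#'
#' A tibble of regressor columns of common length T, each labeled with a
#' group in `task`, `motion`, `csf`, `retro`, `pca`, `other`. Groups drive
#' design assembly ([assemble_design()]) and omnibus F-tests.
#'
#' @param columns A data frame / tibble (or named list) of numeric columns
#'   of equal length.
#' @param groups Character vector of group labels, either length 1
#'   (recycled) or one per column.
#' @return An object of class `regressor_table` (a tibble subclass).
#' @export
regressor_table <- function(columns = list(), groups = character()) {
  tbl <- tibble::as_tibble(columns)
  if (ncol(tbl) > 0 && !all(vapply(tbl, is.numeric, TRUE)))
    stop("all regressor columns must be numeric", call. = FALSE)
  if (anyDuplicated(names(tbl)))
    stop("regressor names must be unique", call. = FALSE)
  if (ncol(tbl) > 0) {
    if (length(groups) == 1L) groups <- rep(groups, ncol(tbl))
    if (length(groups) != ncol(tbl))
      stop("`groups` must have one label per column", call. = FALSE)
  }
  if (!all(groups %in% REGRESSOR_GROUPS))
    stop("groups must be in {", paste(REGRESSOR_GROUPS, collapse = ", "), "}",
         call. = FALSE)
  attr(tbl, "regressor_groups") <- stats::setNames(as.character(groups),
                                                   names(tbl))
  class(tbl) <- c("regressor_table", class(tbl))
  tbl
}

#' @rdname regressor_table
#' @param x A `regressor_table`.
#' @return `regressor_groups()`: named character vector of group labels.
#' @export
regressor_groups <- function(x) attr(x, "regressor_groups")

#' Combine regressor tables column-wise
#' @param ... `regressor_table` objects of equal length.
#' @return A single [regressor_table()].
#' @export
bind_regressors <- function(...) {
  tabs <- Filter(function(t) !is.null(t) && ncol(t) > 0, list(...))
  if (length(tabs) == 0) return(regressor_table())
  lens <- vapply(tabs, nrow, 1L)
  if (length(unique(lens)) != 1L)
    stop("regressor tables have differing lengths", call. = FALSE)
  cols <- do.call(cbind, lapply(tabs, as.data.frame))
  groups <- unlist(lapply(tabs, regressor_groups), use.names = FALSE)
  regressor_table(cols, groups)
}

#' Read / write regressor tables as TSV
#'
#' Group labels are stored in a leading comment line `# groups: ...` so the
#' table round-trips.
#'
#' @param path TSV path.
#' @param groups Optional group labels overriding any stored in the file
#'   (default `"other"` when absent).
#' @return A [regressor_table()].
#' @export
read_regressors <- function(path, groups = NULL) {
  first <- readLines(path, n = 1L)
  stored <- NULL
  if (startsWith(first, "# groups:")) {
    stored <- strsplit(trimws(sub("^# groups:", "", first)), "[ \t]+")[[1]]
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#")
  if (!all(vapply(tab, is.numeric, TRUE)))
    stop("regressor TSV contains non-numeric columns", call. = FALSE)
  if (is.null(groups)) groups <- if (is.null(stored)) "other" else stored
  regressor_table(tab, groups)
}

#' @rdname read_regressors
#' @param x A [regressor_table()].
#' @export
write_regressors <- function(x, path) {
  stopifnot(inherits(x, "regressor_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# groups:", paste(regressor_groups(x), collapse = "\t")),
             con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
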