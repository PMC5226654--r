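#' Construct a multivariate spike-time dataset
#'
#' A `spike_dataset` holds spike times (seconds) of several simultaneously
#' recorded units over a common recording span. Times are sorted on
#' construction; unit identifiers are kept as character labels.
#'
#' @param spikes data frame with columns `unit_id` and `time` (seconds).
#'   An optional `source` column records per-spike provenance (used by the
#'   synthetic ground-truth generator).
#' @param span numeric length-2 vector `c(t_start, t_end)`; defaults to
#'   `c(0, max(time))`.
#' @param units character vector of unit identifiers, so that silent units
#'   can be represented; defaults to the units present in `spikes`.
#' @return An object of class `spike_dataset`: a list with elements
#'   `spikes` (sorted data frame), `units`, and `span`.
#' @export
spike_dataset <- function(spikes, span = NULL, units = NULL) {
  stopifnot(is.data.frame(spikes), all(c("unit_id", "time") %in% names(spikes)))
  if (nrow(spikes) > 0 && !is.numeric(spikes$time))
    stop("spike times must be numeric")
  spikes$unit_id <- as.character(spikes$unit_id)
  if (is.null(units)) units <- sort(unique(spikes$unit_id))
  if (anyDuplicated(units)) stop("unit identifiers must be unique")
  if (!all(spikes$unit_id %in% units))
    stop("spikes refer to units not listed in 'units'")
  if (is.null(span)) span <- c(0, if (nrow(spikes)) max(spikes$time) else 0)
  span <- as.numeric(span)
  if (length(span) != 2 || span[2] < span[1]) stop("invalid span")
  if (nrow(spikes) && (any(spikes$time < span[1]) || any(spikes$time > span[2])))
    stop("spike times outside recording span")
  ord <- order(match(spikes$unit_id, units), spikes$time)
  spikes <- spikes[ord, , drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, units = units, span = span),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("spike_dataset: %d units, %d spikes, span [%.3f, %.3f] s\n",
              length(x$units), nrow(x$spikes), x$span[1], x$span[2]))
  invisible(x)
}

#' Read a spike-time table from disk
#'
#' Expects a two-column text table `(unit_id, time_seconds)`, comma- or
#' tab-separated, with an optional header line. Duplicate rows are retained
#' (two spikes can legitimately occupy one elementary instant after binning)
#' with a warning.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`; guessed from the extension by default.
#' @param span optional recording span `c(t_start, t_end)`; defaults to
#'   `[0, last spike time]`.
#' @param min_rate if positive, units with mean firing rate below this value
#'   (Hz) are dropped, a common preprocessing step for very sparse units.
#'   Default 0 (keep everything).
#' @return A [spike_dataset].
#' @export
read_spike_dataset <- function(path, format = c("guess", "csv", "tsv"),
                               span = NULL, min_rate = 0) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  if (!file.exists(path)) stop("missing spike file: ", path)
  if (file.size(path) == 0) stop("empty spike file: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE, stringsAsFactors = FALSE,
                      strip.white = TRUE, comment.char = "#"),
    error = function(e) stop("could not read spike table: ", conditionMessage(e)))
  if (nrow(raw) == 0) stop("empty spike file: ", path)
  # tolerate a header line
  if (suppressWarnings(is.na(as.numeric(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop("empty spike file: ", path)
  times <- suppressWarnings(as.numeric(raw[, 2]))
  if (anyNA(times)) {
    bad <- which(is.na(times))[1]
    stop(sprintf("non-numeric spike time at line %d of %s", bad, path))
  }
  spk <- data.frame(unit_id = as.character(raw[, 1]), time = times,
                    stringsAsFactors = FALSE)
  ndup <- nrow(spk) - nrow(unique(spk))
  if (ndup > 0)
    warning(sprintf("%d duplicate (unit, time) rows retained as separate spikes", ndup))
  ds <- spike_dataset(spk, span = span)
  if (min_rate > 0) {
    dur <- diff(ds$span)
    rates <- vapply(ds$units,
                    function(u) sum(ds$spikes$unit_id == u) / dur, 0)
    keep <- ds$units[rates >= min_rate]
    ds <- spike_dataset(ds$spikes[ds$spikes$unit_id %in% keep, , drop = FALSE],
                        span = ds$span, units = keep)
  }
  ds
}

#' Bin a spike dataset into equal-width count series
#'
#' Bin i (1-based) covers the half-open interval
#' `[t_start + (i-1) * delta, t_start + i * delta)`; a trailing partial bin
#' is dropped so that all count statistics see equal-width bins. All units
#' share the same number of bins `T = floor(span / delta)`.
#'
#' @param dataset a [spike_dataset].
#' @param delta bin width in seconds (> 0, at most the span length).
#' @return An object of class `binned_spikes`: list with `counts`
#'   (integer matrix, T rows x N unit columns), `delta`, `t_start`,
#'   `unit_ids`.
#' @export
bin_dataset <- function(dataset, delta) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a positive number")
  dur <- diff(dataset$span)
  if (delta > dur) stop("delta exceeds the recording span")
  T <- floor(dur / delta + 1e-9)
  if (T < 1) stop("no complete bin fits into the span")
  counts <- matrix(0L, nrow = T, ncol = length(dataset$units),
                   dimnames = list(NULL, dataset$units))
  if (nrow(dataset$spikes)) {
    idx <- floor((dataset$spikes$time - dataset$span[1]) / delta) + 1L
    ok <- idx >= 1L & idx <= T
    u <- match(dataset$spikes$unit_id, dataset$units)
    for (j in seq_along(dataset$units)) {
      sel <- ok & u == j
      if (any(sel)) counts[, j] <- tabulate(idx[sel], nbins = T)
    }
  }
  structure(list(counts = counts, delta = delta,
                 t_start = dataset$span[1], unit_ids = dataset$units),
            class = "binned_spikes")
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("binned_spikes: %d units x %d bins at delta = %g s\n",
              ncol(x$counts), nrow(x$counts), x$delta))
  invisible(x)
}

#' Extract one unit's count series
#'
#' @param binned a `binned_spikes` object.
#' @param unit unit identifier or column index.
#' @return A `count_series`: list with `unit_id`, `delta`, `counts`,
#'   `max_count`.
#' @export
count_series <- function(binned, unit) {
  stopifnot(inherits(binned, "binned_spikes"))
  j <- if (is.character(unit)) match(unit, binned$unit_ids) else as.integer(unit)
  if (is.na(j) || j < 1 || j > ncol(binned$counts)) stop("unknown unit: ", unit)
  cnt <- binned$counts[, j]
  structure(list(unit_id = binned$unit_ids[j], delta = binned$delta,
                 counts = cnt, max_count = max(cnt)),
            class = "count_series")
}

#' Remove the non-informative floor count from a count series
#'
#' At very coarse bin widths a series may never drop below some minimum
#' count; those baseline spikes carry no information about co-fluctuations
#' and would bias the coincidence statistics, so the series minimum is
#' subtracted. A no-op when the minimum is already zero. Idempotent.
#'
#' @param counts integer vector of bin counts, or a `count_series`.
#' @return Same type as the input, floor-subtracted.
#' @export
subtract_floor <- function(counts) {
  if (inherits(counts, "count_series")) {
    counts$counts <- subtract_floor(counts$counts)
    counts$max_count <- max(counts$counts)
    return(counts)
  }
  if (length(counts) == 0) return(counts)
  counts - min(counts)
}
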