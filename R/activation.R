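#' Assembly activation instants in a spike dataset
#'
#' Locates every occurrence of an assembly's full lag constellation in the
#' binned spike data at the assembly's bin width. An instance exists at
#' anchor bin t when every member's bin at its prescribed lag offset is
#' non-empty; each combination of member spikes is counted, so the
#' multiplicity of anchor bin t is the product of the member bin counts.
#' The activation time point of an instance is that of the earliest-spiking
#' member (the anchor, lag 0): each anchor-unit spike in bin t is reported,
#' repeated once per combination of the other members' spikes.
#'
#' @param dataset a [spike_dataset] containing all assembly units.
#' @param assembly an assembly record with fields `unit_ids` (or `units`
#'   as identifiers), `lags` (bins, anchor first at 0), and `delta`
#'   (seconds); e.g. an element of an `assembly_catalog`.
#' @return An `activation_record`: list with `instants` (sorted seconds),
#'   `score` (activations per bin, see [activation_score]), `delta`.
#' @export
activation_times <- function(dataset, assembly) {
  stopifnot(inherits(dataset, "spike_dataset"))
  ids <- if (!is.null(assembly$unit_ids)) assembly$unit_ids else assembly$units
  if (!all(ids %in% dataset$units))
    stop("assembly unit(s) missing from dataset: ",
         paste(setdiff(ids, dataset$units), collapse = ", "))
  delta <- assembly$delta
  lags <- as.integer(assembly$lags)
  binned <- bin_dataset(dataset, delta)
  score <- activation_score(dataset, assembly, delta, binned = binned)
  anchor <- ids[1]
  others <- seq_along(ids)[-1]
  cnt <- binned$counts
  T <- nrow(cnt)
  spk_a <- dataset$spikes$time[dataset$spikes$unit_id == anchor]
  bin_a <- floor((spk_a - dataset$span[1]) / delta) + 1L
  keep <- bin_a >= 1L & bin_a <= T
  spk_a <- spk_a[keep]; bin_a <- bin_a[keep]
  inst <- numeric(0)
  active_bins <- which(score > 0)
  for (t in active_bins) {
    mult <- 1
    for (j in others) mult <- mult * cnt[t + lags[j], ids[j]]
    ts <- spk_a[bin_a == t]
    if (length(ts) && mult > 0) inst <- c(inst, rep(ts, each = mult))
  }
  structure(list(instants = sort(inst), score = score, delta = delta),
            class = "activation_record")
}

#' Binned assembly activation score
#'
#' The number of assembly activation instances anchored in each bin of
#' width `delta`: the product of the member bin counts at the prescribed
#' lag offsets (zero when any member is silent there). Scores can greatly
#' exceed one, especially for assemblies defined by rate increases at
#' coarse scales. The series sums to the total number of activation
#' instants.
#'
#' @inheritParams activation_times
#' @param delta bin width in seconds; defaults to the assembly's own.
#' @param binned optional pre-binned `binned_spikes` at `delta`.
#' @return Numeric vector of length T (activations per bin).
#' @export
activation_score <- function(dataset, assembly, delta = assembly$delta,
                             binned = NULL) {
  stopifnot(delta > 0)
  ids <- if (!is.null(assembly$unit_ids)) assembly$unit_ids else assembly$units
  lags <- as.integer(assembly$lags)
  if (is.null(binned)) binned <- bin_dataset(dataset, delta)
  cnt <- binned$counts
  T <- nrow(cnt)
  maxlag <- max(lags)
  score <- numeric(T)
  if (T > maxlag) {
    tt <- seq_len(T - maxlag)
    prod <- rep(1, length(tt))
    for (j in seq_along(ids)) prod <- prod * cnt[tt + lags[j], ids[j]]
    score[tt] <- prod
  }
  score
}
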