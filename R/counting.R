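#' Decompose a count series into nested binary layers
#'
#' Layer alpha (alpha = 1..M, M the maximum bin count) has a 1 wherever the
#' count is at least alpha, so the layers are nested and their elementwise
#' sum reconstructs the counts. All coincidence statistics in this package
#' operate on matched layers of two such stacks.
#'
#' @param counts integer vector of bin counts, or a `count_series`.
#' @return A `binary_layer_stack`: list with `layers` (M x T 0/1 integer
#'   matrix; zero rows when the unit is silent), `layer_totals`,
#'   `max_count`, `counts`, `silent` flag.
#' @export
binary_layers <- function(counts) {
  unit_id <- NA_character_
  if (inherits(counts, "count_series")) {
    unit_id <- counts$unit_id
    counts <- counts$counts
  }
  counts <- as.integer(counts)
  M <- if (length(counts)) max(counts) else 0L
  layers <- if (M > 0)
    t(vapply(seq_len(M), function(a) as.integer(counts >= a),
             integer(length(counts))))
  else matrix(0L, nrow = 0, ncol = length(counts))
  structure(list(unit_id = unit_id, layers = layers,
                 layer_totals = if (M > 0) rowSums(layers) else numeric(0),
                 max_count = M, counts = counts, silent = M == 0L),
            class = "binary_layer_stack")
}

.as_counts <- function(x) {
  if (inherits(x, "binary_layer_stack")) return(x$counts)
  if (inherits(x, "count_series")) return(as.integer(x$counts))
  as.integer(x)
}

#' Lagged joint coincidence count of two units
#'
#' The number of matched spike coincidences between units A and B at a lag
#' of `lag` bins (positive lag: B follows A), summed across matched binary
#' layers alpha = 1..min(M_A, M_B). For nested layers this equals
#' `sum_t min(c_A[t], c_B[t + lag])`, which is how it is computed.
#'
#' @param A,B count vectors, `count_series`, or `binary_layer_stack`s of
#'   equal length.
#' @param lag integer lag in bins, `|lag| < T`.
#' @return Non-negative joint count.
#' @export
joint_count <- function(A, B, lag) {
  a <- .as_counts(A); b <- .as_counts(B)
  stopifnot(length(a) == length(b))
  lag <- as.integer(lag)
  if (abs(lag) >= length(a)) stop("|lag| must be smaller than the series length")
  .cpp_joint_count(a, b, lag)
}

#' Joint-count lag profile of a unit pair
#'
#' Computes the joint count at every lag in `-l_max..l_max` and selects the
#' lag with the highest count. Ties are broken towards the smallest `|lag|`,
#' then towards the non-negative lag, favouring the synchrony
#' interpretation. The pair is flagged non-testable when all counts vanish.
#'
#' @param A,B count vectors, `count_series`, or `binary_layer_stack`s.
#' @param l_max maximum lag in bins (>= 0, < T).
#' @return A `pair_profile`: list with `lags`, `joint_counts`,
#'   `selected_lag`, `selected_count`, `testable`.
#' @export
lag_profile <- function(A, B, l_max) {
  a <- .as_counts(A); b <- .as_counts(B)
  stopifnot(length(a) == length(b), l_max >= 0, l_max < length(a))
  lags <- seq.int(-l_max, l_max)
  counts <- .cpp_lag_profile(a, b, as.integer(l_max))
  sel <- select_lag(lags, counts)
  structure(list(lags = lags, joint_counts = counts, selected_lag = sel,
                 selected_count = counts[match(sel, lags)],
                 testable = any(counts > 0)),
            class = "pair_profile")
}

# argmax over lags with deterministic tie-breaking:
# smallest |lag| first, then the non-negative one.
select_lag <- function(lags, counts) {
  best <- which(counts == max(counts))
  ord <- order(abs(lags[best]), lags[best] < 0)
  lags[best[ord[1]]]
}
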