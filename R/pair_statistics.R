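# Overlapping windows of the two series at a given lag: for lag >= 0 the
# A-window is 1..T-lag and the B-window is (1+lag)..T (and mirrored for
# negative lags), so that forward and reference counts use comparable
# marginals recomputed on the window of length T - |lag|.
.lag_windows <- function(T, lag) {
  l <- abs(lag)
  if (lag >= 0)
    list(a = c(1L, T - l), b = c(1L + l, T))
  else
    list(a = c(1L + l, T), b = c(1L, T - l))
}

# layer totals #X^alpha, alpha = 1..max count, on bins from..to
.layer_totals <- function(x, from = 1L, to = length(x)) {
  w <- x[from:to]
  M <- max(w, 0L)
  if (M == 0L) return(numeric(0))
  tab <- tabulate(w, nbins = M)
  rev(cumsum(rev(as.numeric(tab))))
}

# Multivariate-hypergeometric variance of the joint count from layer
# totals on a window of length n; the cross-layer covariance terms use the
# higher-rank totals weighted by the lower-rank window factors.
.hyper_var <- function(Atot, Btot, n) {
  M <- min(length(Atot), length(Btot))
  if (M == 0 || n < 2) return(0)
  n <- as.numeric(n)
  A <- as.numeric(Atot[seq_len(M)]); B <- as.numeric(Btot[seq_len(M)])
  Fct <- (n - A) * (n - B)
  W <- A * B
  sum(W * (2 * cumsum(Fct) - Fct)) / (n^2 * (n - 1))
}

#' Null moments of the lagged joint count
#'
#' Mean and variance of the joint count of two units at a given lag under
#' the null hypothesis of independence, from the first two moments of a
#' multivariate hypergeometric distribution over matched binary layers.
#' Marginal layer totals are computed on the overlapping window of length
#' `T - |lag|`.
#'
#' @param A,B count vectors, `count_series`, or `binary_layer_stack`s.
#' @param lag lag in bins.
#' @return List with `mean`, `variance`, `effective_length`.
#' @export
hypergeometric_moments <- function(A, B, lag) {
  a <- .as_counts(A); b <- .as_counts(B)
  stopifnot(length(a) == length(b))
  T <- length(a)
  if (abs(lag) >= T) stop("|lag| must be smaller than the series length")
  Tt <- T - abs(lag)
  if (Tt <= 1) stop("effective window length must exceed 1")
  w <- .lag_windows(T, lag)
  Atot <- .layer_totals(a, w$a[1], w$a[2])
  Btot <- .layer_totals(b, w$b[1], w$b[2])
  M <- min(length(Atot), length(Btot))
  mu <- if (M == 0) 0 else sum(Atot[seq_len(M)] * Btot[seq_len(M)]) / Tt
  list(mean = mu, variance = .hyper_var(Atot, Btot, Tt),
       effective_length = Tt)
}

#' Uncorrected standardized joint-count statistic
#'
#' The joint count standardized by its null moments,
#' `S = (#AB - mu) / sigma`, approximately t-distributed with
#' `2(T - |lag|) M - 1` degrees of freedom under a *stationary* null. This
#' statistic is not corrected for non-stationarity and is provided for
#' calibration studies only; detection uses the corrected [pair_test].
#'
#' @inheritParams hypergeometric_moments
#' @return List with `statistic`, `dof`, `p_value` (two-sided).
#' @export
uncorrected_statistic <- function(A, B, lag) {
  a <- .as_counts(A); b <- .as_counts(B)
  mom <- hypergeometric_moments(a, b, lag)
  if (mom$variance <= 0) stop("zero null variance: statistic undefined")
  M <- min(max(a), max(b))
  S <- (joint_count(a, b, lag) - mom$mean) / sqrt(mom$variance)
  v <- 2 * mom$effective_length * M - 1
  list(statistic = S, dof = v,
       p_value = 2 * stats::pt(abs(S), df = v, lower.tail = FALSE))
}

#' Non-stationarity-corrected difference count
#'
#' The forward joint count minus the joint count at a reference lag,
#' `#ABBA = #AB,sel - #AB,ref`. Slow rate (co-)fluctuations affect both
#' terms alike and cancel locally, so the difference has null mean zero
#' even under coupled non-stationarity on scales slower than `|lag| * delta`.
#'
#' @inheritParams hypergeometric_moments
#' @param selected_lag lag of interest (bins).
#' @param reference_lag reference lag (bins), distinct from `selected_lag`;
#'   see [reference_lag_for] for the default policy.
#' @return Signed difference of the two joint counts.
#' @export
difference_count <- function(A, B, selected_lag, reference_lag) {
  if (selected_lag == reference_lag)
    stop("reference lag must differ from the selected lag")
  joint_count(A, B, selected_lag) - joint_count(A, B, reference_lag)
}

#' Reference-lag policy
#'
#' The default (`"mirror"`) pairs each lag with its time reverse,
#' `l* = -l`, and uses `l* = -2` for the synchronous case `l = 0` (a
#' neighbouring bin would risk removing true structure through spillover).
#' The `"fixed"` policy uses `l* = -(l_max + 1)` for every lag, which keeps
#' the correction timescale identical across lags (a robustness check).
#'
#' @param selected_lag lag of interest (bins).
#' @param policy `"mirror"` or `"fixed"`.
#' @param l_max maximum tested lag (needed for `"fixed"`).
#' @return Reference lag in bins.
#' @export
reference_lag_for <- function(selected_lag, policy = c("mirror", "fixed"),
                              l_max = NULL) {
  policy <- match.arg(policy)
  if (policy == "fixed") {
    if (is.null(l_max)) stop("l_max required for the fixed reference policy")
    return(-(l_max + 1L))
  }
  if (selected_lag == 0L) -2L else -selected_lag
}

#' Segmentation scheme for the variance estimate
#'
#' Contiguous segments of `k` bins; a trailing remainder of at least
#' `2 (|lag| + 1)` bins forms a final shorter segment, otherwise it is
#' merged into the previous segment so no segment is degenerate.
#'
#' @param T series length in bins.
#' @param k segment length in bins (default 100).
#' @param lag selected lag (bins), used for the degenerate-remainder rule.
#' @return Data frame with `start`, `end` (1-based inclusive).
#' @export
segment_scheme <- function(T, k = 100L, lag = 0L) {
  k <- as.integer(k)
  if (k <= 1) stop("segment length k must exceed 1")
  if (k <= abs(lag) + 1) stop("segment length k must exceed |lag| + 1")
  if (T <= k) return(data.frame(start = 1L, end = as.integer(T)))
  C <- T %/% k
  start <- seq.int(1L, by = k, length.out = C)
  end <- start + k - 1L
  rem <- T - C * k
  if (rem >= 2 * (abs(lag) + 1)) {
    start <- c(start, C * k + 1L)
    end <- c(end, as.integer(T))
  } else if (rem > 0) {
    end[C] <- as.integer(T)
  }
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Segmented variance of the corrected difference count
#'
#' Estimates `Var(#ABBA)` as
#' `2 sum_c var(#AB,c) - 2 sum_c cov(#AB,c, #BA,c)`, with within-segment
#' hypergeometric variances and within-segment forward/reverse covariances
#' `cov_c = -var_c / (k_c - 1)`; cross-segment covariance terms are
#' omitted. Short segments make the estimate robust to non-stationarity,
#' since within a segment the process is approximately stationary.
#'
#' @inheritParams difference_count
#' @param k segment length in bins (default 100).
#' @return Non-negative variance estimate.
#' @export
segmented_variance <- function(A, B, selected_lag, reference_lag = NULL,
                               k = 100L) {
  a <- .as_counts(A); b <- .as_counts(B)
  stopifnot(length(a) == length(b))
  segs <- segment_scheme(length(a), k = k, lag = selected_lag)
  .cpp_segmented_variance(a, b, segs$start, segs$end)
}

#' Corrected pairwise statistic at a fixed lag
#'
#' Computes the difference count, its segmented variance, the F-statistic
#' `Q = #ABBA^2 / sigma^2`, and the upper-tail p-value of `F(1, v)` at a
#' *given* lag (no lag selection). Used both by [pair_test] and by
#' calibration studies at fixed lags.
#'
#' @inheritParams difference_count
#' @param k segment length in bins (default 100).
#' @param dof one of `"standard"` (`v = 2 (T - |lag|) M - 1`),
#'   `"conservative"` (`v = T - |lag|`), or `"auto"` (conservative when
#'   `T < 50`).
#' @return List with `joint_count`, `reference_count`, `difference`,
#'   `variance`, `Q`, `dof`, `p_value`, `null_mean` (expected joint count,
#'   used for the validity gate), `M`, `testable`.
#' @export
pair_statistic <- function(A, B, selected_lag, reference_lag = NULL,
                           k = 100L, dof = c("standard", "conservative", "auto")) {
  dof <- match.arg(dof)
  a <- .as_counts(A); b <- .as_counts(B)
  stopifnot(length(a) == length(b))
  T <- length(a)
  if (is.null(reference_lag)) reference_lag <- reference_lag_for(selected_lag)
  M <- min(max(a), max(b))
  if (M == 0L)
    return(list(joint_count = 0, reference_count = 0, difference = 0,
                variance = 0, Q = NA_real_, dof = NA_real_, p_value = 1,
                null_mean = 0, M = 0L, testable = FALSE))
  fwd <- joint_count(a, b, selected_lag)
  ref <- joint_count(a, b, reference_lag)
  mu <- hypergeometric_moments(a, b, selected_lag)$mean
  v2 <- segmented_variance(a, b, selected_lag, reference_lag, k = k)
  dd <- fwd - ref
  Tt <- T - abs(selected_lag)
  vdof <- switch(dof,
                 standard = 2 * Tt * M - 1,
                 conservative = Tt,
                 auto = if (T < 50) Tt else 2 * Tt * M - 1)
  if (v2 <= 0) {
    # a non-zero difference with zero estimated variance is not evidence;
    # flag untestable rather than producing an infinite statistic
    return(list(joint_count = fwd, reference_count = ref, difference = dd,
                variance = 0, Q = NA_real_, dof = vdof, p_value = 1,
                null_mean = mu, M = M, testable = FALSE))
  }
  Q <- dd^2 / v2
  list(joint_count = fwd, reference_count = ref, difference = dd,
       variance = v2, Q = Q, dof = vdof,
       p_value = stats::pf(Q, 1, vdof, lower.tail = FALSE),
       null_mean = mu, M = M, testable = TRUE)
}

#' Full corrected pair test with lag selection
#'
#' Screens all lags in `-l_max..l_max`, selects the lag with the highest
#' joint count, and tests the corrected difference statistic at that lag.
#' The test's approximations require an expected joint count above 4; pairs
#' below that gate are flagged untested. Significance additionally requires
#' a positive difference (excess in the selected direction) and
#' `p <= corrected_alpha`.
#'
#' @inheritParams lag_profile
#' @param l_max maximum lag in bins.
#' @param corrected_alpha significance level after multiplicity correction.
#' @param k segment length in bins for the variance estimate.
#' @param reference `"mirror"` or `"fixed"` reference-lag policy.
#' @param dof degrees-of-freedom policy, see [pair_statistic].
#' @param floor_correct subtract the floor count from both series first,
#'   when both series have a positive minimum (relevant at coarse bin
#'   widths only).
#' @return A `pair_test_result`: the [pair_statistic] fields plus
#'   `selected_lag`, `reference_lag`, `gate_passed`, `significant`.
#' @export
pair_test <- function(A, B, l_max, corrected_alpha = 0.05, k = 100L,
                      reference = c("mirror", "fixed"),
                      dof = c("standard", "conservative", "auto"),
                      floor_correct = TRUE) {
  reference <- match.arg(reference)
  dof <- match.arg(dof)
  a <- .as_counts(A); b <- .as_counts(B)
  if (floor_correct && length(a) && min(a) > 0L && min(b) > 0L) {
    a <- a - min(a)
    b <- b - min(b)
  }
  prof <- lag_profile(a, b, l_max)
  if (!prof$testable) {
    res <- list(selected_lag = 0L, reference_lag = -2L, joint_count = 0,
                reference_count = 0, difference = 0, variance = 0,
                Q = NA_real_, dof = NA_real_, p_value = 1, null_mean = 0,
                M = 0L, testable = FALSE, gate_passed = FALSE,
                significant = FALSE)
    class(res) <- "pair_test_result"
    return(res)
  }
  sel <- prof$selected_lag
  ref <- reference_lag_for(sel, reference, l_max = l_max)
  res <- pair_statistic(a, b, sel, ref, k = k, dof = dof)
  res$selected_lag <- sel
  res$reference_lag <- ref
  res$gate_passed <- res$testable && res$null_mean > 4
  res$significant <- res$gate_passed && res$difference > 0 &&
    res$p_value <= corrected_alpha
  class(res) <- "pair_test_result"
  res
}

#' @export
print.pair_test_result <- function(x, ...) {
  cat(sprintf(
    "pair test: lag %d (ref %d), #AB = %g, #ABBA = %g, Q = %.3g, p = %.3g%s\n",
    x$selected_lag, x$reference_lag, x$joint_count, x$difference,
    if (is.na(x$Q)) NA else x$Q, x$p_value,
    if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}
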