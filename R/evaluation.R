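# coerce a partition (list of unit-id vectors) to a block-label vector
# over a universe; units outside every block become singletons
.partition_labels <- function(partition, universe) {
  lab <- paste0(".single.", seq_along(universe))
  names(lab) <- universe
  for (i in seq_along(partition)) {
    mem <- intersect(partition[[i]], universe)
    lab[mem] <- paste0("block", i)
  }
  lab
}

#' Rand index between a true and a detected unit partition
#'
#' `R = (r + s) / (n (n - 1) / 2)` where `r` counts unit pairs placed in
#' the same assembly in both partitions and `s` pairs placed in different
#' assemblies in both. Units of the comparison universe that belong to no
#' assembly count as singleton blocks. By default the universe is the
#' union of true and detected assembly members.
#'
#' @param truth,detected partitions: lists of unit-id vectors (a
#'   `ground_truth` or `assembly_catalog` is accepted and converted; a
#'   catalog's overlapping memberships are resolved lowest-p-first).
#' @param universe unit ids to compare over; default is the union of the
#'   two partitions' members.
#' @return A `partition_comparison`: list with `r`, `s`, `n`,
#'   `rand_index`.
#' @export
rand_index <- function(truth, detected, universe = NULL) {
  truth <- .as_partition(truth)
  detected <- .as_partition(detected)
  if (is.null(universe))
    universe <- union(unlist(truth), unlist(detected))
  universe <- unique(as.character(universe))
  n <- length(universe)
  if (n == 0) stop("empty comparison universe")
  lt <- .partition_labels(truth, universe)
  ld <- .partition_labels(detected, universe)
  r <- 0L; s <- 0L
  if (n > 1) {
    cmb <- utils::combn(n, 2)
    same_t <- lt[cmb[1, ]] == lt[cmb[2, ]]
    same_d <- ld[cmb[1, ]] == ld[cmb[2, ]]
    r <- sum(same_t & same_d)
    s <- sum(!same_t & !same_d)
  }
  structure(list(r = r, s = s, n = n,
                 rand_index = if (n > 1) (r + s) / (n * (n - 1) / 2) else 1),
            class = "partition_comparison")
}

.as_partition <- function(x) {
  if (inherits(x, "ground_truth")) return(truth_partition(x))
  if (inherits(x, "assembly_catalog")) return(catalog_partition(x))
  stopifnot(is.list(x))
  if (!is.null(x$members)) return(list(as.character(x$members)))  # one record
  if (all(vapply(x, function(e) is.list(e) && !is.null(e$members), TRUE)) &&
      length(x))
    return(lapply(x, function(e) as.character(e$members)))
  lapply(x, as.character)
}

#' Resolve an assembly catalog into a unit partition
#'
#' Units detected in several assemblies are assigned to the one with the
#' lowest p-value, so the result is a proper partition of the detected
#' assembly units.
#'
#' @param catalog an `assembly_catalog`.
#' @return List of unit-id vectors (empty list for an empty catalog).
#' @export
catalog_partition <- function(catalog) {
  stopifnot(inherits(catalog, "assembly_catalog"))
  if (!length(catalog$assemblies)) return(list())
  ord <- order(vapply(catalog$assemblies, `[[`, 0, "p"))
  taken <- character(0)
  out <- list()
  for (i in ord) {
    mem <- setdiff(catalog$assemblies[[i]]$unit_ids, taken)
    if (length(mem) >= 2) {
      out[[length(out) + 1L]] <- mem
      taken <- c(taken, mem)
    }
  }
  out
}

#' Retrieval score and false-assignment fraction
#'
#' Each detected assembly is matched to the true assembly with maximal
#' member overlap (ties resolved towards the lower p-value). The retrieval
#' score is the fraction of true assembly members assigned to their
#' matched detected assembly; the false fraction is the fraction of
#' detected assembly units that are not members of the matched true
#' assembly (units belonging to no true assembly count against every
#' match).
#'
#' @param truth a `ground_truth` or a partition (list of member vectors).
#' @param catalog an `assembly_catalog` or a detected partition.
#' @return List with `retrieval`, `false_fraction`, `matching` (data
#'   frame of detected-to-true matches).
#' @export
retrieval_metrics <- function(truth, catalog) {
  tp <- .as_partition(truth)
  dp <- .as_partition(catalog)
  n_true <- sum(lengths(tp))
  if (!length(dp))
    return(list(retrieval = 0, false_fraction = 0,
                matching = data.frame(detected = integer(0),
                                      true = integer(0))))
  match_of <- integer(length(dp))
  for (i in seq_along(dp)) {
    ov <- vapply(tp, function(m) length(intersect(dp[[i]], m)), 0L)
    match_of[i] <- if (length(ov) && max(ov) > 0) which.max(ov) else NA_integer_
  }
  correct <- 0L
  false_units <- 0L
  detected_units <- 0L
  for (i in seq_along(dp)) {
    detected_units <- detected_units + length(dp[[i]])
    if (is.na(match_of[i])) {
      false_units <- false_units + length(dp[[i]])
    } else {
      inm <- length(intersect(dp[[i]], tp[[match_of[i]]]))
      correct <- correct + inm
      false_units <- false_units + length(dp[[i]]) - inm
    }
  }
  list(retrieval = if (n_true > 0) correct / n_true else 0,
       false_fraction = if (detected_units > 0)
         false_units / detected_units else 0,
       matching = data.frame(detected = seq_along(dp), true = match_of))
}

#' Assembly-assignment matrix
#'
#' Rows are units, columns are detected assemblies sorted by bin width
#' then p-value; a cell holds the member's lag (in bins) relative to the
#' assembly's leading unit, and is empty (NA) for non-members. The first
#' two rows of the returned data frame record each column's bin width and
#' characteristic scale.
#'
#' @param catalog an `assembly_catalog`.
#' @return Data frame with one row per unit (plus attribute rows `delta`
#'   and `delta_star` returned as the first two rows), columns per
#'   assembly.
#' @export
assignment_matrix <- function(catalog) {
  stopifnot(inherits(catalog, "assembly_catalog"))
  units <- catalog$unit_ids
  asms <- catalog$assemblies
  if (length(asms)) {
    ord <- order(vapply(asms, `[[`, 0, "delta"),
                 vapply(asms, `[[`, 0, "p"))
    asms <- asms[ord]
  }
  mat <- matrix(NA_real_, nrow = length(units) + 2, ncol = length(asms),
                dimnames = list(c("delta", "delta_star", units),
                                if (length(asms))
                                  paste0("assembly", seq_along(asms))
                                else character(0)))
  for (j in seq_along(asms)) {
    mat["delta", j] <- asms[[j]]$delta
    mat["delta_star", j] <- asms[[j]]$delta_star
    mat[asms[[j]]$unit_ids, j] <- asms[[j]]$lags
  }
  as.data.frame(mat)
}

#' Per-scale retrieval of each true assembly
#'
#' For every bin width tested and every true assembly, the fraction of its
#' members present in the best-overlapping assembly detected at that scale
#' (0 when nothing overlaps). This is the data behind retrieval-versus-
#' bin-width curves, which characterize each assembly's temporal scale.
#'
#' @param truth a `ground_truth` (or partition list).
#' @param catalog an `assembly_catalog`.
#' @return Numeric matrix, true assemblies x bin widths.
#' @export
retrieval_by_scale <- function(truth, catalog) {
  stopifnot(inherits(catalog, "assembly_catalog"))
  tp <- .as_partition(truth)
  deltas <- catalog$deltas
  out <- matrix(0, nrow = length(tp), ncol = length(deltas),
                dimnames = list(names(tp), as.character(deltas)))
  for (d in seq_along(deltas)) {
    at_d <- Filter(function(a) a$delta == deltas[d], catalog$assemblies)
    if (!length(at_d)) next
    for (i in seq_along(tp)) {
      ov <- vapply(at_d, function(a)
        length(intersect(a$unit_ids, tp[[i]])), 0L)
      out[i, d] <- max(ov) / length(tp[[i]])
    }
  }
  out
}
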