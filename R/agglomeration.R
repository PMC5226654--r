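#' Bonferroni test budget for pair screening
#'
#' At the pair-screening step every unordered unit pair is tested across
#' all `2 l_max + 1` lags, so `R1 = N (N - 1) (2 l_max + 1) / 2` tests are
#' budgeted and each is run at level `alpha / R1`. Later agglomeration
#' steps use `R_i = N_assemblies * N_candidates * (2 l_max + 1)` per step.
#'
#' @param n_units number of units N.
#' @param l_max maximum lag in bins.
#' @param alpha family-wise level (default 0.05).
#' @return List with `alpha`, `R1`, `corrected_alpha`.
#' @export
test_budget <- function(n_units, l_max, alpha = 0.05) {
  R1 <- n_units * (n_units - 1) * (2 * l_max + 1) / 2
  list(alpha = alpha, R1 = R1, corrected_alpha = alpha / R1)
}

#' Activation count series of an assembly
#'
#' The per-bin number of complete lag constellations anchored at each bin:
#' `min_j counts[t + lag_j, unit_j]`, zero where the constellation runs
#' past the recording end. Matched-layer counting keeps the series on the
#' same scale as single-unit counts (for a pair it sums to the pairwise
#' joint count), so an assembly can be paired against further units exactly
#' like a unit.
#'
#' @param binned a `binned_spikes` object.
#' @param units unit identifiers or column indices (anchor first).
#' @param lags non-negative integer lags (bins) relative to the anchor;
#'   first element must be 0.
#' @return Integer vector of length T.
#' @export
assembly_series <- function(binned, units, lags) {
  stopifnot(inherits(binned, "binned_spikes"), length(units) == length(lags))
  if (lags[1] != 0L || any(lags < 0L))
    stop("lags must be non-negative with the anchor at 0")
  idx <- if (is.character(units)) match(units, binned$unit_ids) else as.integer(units)
  if (anyNA(idx)) stop("unknown unit in assembly")
  .cpp_assembly_series(binned$counts, idx, as.integer(lags))
}

# normalize a lag vector so the earliest unit carries lag 0 and units are
# ordered by lag (stable in the original order for ties)
.normalize_assembly <- function(units, lags) {
  lags <- lags - min(lags)
  ord <- order(lags, seq_along(lags))
  list(units = units[ord], lags = as.integer(lags[ord]))
}

.assembly_key <- function(units) paste(sort(units), collapse = "|")

#' Screen all unit pairs for significant lagged dependence
#'
#' Tests every unordered unit pair at all lags in `-l_max..l_max` with the
#' corrected pair test at the Bonferroni level `alpha / R1`. Significant
#' pairs become elementary two-unit assemblies; the symmetric logical
#' matrix `Z` records which single-unit pairs were significantly related
#' (used to restrict candidates during agglomeration).
#'
#' @param binned a `binned_spikes` object.
#' @param l_max maximum lag in bins.
#' @param alpha family-wise significance level.
#' @param k segment length in bins for the variance estimate.
#' @param reference,dof,floor_correct passed to [pair_test].
#' @return List with `assemblies` (list of elementary assemblies), `Z`
#'   (N x N logical), `pair_table` (one row per tested pair), `budget`.
#' @export
seed_pairs <- function(binned, l_max, alpha = 0.05, k = 100L,
                       reference = "mirror", dof = "auto",
                       floor_correct = TRUE) {
  stopifnot(inherits(binned, "binned_spikes"))
  N <- ncol(binned$counts)
  if (N < 2) stop("need at least two units")
  budget <- test_budget(N, l_max, alpha)
  Z <- matrix(FALSE, N, N, dimnames = list(binned$unit_ids, binned$unit_ids))
  assemblies <- list()
  rows <- vector("list", N * (N - 1) / 2)
  r <- 0L
  for (i in seq_len(N - 1)) {
    for (j in seq.int(i + 1, N)) {
      res <- pair_test(binned$counts[, i], binned$counts[, j], l_max,
                       corrected_alpha = budget$corrected_alpha, k = k,
                       reference = reference, dof = dof,
                       floor_correct = floor_correct)
      r <- r + 1L
      rows[[r]] <- data.frame(
        unit_a = binned$unit_ids[i], unit_b = binned$unit_ids[j],
        lag = res$selected_lag, p_value = res$p_value,
        significant = res$significant, gate_passed = res$gate_passed,
        stringsAsFactors = FALSE)
      if (res$significant) {
        Z[i, j] <- Z[j, i] <- TRUE
        nl <- if (res$selected_lag >= 0)
          list(units = c(i, j), lags = c(0L, res$selected_lag))
        else
          list(units = c(j, i), lags = c(0L, -res$selected_lag))
        assemblies[[length(assemblies) + 1L]] <- list(
          units = nl$units, lags = nl$lags, p = res$p_value,
          count = res$joint_count, generation = 1L)
      }
    }
  }
  list(assemblies = assemblies, Z = Z, pair_table = do.call(rbind, rows),
       budget = budget)
}

#' Attempt to extend an assembly by one candidate unit
#'
#' The assembly's activation series is pair-tested against the candidate's
#' count series at all lags; on success a new assembly is returned with
#' the candidate appended at the winning lag and lags re-referenced so the
#' earliest unit carries lag 0.
#'
#' @param binned a `binned_spikes` object.
#' @param assembly an assembly record (fields `units`, `lags`, `p`).
#' @param candidate unit column index (not already a member).
#' @param l_max maximum lag in bins.
#' @param corrected_alpha Bonferroni-corrected level for this test.
#' @param k,reference,dof,floor_correct passed to [pair_test].
#' @return The extended assembly record, or `NULL` if not significant.
#' @export
extend_assembly <- function(binned, assembly, candidate, l_max,
                            corrected_alpha, k = 100L, reference = "mirror",
                            dof = "auto", floor_correct = TRUE) {
  if (candidate %in% assembly$units) stop("candidate is already a member")
  pser <- assembly_series(binned, assembly$units, assembly$lags)
  res <- pair_test(pser, binned$counts[, candidate], l_max,
                   corrected_alpha = corrected_alpha, k = k,
                   reference = reference, dof = dof,
                   floor_correct = floor_correct)
  if (!res$significant) return(NULL)
  nl <- .normalize_assembly(c(assembly$units, candidate),
                            c(assembly$lags, res$selected_lag))
  list(units = nl$units, lags = nl$lags, p = res$p_value,
       count = res$joint_count, generation = assembly$generation + 1L)
}

# keep, per unit-set, only the lag variant with the lowest p-value
.prune_lag_variants <- function(assemblies) {
  if (!length(assemblies)) return(assemblies)
  keys <- vapply(assemblies, function(a) .assembly_key(a$units), "")
  keep <- !logical(length(assemblies))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    if (length(idx) > 1) {
      best <- idx[which.min(vapply(assemblies[idx], `[[`, 0, "p"))]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  assemblies[keep]
}

# drop assemblies whose unit set is a strict subset of another's
.prune_subsets <- function(assemblies) {
  n <- length(assemblies)
  if (n < 2) return(assemblies)
  sets <- lapply(assemblies, function(a) sort(a$units))
  keep <- !logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  assemblies[keep]
}

#' Detect assemblies at one bin width
#'
#' Runs the full agglomerative scheme at a single temporal scale: pair
#' screening, recursive extension of every assembly formed in the previous
#' iteration by eligible candidate units (those significantly paired with
#' at least one member), per-iteration Bonferroni budgets, lag-variant
#' pruning after each iteration, and terminal within-scale subset pruning.
#'
#' The optional hierarchical mode (`method = "hierarchical"`) instead fuses,
#' at each step, only the single lowest-p significant pair among all current
#' assemblies and units, yielding a dendrogram-like strictly nested
#' structure; it can miss overlapping assemblies and is off by default.
#'
#' @inheritParams seed_pairs
#' @param method `"recursive"` (default) or `"hierarchical"`.
#' @param prune_subsets drop within-scale strict unit-subsets (default
#'   TRUE; set FALSE to retain nested structure).
#' @return List with `assemblies`, `Z`, `pair_table`.
#' @export
agglomerate_at_scale <- function(binned, l_max, alpha = 0.05, k = 100L,
                                 reference = "mirror", dof = "auto",
                                 floor_correct = TRUE,
                                 method = c("recursive", "hierarchical"),
                                 prune_subsets = TRUE) {
  method <- match.arg(method)
  seeds <- seed_pairs(binned, l_max, alpha, k = k, reference = reference,
                      dof = dof, floor_correct = floor_correct)
  if (method == "hierarchical")
    return(c(.agglomerate_hier(binned, seeds, l_max, alpha, k, reference,
                               dof, floor_correct),
             list(pair_table = seeds$pair_table)))
  Z <- seeds$Z
  generation <- .prune_lag_variants(seeds$assemblies)
  all_assemblies <- generation
  while (length(generation)) {
    n_a <- length(generation)
    next_gen <- list()
    for (asm in generation) {
      elig <- which(apply(Z[, asm$units, drop = FALSE], 1, any))
      elig <- setdiff(elig, asm$units)
      if (!length(elig)) next
      R_ia <- n_a * length(elig) * (2 * l_max + 1)
      for (s in elig) {
        ext <- extend_assembly(binned, asm, s, l_max,
                               corrected_alpha = alpha / R_ia, k = k,
                               reference = reference, dof = dof,
                               floor_correct = floor_correct)
        if (!is.null(ext)) next_gen[[length(next_gen) + 1L]] <- ext
      }
    }
    generation <- .prune_lag_variants(next_gen)
    all_assemblies <- c(all_assemblies, generation)
  }
  if (prune_subsets) all_assemblies <- .prune_subsets(all_assemblies)
  list(assemblies = all_assemblies, Z = Z, pair_table = seeds$pair_table)
}

# hierarchical variant: fuse only the lowest-p significant assembly/unit
# pair at each step; strictly nested, no overlapping memberships
.agglomerate_hier <- function(binned, seeds, l_max, alpha, k, reference,
                              dof, floor_correct) {
  N <- ncol(binned$counts)
  active <- lapply(seq_len(N), function(i)
    list(units = i, lags = 0L, p = NA_real_, count = NA_real_,
         generation = 0L))
  formed <- list()
  repeat {
    n <- length(active)
    if (n < 2) break
    R <- n * (n - 1) / 2 * (2 * l_max + 1)
    best <- NULL
    best_pair <- NULL
    for (i in seq_len(n - 1)) {
      si <- if (length(active[[i]]$units) == 1)
        binned$counts[, active[[i]]$units]
      else assembly_series(binned, active[[i]]$units, active[[i]]$lags)
      for (j in seq.int(i + 1, n)) {
        sj <- if (length(active[[j]]$units) == 1)
          binned$counts[, active[[j]]$units]
        else assembly_series(binned, active[[j]]$units, active[[j]]$lags)
        res <- pair_test(si, sj, l_max, corrected_alpha = alpha / R, k = k,
                         reference = reference, dof = dof,
                         floor_correct = floor_correct)
        if (res$significant && (is.null(best) || res$p_value < best$p_value)) {
          best <- res
          best_pair <- c(i, j)
        }
      }
    }
    if (is.null(best)) break
    a <- active[[best_pair[1]]]; b <- active[[best_pair[2]]]
    nl <- .normalize_assembly(c(a$units, b$units),
                              c(a$lags, b$lags + best$selected_lag))
    fused <- list(units = nl$units, lags = nl$lags, p = best$p_value,
                  count = best$joint_count,
                  generation = max(a$generation, b$generation) + 1L)
    active <- c(active[-best_pair], list(fused))
    formed[[length(formed) + 1L]] <- fused
  }
  list(assemblies = formed, Z = seeds$Z)
}

#' Detect assemblies across a set of bin widths
#'
#' Runs the full agglomeration scheme at every requested bin width and
#' tags each detected assembly with its characteristic scale `delta_star`,
#' the bin width at which its unit set attains the lowest p-value.
#'
#' @param dataset a [spike_dataset].
#' @param deltas strictly increasing vector of bin widths (seconds).
#' @param l_max maximum lag in bins.
#' @param alpha family-wise significance level for the whole multi-scale
#'   analysis (default 0.05); each scale receives `alpha / length(deltas)`
#'   on top of its own per-scale Bonferroni budget.
#' @param k segment length in bins for the variance estimate.
#' @param reference,dof,floor_correct,method,prune_subsets passed to
#'   [agglomerate_at_scale].
#' @return An `assembly_catalog`: list with `assemblies` (each having
#'   `unit_ids`, `lags` in bins, `delta`, `delta_star`, `p`, `count`),
#'   `deltas`, `unit_ids`, `pair_table` (per-scale pair significance
#'   tallies), and `params`.
#' @export
detect_assemblies <- function(dataset, deltas, l_max = 10L, alpha = 0.05,
                              k = 100L, reference = "mirror", dof = "auto",
                              floor_correct = TRUE, method = "recursive",
                              prune_subsets = TRUE) {
  stopifnot(inherits(dataset, "spike_dataset"), length(deltas) >= 1)
  if (is.unsorted(deltas, strictly = TRUE))
    stop("deltas must be strictly increasing")
  assemblies <- list()
  tables <- list()
  # each temporal scale is its own Bonferroni family; dividing alpha by the
  # number of scales keeps the family-wise guarantee over the whole sweep
  alpha_scale <- alpha / length(deltas)
  for (d in deltas) {
    binned <- bin_dataset(dataset, d)
    res <- agglomerate_at_scale(binned, l_max, alpha_scale, k = k,
                                reference = reference, dof = dof,
                                floor_correct = floor_correct,
                                method = method,
                                prune_subsets = prune_subsets)
    for (a in res$assemblies) {
      a$unit_ids <- binned$unit_ids[a$units]
      a$delta <- d
      assemblies[[length(assemblies) + 1L]] <- a
    }
    if (!is.null(res$pair_table)) {
      res$pair_table$delta <- d
      tables[[length(tables) + 1L]] <- res$pair_table
    }
  }
  # characteristic scale: bin width with the lowest p per unit set
  if (length(assemblies)) {
    keys <- vapply(assemblies, function(a) .assembly_key(a$unit_ids), "")
    for (key in unique(keys)) {
      idx <- which(keys == key)
      best <- idx[which.min(vapply(assemblies[idx], `[[`, 0, "p"))]
      for (i in idx) assemblies[[i]]$delta_star <- assemblies[[best]]$delta
    }
  }
  structure(list(assemblies = assemblies, deltas = deltas,
                 unit_ids = dataset$units,
                 pair_table = if (length(tables)) do.call(rbind, tables) else NULL,
                 params = list(l_max = l_max, alpha = alpha, k = k,
                               reference = reference, dof = dof,
                               floor_correct = floor_correct,
                               method = method)),
            class = "assembly_catalog")
}

#' @export
print.assembly_catalog <- function(x, ...) {
  cat(sprintf("assembly_catalog: %d assemblies across %d bin widths\n",
              length(x$assemblies), length(x$deltas)))
  for (a in x$assemblies)
    cat(sprintf("  delta %g s: {%s} lags (%s), p = %.3g, delta* = %g\n",
                a$delta, paste(a$unit_ids, collapse = ","),
                paste(a$lags, collapse = ","), a$p, a$delta_star))
  invisible(x)
}

#' @export
as.data.frame.assembly_catalog <- function(x, ...) {
  if (!length(x$assemblies))
    return(data.frame(delta = numeric(0), units = character(0),
                      lags = character(0), p_value = numeric(0),
                      count = numeric(0), delta_star = numeric(0)))
  do.call(rbind, lapply(x$assemblies, function(a)
    data.frame(delta = a$delta, units = paste(a$unit_ids, collapse = ";"),
               lags = paste(a$lags, collapse = ";"), p_value = a$p,
               count = a$count, delta_star = a$delta_star,
               stringsAsFactors = FALSE)))
}

#' Prune an assembly catalog across scales
#'
#' Within-scale subset and lag-variant pruning are always applied during
#' detection; this function offers the optional across-scale prunings used
#' for visualization: keep, among assemblies whose unit-membership
#' indicator vectors are closer than `cosine_threshold` in cosine distance,
#' only the lowest-p one (greedy from the lowest p upward); and optionally
#' drop any assembly whose unit set is a strict subset of another assembly
#' at any scale.
#'
#' @param catalog an `assembly_catalog`.
#' @param cosine_threshold cosine-distance threshold in (0, 1], or `NULL`
#'   to skip (a common choice is 0.3).
#' @param across_scale_subsets drop strict unit-subsets across scales.
#' @return The pruned catalog.
#' @export
prune_catalog <- function(catalog, cosine_threshold = NULL,
                          across_scale_subsets = FALSE) {
  stopifnot(inherits(catalog, "assembly_catalog"))
  asms <- catalog$assemblies
  if (!is.null(cosine_threshold)) {
    if (cosine_threshold <= 0 || cosine_threshold > 1)
      stop("cosine_threshold must be in (0, 1]")
    if (length(asms) > 1) {
      ind <- vapply(asms, function(a)
        as.numeric(catalog$unit_ids %in% a$unit_ids),
        numeric(length(catalog$unit_ids)))
      cosdist <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      ord <- order(vapply(asms, `[[`, 0, "p"))
      kept <- integer(0)
      for (i in ord) {
        close <- any(vapply(kept, function(j)
          cosdist(ind[, i], ind[, j]) < cosine_threshold, TRUE))
        if (!close) kept <- c(kept, i)
      }
      asms <- asms[sort(kept)]
    }
  }
  if (across_scale_subsets) {
    tmp <- lapply(asms, function(a) list(units = a$unit_ids, p = a$p))
    keep <- seq_along(asms) %in% which(vapply(seq_along(tmp), function(i) {
      any_super <- any(vapply(seq_along(tmp), function(j)
        i != j && length(tmp[[i]]$units) < length(tmp[[j]]$units) &&
          all(tmp[[i]]$units %in% tmp[[j]]$units), TRUE))
      !any_super
    }, TRUE))
    asms <- asms[keep]
  }
  catalog$assemblies <- asms
  catalog
}

#' Write an assembly catalog to JSON
#'
#' @param catalog an `assembly_catalog`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "assembly_catalog"))
  out <- list(
    deltas = catalog$deltas,
    units = catalog$unit_ids,
    params = catalog$params,
    assemblies = lapply(catalog$assemblies, function(a)
      list(units = a$unit_ids, lags = a$lags, delta = a$delta,
           delta_star = a$delta_star, p_value = a$p, count = a$count)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an assembly catalog from JSON
#'
#' @param path file written by [write_catalog].
#' @return An `assembly_catalog` (without pair tallies).
#' @export
read_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  asms <- lapply(raw$assemblies, function(a)
    list(unit_ids = unlist(a$units), lags = as.integer(unlist(a$lags)),
         delta = a$delta, delta_star = a$delta_star, p = a$p_value,
         count = a$count))
  structure(list(assemblies = asms, deltas = unlist(raw$deltas),
                 unit_ids = unlist(raw$units), pair_table = NULL,
                 params = raw$params),
            class = "assembly_catalog")
}
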