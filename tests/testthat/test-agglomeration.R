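# helper: dataset from per-unit spike time lists
.ds_from_times <- function(times, span) {
  spk <- do.call(rbind, lapply(names(times), function(u)
    if (length(times[[u]]))
      data.frame(unit_id = u, time = times[[u]], stringsAsFactors = FALSE)))
  spike_dataset(spk, span = span, units = names(times))
}

# helper: dataset whose bins at delta = 1 s hold the given 0/1 series
.ds_from_binary <- function(mat, unit_ids = colnames(mat)) {
  times <- lapply(seq_len(ncol(mat)), function(j) which(mat[, j] > 0) - 0.5)
  names(times) <- unit_ids
  .ds_from_times(times, span = c(0, nrow(mat)))
}

test_that("the pair-screening budget follows the Bonferroni formula", {
  b <- test_budget(3, 10)
  expect_equal(b$R1, 63)
  expect_equal(b$corrected_alpha, 0.05 / 63)
  expect_equal(test_budget(50, 10)$R1, 50 * 49 * 21 / 2)
})

test_that("an embedded lag-2 pair seeds one elementary assembly", {
  set.seed(41)
  ta <- sort(runif(900, 0, 200))
  times <- list(
    a = ta,
    b = ta + 0.032,                 # ~2 bins at delta = 15 ms
    c = sort(runif(900, 0, 201)),   # independent
    d = sort(runif(900, 0, 201)))
  ds <- .ds_from_times(times, span = c(0, 201))
  binned <- bin_dataset(ds, 0.015)
  res <- seed_pairs(binned, l_max = 10)
  sig <- Filter(function(a) TRUE, res$assemblies)
  expect_equal(length(sig), 1L)
  expect_equal(binned$unit_ids[sig[[1]]$units], c("a", "b"))
  expect_equal(sig[[1]]$lags, c(0L, 2L))
  expect_true(res$Z["a", "b"])
  expect_false(any(res$Z[c("c", "d"), ]))
})

test_that("agglomeration recovers a 3-unit chain and leaves independents alone", {
  set.seed(42)
  ta <- sort(runif(800, 0, 200))
  times <- list(
    a = ta, b = ta + 0.030, c = ta + 0.062,     # chain a -> b -> c
    x = sort(runif(800, 0, 200.2)),
    y = sort(runif(800, 0, 200.2)))
  ds <- .ds_from_times(times, span = c(0, 200.2))
  cat1 <- detect_assemblies(ds, deltas = 0.015, l_max = 10)
  expect_equal(length(cat1$assemblies), 1L)
  asm <- cat1$assemblies[[1]]
  expect_equal(asm$unit_ids, c("a", "b", "c"))
  expect_equal(asm$lags[1], 0L)
  expect_true(all(diff(asm$lags) > 0))  # ordered chain
  # determinism: identical input and config give identical catalogs
  cat2 <- detect_assemblies(ds, deltas = 0.015, l_max = 10)
  expect_identical(as.data.frame(cat1), as.data.frame(cat2))
})

test_that("two disjoint embedded assemblies are both recovered without cross-merging", {
  set.seed(43)
  t1 <- sort(runif(700, 0, 180))
  t2 <- sort(runif(700, 0, 180))
  times <- list(
    a = t1, b = t1, c = t1,          # synchronous triplet 1
    p = t2, q = t2 + 0.015,          # lagged pair 2
    u = sort(runif(700, 0, 180.1)),
    v = sort(runif(700, 0, 180.1)))
  ds <- .ds_from_times(times, span = c(0, 180.1))
  catl <- detect_assemblies(ds, deltas = 0.015, l_max = 10)
  sets <- lapply(catl$assemblies, function(a) sort(a$unit_ids))
  expect_true(any(vapply(sets, identical, TRUE, c("a", "b", "c"))))
  expect_true(any(vapply(sets, identical, TRUE, c("p", "q"))))
  expect_equal(length(catl$assemblies), 2L)
})

test_that("fully independent units yield an empty catalog in almost all runs", {
  set.seed(44)
  hits <- 0L
  for (rep in 1:15) {
    times <- lapply(1:8, function(i) sort(runif(500, 0, 100)))
    names(times) <- sprintf("u%02d", 1:8)
    ds <- .ds_from_times(times, span = c(0, 100))
    catl <- detect_assemblies(ds, deltas = c(0.05), l_max = 10)
    if (length(catl$assemblies)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("extension tests the joint activation series, not pairwise aggregates", {
  # A and B are coupled; C is pairwise independent of each of A and B but
  # fires preferentially when A and B coincide. The corrected test on the
  # (A,B) activation series versus C must detect this triplet structure,
  # while the direct A-C and B-C pair tests must not.
  set.seed(45)
  T <- 4000
  A <- rbinom(T, 1, 0.15)
  B <- ifelse(A == 1, rbinom(T, 1, 0.5), rbinom(T, 1, 0.075 / 0.85))
  pc <- ifelse(A & B, 0.9, ifelse(A & !B, 0.1, ifelse(!A & B, 0.1, 0.53871)))
  C <- rbinom(T, 1, pc)
  ds <- .ds_from_binary(cbind(A = A, B = B, C = C))
  binned <- bin_dataset(ds, 1)
  aC <- pair_test(binned$counts[, "A"], binned$counts[, "C"], 10,
                  corrected_alpha = 0.05 / 63)
  bC <- pair_test(binned$counts[, "B"], binned$counts[, "C"], 10,
                  corrected_alpha = 0.05 / 63)
  expect_false(aC$significant)
  expect_false(bC$significant)
  seeds <- seed_pairs(binned, l_max = 10)
  expect_equal(length(seeds$assemblies), 1L)
  ab <- seeds$assemblies[[1]]
  expect_setequal(binned$unit_ids[ab$units], c("A", "B"))
  ext <- extend_assembly(binned, ab, candidate = 3L, l_max = 10,
                         corrected_alpha = 0.05 / 63)
  expect_false(is.null(ext))
  expect_setequal(binned$unit_ids[ext$units], c("A", "B", "C"))
  # under the single-unit screening restriction C is not eligible, so the
  # full recursion keeps only the pair
  full <- agglomerate_at_scale(binned, l_max = 10)
  expect_equal(length(full$assemblies), 1L)
  expect_setequal(binned$unit_ids[full$assemblies[[1]]$units], c("A", "B"))
})

.mk_catalog <- function(asms, units) {
  structure(list(assemblies = asms, deltas = unique(vapply(asms, `[[`, 0, "delta")),
                 unit_ids = units, pair_table = NULL, params = list()),
            class = "assembly_catalog")
}

test_that("catalog pruning keeps minimal-p variants and drops subsets/near-duplicates", {
  # same unit set, different lag vectors: lowest p survives
  lv <- spikeassembly:::.prune_lag_variants(list(
    list(units = c(1, 2), lags = c(0L, 1L), p = 0.001),
    list(units = c(1, 2), lags = c(0L, 2L), p = 0.01)))
  expect_equal(length(lv), 1L)
  expect_equal(lv[[1]]$lags, c(0L, 1L))

  # strict unit-subset removed within a scale
  ss <- spikeassembly:::.prune_subsets(list(
    list(units = c(1, 2, 3), lags = c(0L, 1L, 2L), p = 1e-5),
    list(units = c(1, 2), lags = c(0L, 1L), p = 1e-4)))
  expect_equal(length(ss), 1L)
  expect_equal(ss[[1]]$units, c(1, 2, 3))

  # optional across-scale cosine pruning keeps the lowest-p duplicate
  units <- sprintf("u%02d", 1:6)
  catl <- .mk_catalog(list(
    list(unit_ids = units[1:3], lags = c(0L, 0L, 0L), delta = 0.1,
         delta_star = 0.1, p = 1e-8, count = 50),
    list(unit_ids = units[1:3], lags = c(0L, 1L, 1L), delta = 0.15,
         delta_star = 0.1, p = 1e-4, count = 40),
    list(unit_ids = units[4:6], lags = c(0L, 0L, 0L), delta = 0.1,
         delta_star = 0.1, p = 1e-6, count = 30)), units)
  pruned <- prune_catalog(catl, cosine_threshold = 0.3)
  expect_equal(length(pruned$assemblies), 2L)
  expect_equal(min(vapply(pruned$assemblies, `[[`, 0, "p")), 1e-8)
  expect_error(prune_catalog(catl, cosine_threshold = 1.5), "cosine")

  # across-scale subset pruning
  catl2 <- .mk_catalog(list(
    list(unit_ids = units[1:3], lags = c(0L, 0L, 0L), delta = 0.1,
         delta_star = 0.1, p = 1e-8, count = 50),
    list(unit_ids = units[1:2], lags = c(0L, 0L), delta = 1,
         delta_star = 0.1, p = 1e-9, count = 60)), units)
  pr2 <- prune_catalog(catl2, across_scale_subsets = TRUE)
  expect_equal(length(pr2$assemblies), 1L)
  expect_equal(length(pr2$assemblies[[1]]$unit_ids), 3L)
})

test_that("catalogs round-trip through JSON", {
  set.seed(46)
  ta <- sort(runif(500, 0, 150))
  ds <- .ds_from_times(list(a = ta, b = ta + 0.02,
                            c = sort(runif(500, 0, 150.1))),
                       span = c(0, 150.1))
  catl <- detect_assemblies(ds, deltas = c(0.015, 0.05), l_max = 5)
  path <- tempfile(fileext = ".json")
  write_catalog(catl, path)
  back <- read_catalog(path)
  expect_equal(length(back$assemblies), length(catl$assemblies))
  for (i in seq_along(back$assemblies)) {
    expect_equal(back$assemblies[[i]]$unit_ids, catl$assemblies[[i]]$unit_ids)
    expect_equal(back$assemblies[[i]]$lags, catl$assemblies[[i]]$lags)
    expect_equal(back$assemblies[[i]]$p, catl$assemblies[[i]]$p)
  }
})
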