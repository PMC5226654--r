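#' Configuration for the inhomogeneous-Poisson background
#'
#' Background units spike as inhomogeneous Poisson processes whose
#' instantaneous rates follow a stable first-order autoregressive latent
#' process pushed through an error-function sigmoid,
#' `lambda_t = (1 + erf(gain * s_t / noise_sd)) * mean_rate`, with
#' `s_{t+1} = ar_coef * s_t + eps_t`, `eps_t ~ N(0, noise_sd^2)`. Rates are
#' therefore bounded in `(0, 2 * mean_rate)`. Inter-spike intervals are
#' drawn from an exponential at the current rate with a constant
#' refractory delay added. Setting `noise_sd = 0` yields stationary
#' Poisson units at `mean_rate`.
#'
#' @param n_units number of units (default 50).
#' @param duration recording length in seconds (default 1400).
#' @param mean_rate mean firing rate in Hz (default 5).
#' @param refractory refractory delay in seconds (default 0.015).
#' @param ar_coef AR(1) coefficient, `|ar_coef| < 1` (default 0.9).
#' @param noise_sd AR innovation s.d. (default 0.01).
#' @param gain sigmoid gain (default 0.2).
#' @param ar_dt time step of the latent rate process in seconds (default
#'   0.1, so with `ar_coef = 0.9` the rate autocorrelation time is about
#'   1 s -- slow relative to typical inter-spike intervals, the regime the
#'   corrected statistic is built for).
#' @return A `background_config` list.
#' @export
background_config <- function(n_units = 50, duration = 1400, mean_rate = 5,
                              refractory = 0.015, ar_coef = 0.9,
                              noise_sd = 0.01, gain = 0.2, ar_dt = 0.1) {
  if (abs(ar_coef) >= 1) stop("unstable AR process: |ar_coef| must be < 1")
  structure(list(n_units = n_units, duration = duration,
                 mean_rate = mean_rate, refractory = refractory,
                 ar_coef = ar_coef, noise_sd = noise_sd, gain = gain,
                 ar_dt = ar_dt),
            class = "background_config")
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

.unit_labels <- function(n) sprintf("u%02d", seq_len(n))

# One unit's spikes: exact inhomogeneous Poisson over the piecewise-
# constant rate grid (time-rescaling inversion), then a refractory dead
# time after every accepted spike. For a constant rate this is exactly
# the renewal process with inter-spike intervals Exp(rate) + refractory
# (memorylessness), and for slowly varying rates the same to excellent
# approximation.
.sim_unit_spikes <- function(rates, dt, duration, refractory) {
  cum <- c(0, cumsum(rates * dt))
  grid <- seq(0, by = dt, length.out = length(cum))
  total <- cum[length(cum)]
  n <- stats::rpois(1, total)
  if (n == 0) return(numeric(0))
  u <- sort(stats::runif(n, 0, total))
  tt <- stats::approx(cum, grid, xout = u, ties = "ordered")$y
  tt <- .cpp_dead_time_filter(tt, refractory)
  tt[tt <= duration]
}

#' Generate background spike trains
#'
#' @param config a [background_config].
#' @return List with `dataset` (a [spike_dataset] whose spikes carry
#'   `source = "background"`) and `rates` (latent rate matrix, time steps
#'   by units).
#' @export
generate_background <- function(config = background_config()) {
  stopifnot(inherits(config, "background_config"))
  nsteps <- ceiling(config$duration / config$ar_dt)
  N <- config$n_units
  if (config$noise_sd > 0) {
    s <- matrix(0, nsteps, N)
    eps <- matrix(stats::rnorm(nsteps * N, 0, config$noise_sd), nsteps, N)
    prev <- eps[1, ]
    s[1, ] <- prev
    for (t in seq_len(nsteps - 1)) {
      prev <- config$ar_coef * prev + eps[t + 1, ]
      s[t + 1, ] <- prev
    }
    rates <- (1 + .erf(config$gain * s / config$noise_sd)) * config$mean_rate
  } else {
    rates <- matrix(config$mean_rate, nsteps, N)
  }
  units <- .unit_labels(N)
  spk <- lapply(seq_len(N), function(i) {
    tt <- .sim_unit_spikes(rates[, i], config$ar_dt, config$duration,
                           config$refractory)
    if (length(tt))
      data.frame(unit_id = units[i], time = tt, source = "background",
                 stringsAsFactors = FALSE)
  })
  spk <- do.call(rbind, spk)
  ds <- spike_dataset(spk, span = c(0, config$duration), units = units)
  list(dataset = ds, rates = rates)
}

#' Specification of an embedded assembly
#'
#' The five archetypes span the spectrum from precise synchrony to slow
#' co-modulation:
#' * **I** exact spike synchrony across members at each occurrence;
#' * **II** a precise sequence: inter-member lags drawn once uniformly
#'   from `[0, 0.1]` s, then frozen for every occurrence;
#' * **III** a precise but non-sequential template: per member a frozen
#'   set of spikes drawn once at Poisson 10 Hz over 0.2 s (redrawn until
#'   every member contributes at least one spike);
#' * **IV** sequential 0.3-s windows of extra spikes at Poisson 10 Hz,
#'   window lags drawn once uniformly from `[0, 0.4]` s and frozen, spike
#'   times redrawn inside the windows at every occurrence;
#' * **V** a simultaneous rate step from 5 to 10 Hz for 1 s (extra
#'   Poisson 5 Hz spikes on top of the 5 Hz background).
#'
#' @param type one of `"I".."V"`.
#' @param members character vector of member unit ids (default 5 units).
#' @param n_occurrences number of pattern occurrences to embed.
#' @return An `assembly_spec` list.
#' @export
assembly_spec <- function(type = c("I", "II", "III", "IV", "V"),
                          members, n_occurrences) {
  type <- match.arg(type)
  stopifnot(length(members) >= 2, n_occurrences >= 1)
  structure(list(type = type, members = as.character(members),
                 n_occurrences = as.integer(n_occurrences)),
            class = "assembly_spec")
}

# frozen pattern template for one spec: list of per-member spike offsets
# (types I-III), or window starts (type IV), or NULL (type V)
.draw_template <- function(spec) {
  n <- length(spec$members)
  switch(spec$type,
         I = lapply(seq_len(n), function(j) 0),
         II = {
           off <- cumsum(c(0, stats::runif(n - 1, 0, 0.1)))
           lapply(seq_len(n), function(j) off[j])
         },
         III = {
           lapply(seq_len(n), function(j) {
             repeat {
               k <- stats::rpois(1, 10 * 0.2)
               if (k >= 1) return(sort(stats::runif(k, 0, 0.2)))
             }
           })
         },
         IV = {
           w <- cumsum(c(0, stats::runif(n - 1, 0, 0.4)))
           lapply(seq_len(n), function(j) w[j])  # window starts
         },
         V = NULL)
}

.template_extent <- function(spec, template) {
  switch(spec$type,
         I = 0,
         II = max(unlist(template)),
         III = 0.2,
         IV = max(unlist(template)) + 0.3,
         V = 1)
}

#' Embed an assembly pattern into a spike dataset
#'
#' Activation anchors are placed uniformly at random over the recording
#' (occurrences may overlap). Assembly spikes are inserted with provenance
#' `source = <assembly id>`; background spikes of the same unit within
#' +/- 15 ms of each inserted spike are erased to preserve the refractory
#' period.
#'
#' @param dataset a [spike_dataset] (spikes need a `source` column; one is
#'   added with value `"background"` if missing).
#' @param spec an [assembly_spec].
#' @param id assembly identifier recorded in provenance (default `"A1"`).
#' @return List with `dataset` (spikes inserted/erased) and `truth`, a
#'   per-assembly ground-truth record: `id`, `type`, `members`,
#'   `lag_offsets` (seconds, per member; pattern template), `activations`
#'   (anchor instants), `n_inserted`.
#' @export
embed_assembly <- function(dataset, spec, id = "A1") {
  stopifnot(inherits(dataset, "spike_dataset"), inherits(spec, "assembly_spec"))
  if (!all(spec$members %in% dataset$units))
    stop("assembly members missing from dataset")
  spikes <- dataset$spikes
  if (is.null(spikes$source)) spikes$source <- "background"
  template <- .draw_template(spec)
  extent <- .template_extent(spec, template)
  dur <- diff(dataset$span)
  if (extent >= dur) stop("pattern extent exceeds the recording span")
  anchors <- sort(stats::runif(spec$n_occurrences, dataset$span[1],
                               dataset$span[2] - extent))
  n <- length(spec$members)
  new_rows <- vector("list", spec$n_occurrences)
  for (o in seq_along(anchors)) {
    t0 <- anchors[o]
    member_times <- switch(spec$type,
      I = ,
      II = ,
      III = lapply(seq_len(n), function(j) t0 + template[[j]]),
      IV = lapply(seq_len(n), function(j) {
        k <- stats::rpois(1, 10 * 0.3)
        if (k == 0) numeric(0)
        else t0 + template[[j]] + sort(stats::runif(k, 0, 0.3))
      }),
      V = lapply(seq_len(n), function(j) {
        k <- stats::rpois(1, 5 * 1)
        if (k == 0) numeric(0) else t0 + sort(stats::runif(k, 0, 1))
      }))
    new_rows[[o]] <- data.frame(
      unit_id = rep(spec$members, lengths(member_times)),
      time = unlist(member_times), source = id, stringsAsFactors = FALSE)
  }
  new_spk <- do.call(rbind, new_rows)
  # erase background spikes within +/- 15 ms of an inserted assembly spike
  for (u in spec$members) {
    at <- sort(new_spk$time[new_spk$unit_id == u])
    if (!length(at)) next
    sel <- which(spikes$unit_id == u & spikes$source == "background")
    if (!length(sel)) next
    bt <- spikes$time[sel]
    pos <- findInterval(bt, at)
    d_lo <- ifelse(pos >= 1, bt - at[pmax(pos, 1)], Inf)
    d_hi <- ifelse(pos < length(at), at[pmin(pos + 1, length(at))] - bt, Inf)
    erase <- sel[pmin(d_lo, d_hi) <= 0.015]
    if (length(erase)) spikes <- spikes[-erase, , drop = FALSE]
  }
  spikes <- rbind(spikes, new_spk)
  truth <- list(id = id, type = spec$type, members = spec$members,
                lag_offsets = template, activations = anchors,
                n_inserted = nrow(new_spk))
  list(dataset = spike_dataset(spikes, span = dataset$span,
                               units = dataset$units),
       truth = truth)
}

#' Simulate spike sorting errors
#'
#' Reassigns a given fraction of all spikes to a uniformly chosen other
#' unit, keeping spike times and the total spike count unchanged.
#' Reassigned spikes have `".sorterr"` appended to their provenance.
#'
#' @param dataset a [spike_dataset].
#' @param fraction fraction of spikes to reassign, in `[0, 1]`.
#' @return The corrupted [spike_dataset].
#' @export
corrupt_sorting <- function(dataset, fraction) {
  stopifnot(inherits(dataset, "spike_dataset"),
            fraction >= 0, fraction <= 1)
  if (fraction == 0 || nrow(dataset$spikes) == 0) return(dataset)
  spikes <- dataset$spikes
  n <- nrow(spikes)
  n_move <- round(fraction * n)
  idx <- sample.int(n, n_move)
  units <- dataset$units
  cur <- match(spikes$unit_id[idx], units)
  shift <- sample.int(length(units) - 1L, n_move, replace = TRUE)
  spikes$unit_id[idx] <- units[1L + (cur - 1L + shift) %% length(units)]
  if (!is.null(spikes$source))
    spikes$source[idx] <- paste0(spikes$source[idx], ".sorterr")
  spike_dataset(spikes, span = dataset$span, units = units)
}

#' Generate a named simulation scenario
#'
#' * `"figure1"`: 50 units over `duration` seconds (default 1400) with
#'   five disjoint 5-member assemblies, one of each archetype I-V (units
#'   u01-u05 = I, ..., u21-u25 = V), embedded in AR-modulated 5-Hz
#'   inhomogeneous-Poisson background. Default occurrence count is
#'   `round(0.25 * duration)` per assembly.
#' * `"step_rate"`: a two-unit Bernoulli pair at elementary-bin resolution
#'   (times are in elementary-bin units; bin detection with `delta` in the
#'   same units). Low-rate states interspersed with `m` high-rate states
#'   of `L` elementary bins; `variant = "fast"` gives `m = 25, L = 3000`,
#'   `"slow"` gives `m = 1, L = 75000` (at the default 1e6 elementary
#'   bins). `coupled = TRUE` synchronizes the high states of both units.
#' * `"oscillation"`: two units driven by a common 4-Hz oscillatory rate,
#'   `lambda_{A,B}(t) = 5 (0.6 sin(2 pi 4 t) + a_{A,B})` with
#'   `a_A = 1, a_B = 0.5` (negative instantaneous rates clipped to 0),
#'   over `duration` seconds (default 1500); with `patterns = TRUE`, 90
#'   A-then-B spike pairs 20 ms apart are inserted 20 ms after randomly
#'   chosen oscillation peaks.
#'
#' @param name scenario name.
#' @param seed optional integer seed (applied via [set.seed]).
#' @param duration recording length in seconds (figure1, oscillation).
#' @param n_occurrences per-assembly occurrence count (figure1).
#' @param types assembly types to embed (figure1; default all five).
#' @param n_elementary,m,L,pi_a,pi_b,coupled,variant step-rate parameters.
#' @param patterns,n_patterns oscillation pattern embedding.
#' @return List with `dataset` (a [spike_dataset]) and `truth` (a
#'   `ground_truth` record: list of per-assembly records plus scenario
#'   metadata).
#' @export
generate_scenario <- function(name = c("figure1", "step_rate", "oscillation"),
                              seed = NULL, duration = NULL,
                              n_occurrences = NULL,
                              types = c("I", "II", "III", "IV", "V"),
                              n_elementary = 1e6, m = NULL, L = NULL,
                              pi_a = c(0.01, 0.05), pi_b = c(0.03, 0.15),
                              coupled = FALSE,
                              variant = c("fast", "slow"),
                              patterns = FALSE, n_patterns = 90) {
  name <- match.arg(name)
  if (!is.null(seed)) set.seed(seed)
  switch(name,
    figure1 = {
      if (is.null(duration)) duration <- 1400
      if (is.null(n_occurrences)) n_occurrences <- round(0.25 * duration)
      bg <- generate_background(background_config(n_units = 50,
                                                  duration = duration))
      ds <- bg$dataset
      truths <- list()
      all_types <- c("I", "II", "III", "IV", "V")
      for (ti in seq_along(all_types)) {
        if (!all_types[ti] %in% types) next
        members <- .unit_labels(50)[(5 * (ti - 1) + 1):(5 * ti)]
        spec <- assembly_spec(all_types[ti], members, n_occurrences)
        emb <- embed_assembly(ds, spec, id = paste0("A", ti))
        ds <- emb$dataset
        truths[[length(truths) + 1L]] <- emb$truth
      }
      truth <- structure(list(assemblies = truths, scenario = "figure1",
                              duration = duration,
                              n_occurrences = n_occurrences),
                         class = "ground_truth")
      list(dataset = ds, truth = truth)
    },
    step_rate = {
      variant <- match.arg(variant)
      scale <- n_elementary / 1e6
      if (is.null(m)) m <- if (variant == "fast") 25L else 1L
      if (is.null(L)) L <- round((if (variant == "fast") 3000 else 75000) * scale)
      if (m * L > n_elementary) stop("high states do not fit")
      place_states <- function() {
        starts <- integer(0)
        while (length(starts) < m) {
          cand <- sample.int(n_elementary - L + 1L, 1)
          if (!any(abs(cand - starts) < L)) starts <- c(starts, cand)
        }
        sort(starts)
      }
      st_a <- place_states()
      st_b <- if (coupled) st_a else place_states()
      draw_unit <- function(starts, pi_lo, pi_hi) {
        p <- rep(pi_lo, n_elementary)
        for (s in starts) p[s:(s + L - 1L)] <- pi_hi
        which(stats::runif(n_elementary) < p)
      }
      bins_a <- draw_unit(st_a, pi_a[1], pi_a[2])
      bins_b <- draw_unit(st_b, pi_b[1], pi_b[2])
      spk <- data.frame(
        unit_id = c(rep("A", length(bins_a)), rep("B", length(bins_b))),
        time = c(bins_a, bins_b) - 0.5, source = "background",
        stringsAsFactors = FALSE)
      truth <- structure(list(assemblies = list(), scenario = "step_rate",
                              high_states_a = st_a, high_states_b = st_b,
                              m = m, L = L, coupled = coupled,
                              n_elementary = n_elementary),
                         class = "ground_truth")
      list(dataset = spike_dataset(spk, span = c(0, n_elementary),
                                   units = c("A", "B")),
           truth = truth)
    },
    oscillation = {
      if (is.null(duration)) duration <- 1500
      amp <- c(A = 1, B = 0.5)
      theta <- 4
      sim_osc <- function(a) {
        lmax <- 5 * (0.6 + a)
        n <- stats::rpois(1, lmax * duration)
        tt <- sort(stats::runif(n, 0, duration))
        lam <- pmax(0, 5 * (0.6 * sin(2 * pi * theta * tt) + a))
        tt[stats::runif(n) < lam / lmax]
      }
      ta <- sim_osc(amp["A"])
      tb <- sim_osc(amp["B"])
      inst <- numeric(0)
      if (patterns) {
        peaks <- (seq_len(floor(duration * theta)) - 1 + 0.25) / theta
        peaks <- peaks[peaks + 0.06 < duration]
        inst <- sort(sample(peaks, n_patterns)) + 0.020
        ta <- c(ta, inst)
        tb <- c(tb, inst + 0.020)
      }
      spk <- data.frame(
        unit_id = c(rep("A", length(ta)), rep("B", length(tb))),
        time = c(ta, tb),
        source = c(rep("background", length(ta) - length(inst)),
                   rep("pattern", length(inst)),
                   rep("background", length(tb) - length(inst)),
                   rep("pattern", length(inst))),
        stringsAsFactors = FALSE)
      truth <- structure(list(
        assemblies = if (patterns)
          list(list(id = "P1", type = "lagged", members = c("A", "B"),
                    lag_offsets = list(0, 0.020), activations = inst,
                    n_inserted = 2 * length(inst)))
        else list(),
        scenario = "oscillation", duration = duration),
        class = "ground_truth")
      list(dataset = spike_dataset(spk, span = c(0, duration),
                                   units = c("A", "B")),
           truth = truth)
    })
}

#' Membership partition of a ground-truth record
#'
#' @param truth a `ground_truth` object.
#' @return Named list of member-id vectors, one per embedded assembly.
#' @export
truth_partition <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- lapply(truth$assemblies, `[[`, "members")
  names(out) <- vapply(truth$assemblies, `[[`, "", "id")
  out
}

#' Fraction of spikes contributed by embedded assembly patterns
#'
#' @param dataset a [spike_dataset] with per-spike provenance.
#' @return Fraction in `[0, 1]`.
#' @export
assembly_spike_fraction <- function(dataset) {
  src <- dataset$spikes$source
  if (is.null(src)) stop("dataset carries no provenance")
  mean(!grepl("^background", src))
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param truth a `ground_truth` object.
#' @param path file path.
#' @return The path (write) or the `ground_truth` (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$assemblies <- lapply(raw$assemblies, function(a) {
    a$members <- unlist(a$members)
    a$activations <- as.numeric(unlist(a$activations))
    a
  })
  structure(raw, class = "ground_truth")
}

#' Write a spike dataset as a two-column CSV
#'
#' @param dataset a [spike_dataset].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_spike_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  utils::write.csv(dataset$spikes[, c("unit_id", "time")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
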