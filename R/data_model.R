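#' Multi-area spike dataset
#'
#' Container for spike times recorded simultaneously from several brain areas
#' across repeated trials of multiple stimulus conditions, aligned to stimulus
#' onset over a fixed analysis window `[0, T]`.
#'
#' @param table data frame with columns `neuron_id`, `area`, `condition_id`,
#'   `trial_id`, `time_ms`. Neuron ids must be unique across areas. A neuron
#'   with no spikes in some (condition, trial) is simply absent from those
#'   rows. Trial ids index the same physical trial across areas.
#' @param T window length in ms (spikes outside `[0, T]` are rejected).
#' @param neuron_area optional named vector mapping neuron id -> area for
#'   neurons that never spike (otherwise the map is inferred from the table).
#' @return object of class `spike_dataset` with elements `areas`,
#'   `conditions`, `trials` (trial ids per condition), `neurons` (per-area
#'   id vectors), `neuron_area`, `T`, and a nested spike store
#'   `spikes[[area]][[condition]][[trial]] = list(times, neuron)` where
#'   `neuron` holds 1-based indices into `neurons[[area]]`.
#' @export
spike_dataset <- function(table, T = 500, neuron_area = NULL) {
  need <- c("neuron_id", "area", "condition_id", "trial_id", "time_ms")
  if (!all(need %in% names(table))) stop("table must have columns ", paste(need, collapse = ", "))
  if (nrow(table) && (min(table$time_ms) < 0 || max(table$time_ms) > T))
    stop("spike times must lie in [0, T]")
  na_map <- tapply(as.character(table$area), as.character(table$neuron_id),
                   function(a) {
                     u <- unique(a)
                     if (length(u) > 1) stop("a neuron id appears in more than one area")
                     u
                   })
  na_map <- unlist(na_map)
  if (!is.null(neuron_area)) {
    extra <- setdiff(names(neuron_area), names(na_map))
    na_map <- c(na_map, neuron_area[extra])
  }
  areas <- as.character(sort(unique(as.vector(na_map))))
  conditions <- sort(unique(table$condition_id))
  trials <- sort(unique(table$trial_id))
  neurons <- lapply(areas, function(a) sort(names(na_map)[na_map == a]))
  names(neurons) <- areas
  spikes <- lapply(areas, function(a) {
    sub_a <- table[as.character(table$area) == a, , drop = FALSE]
    out_c <- lapply(conditions, function(cc) {
      sub_c <- sub_a[sub_a$condition_id == cc, , drop = FALSE]
      out_r <- lapply(trials, function(rr) {
        sub <- sub_c[sub_c$trial_id == rr, , drop = FALSE]
        o <- order(sub$time_ms)
        list(times = as.numeric(sub$time_ms[o]),
             neuron = match(as.character(sub$neuron_id[o]), neurons[[a]]))
      })
      names(out_r) <- as.character(trials)
      out_r
    })
    names(out_c) <- as.character(conditions)
    out_c
  })
  names(spikes) <- areas
  structure(list(areas = areas, conditions = conditions, trials = trials,
                 neurons = neurons, neuron_area = na_map, T = T,
                 spikes = spikes),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("spike_dataset:", length(x$areas), "areas,",
      length(x$conditions), "conditions,", length(x$trials),
      "trials/condition, window [0,", x$T, "] ms\n")
  for (a in x$areas)
    cat("  ", a, ": ", length(x$neurons[[a]]), " neurons\n", sep = "")
  invisible(x)
}

#' Bin spike times
#'
#' Counts spikes in half-open bins `[k*dt, (k+1)*dt)` over `[0, T]`; a spike
#' at exactly `T` is dropped.
#'
#' @param times spike times in ms.
#' @param T window length; `bin_width` must divide it.
#' @param bin_width bin width in ms.
#' @return object of class `binned_train`: list with integer `counts`,
#'   `bin_width`, `n_bins`.
#' @export
bin_spikes <- function(times, T = 500, bin_width = 2) {
  n_bins <- T / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8) stop("bin_width must divide T")
  if (length(times) && (min(times) < 0 || max(times) > T))
    stop("spike times must lie in [0, T]")
  counts <- bin_counts_cpp(as.numeric(times), as.integer(round(n_bins)), bin_width)
  structure(list(counts = counts, bin_width = bin_width,
                 n_bins = as.integer(round(n_bins))),
            class = "binned_train")
}

# internal: spikes of a member subset in one (area, condition, trial)
.member_spikes <- function(dataset, area, member_idx, condition, trial) {
  tr <- dataset$spikes[[area]][[as.character(condition)]][[as.character(trial)]]
  keep <- tr$neuron %in% member_idx
  list(times = tr$times[keep], neuron = tr$neuron[keep])
}

# internal: resolve member ids to (area, local indices)
.resolve_members <- function(dataset, member_ids) {
  member_ids <- as.character(member_ids)
  if (length(member_ids) == 0L) stop("degenerate population: empty member set")
  ar <- unique(dataset$neuron_area[member_ids])
  if (anyNA(ar)) stop("unknown neuron id in member set")
  if (length(ar) != 1L) stop("member neurons must all belong to one area")
  list(area = ar, idx = match(member_ids, dataset$neurons[[ar]]))
}

#' Merged population spike train for one trial
#'
#' Merges the spike times of the member neurons and bins them; equal to the
#' elementwise sum of the members' binned trains.
#'
#' @param dataset a [spike_dataset()].
#' @param member_ids nonempty set of neuron ids, all in one area.
#' @param condition,trial condition and trial ids.
#' @param bin_width bin width in ms.
#' @return a `binned_train`.
#' @export
population_train <- function(dataset, member_ids, condition, trial, bin_width = 2) {
  m <- .resolve_members(dataset, member_ids)
  sp <- .member_spikes(dataset, m$area, m$idx, condition, trial)
  bin_spikes(sp$times, dataset$T, bin_width)
}

#' Trial-averaged population rate (PSTH)
#'
#' @param dataset a [spike_dataset()].
#' @param member_ids nonempty set of neuron ids in one area.
#' @param condition condition id.
#' @param bin_width bin width in ms.
#' @return numeric vector of rates per bin in spikes/s per neuron: the mean
#'   over trials of `counts / (n_members * dt)` with `dt` in seconds.
#' @export
psth <- function(dataset, member_ids, condition, bin_width = 2) {
  m <- .resolve_members(dataset, member_ids)
  dt_s <- bin_width / 1000
  acc <- 0
  for (rr in dataset$trials) {
    sp <- .member_spikes(dataset, m$area, m$idx, condition, rr)
    acc <- acc + as.numeric(bin_spikes(sp$times, dataset$T, bin_width)$counts)
  }
  acc / (length(dataset$trials) * length(m$idx) * dt_s)
}

# internal: total in-window spike count per neuron in an area, merged over
# conditions and trials
.neuron_totals <- function(dataset, area) {
  n <- length(dataset$neurons[[area]])
  tot <- numeric(n)
  for (cc in as.character(dataset$conditions))
    for (rr in as.character(dataset$trials)) {
      tr <- dataset$spikes[[area]][[cc]][[rr]]
      if (length(tr$neuron))
        tot <- tot + tabulate(tr$neuron, n)
    }
  names(tot) <- dataset$neurons[[area]]
  tot
}

#' Select the most active neurons
#'
#' Ranks neurons within each area by total spike count over the analysis
#' window (merged across conditions and trials) and keeps the top fraction.
#' Ties are broken in favour of the smaller neuron id.
#'
#' @param dataset a [spike_dataset()].
#' @param fraction fraction of neurons to keep per area (ceiling).
#' @param areas areas to consider (default all).
#' @return character vector of selected neuron ids.
#' @export
select_active_neurons <- function(dataset, fraction = 0.5, areas = dataset$areas) {
  unlist(lapply(areas, function(a) {
    tot <- .neuron_totals(dataset, a)
    k <- ceiling(fraction * length(tot))
    ids <- names(tot)
    ord <- order(-tot, ids)
    ids[ord][seq_len(k)]
  }), use.names = FALSE)
}

#' Gaussian-smooth a binned curve
#'
#' Discrete convolution with a Gaussian kernel truncated at +/- 4 standard
#' deviations and renormalized at the edges (so a constant curve stays
#' constant).
#'
#' @param v numeric vector on the bin grid.
#' @param sd_ms kernel standard deviation in ms.
#' @param bin_width bin width in ms.
#' @return smoothed vector, same length.
#' @export
smooth_gaussian <- function(v, sd_ms = 10, bin_width = 2) {
  half <- ceiling(4 * sd_ms / bin_width)
  kern <- stats::dnorm(seq(-half, half) * bin_width, sd = sd_ms)
  n <- length(v)
  out <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1, k - half); hi <- min(n, k + half)
    kk <- kern[(lo - k + half + 1):(hi - k + half + 1)]
    out[k] <- sum(v[lo:hi] * kk) / sum(kk)
  }
  out
}

#' Rank conditions by response strength (total variation)
#'
#' Scores each condition by the sum over areas of the total variation of the
#' Gaussian-smoothed group PSTH (sum of absolute successive differences), and
#' returns the conditions in descending score order. Used to screen for
#' conditions with strong fluctuating (two-peak) responses.
#'
#' @param dataset a [spike_dataset()].
#' @param member_ids neuron ids to form the group PSTH (typically the active
#'   set from [select_active_neurons()]); may span several areas.
#' @param areas areas to include in the score.
#' @param kernel_sd Gaussian kernel standard deviation in ms.
#' @param bin_width bin width in ms.
#' @return data frame with columns `condition` and `score`, sorted descending.
#' @export
rank_conditions_by_tv <- function(dataset, member_ids, areas = dataset$areas,
                                  kernel_sd = 10, bin_width = 2) {
  member_ids <- as.character(member_ids)
  score <- vapply(dataset$conditions, function(cc) {
    s <- 0
    for (a in areas) {
      ids <- member_ids[dataset$neuron_area[member_ids] == a]
      if (length(ids) == 0L) next
      sm <- smooth_gaussian(psth(dataset, ids, cc, bin_width), kernel_sd, bin_width)
      s <- s + sum(abs(diff(sm)))
    }
    s
  }, numeric(1))
  out <- data.frame(condition = dataset$conditions, score = score)
  out[order(-out$score), , drop = FALSE]
}
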