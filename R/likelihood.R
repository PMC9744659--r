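#' Discretized point-process log-likelihood
#'
#' `sum_k [ y_k log mu_k - mu_k - log(y_k!) ]` for bin counts `y` and expected
#' counts `mu` per bin. The factorial constants are retained so that
#' log-likelihoods are comparable across competing intensity models (as needed
#' by the membership update).
#'
#' @param y nonnegative integer counts per bin (or a `binned_train`).
#' @param mu strictly positive expected counts per bin.
#' @return scalar log-likelihood.
#' @export
pp_loglik <- function(y, mu) {
  if (inherits(y, "binned_train")) y <- y$counts
  if (any(mu <= 0)) stop("intensity must be strictly positive")
  pp_loglik_cpp(as.integer(y), as.numeric(mu))
}

#' Template set
#'
#' Per (area, condition) spline-coefficient templates for the three neuron
#' groups, together with the warp landmarks. `beta_pop` and `beta_loc1` are
#' spline coefficient vectors for the interacting-population and local
#' time-varying log rates (spikes/s per neuron); `beta_loc2` is the constant
#' log rate of the background group.
#'
#' @param basis an [bspline_basis()] object shared by all templates.
#' @param areas,conditions labels.
#' @return object of class `template_set`; entries are filled by the
#'   initializer, the samplers, or the simulator via
#'   `ts$tmpl[[area]][[condition]] <- list(beta_pop=, beta_loc1=, beta_loc2=,
#'   spec=)`.
#' @export
template_set <- function(basis, areas, conditions) {
  tmpl <- stats::setNames(lapply(areas, function(a) {
    stats::setNames(vector("list", length(conditions)), as.character(conditions))
  }), areas)
  structure(list(basis = basis, areas = areas,
                 conditions = conditions, tmpl = tmpl),
            class = "template_set")
}

# internal accessor
.tmpl <- function(templates, area, condition)
  templates$tmpl[[area]][[as.character(condition)]]

#' Population intensity on the bin grid
#'
#' Assembles the model intensity (spikes/s for the whole group) for one
#' (group, area, condition, trial): the interacting population uses the
#' time-warped template plus gain, `local-1` the unwarped local template,
#' `local-2` a constant.
#'
#' @param templates a [template_set()] with the entry filled.
#' @param group one of `"pop"`, `"local-1"`, `"local-2"`.
#' @param area,condition labels.
#' @param q feature triple `c(gain, peak1, peak2)` for the trial (used only
#'   for `"pop"`).
#' @param n_neurons group size `N` (exposure).
#' @return numeric vector of rates per bin (spikes/s for the merged group).
#' @export
population_intensity <- function(templates, group, area, condition,
                                 q = c(0, 0, 0), n_neurons = 1) {
  tm <- .tmpl(templates, area, condition)
  if (is.null(tm)) stop("template not set for this (area, condition)")
  basis <- templates$basis
  if (group == "pop") {
    w <- build_warp(tm$spec, q[2], q[3])
    tw <- warp_time(w, basis$times, inverse = TRUE)
    f <- eval_spline(basis, tm$beta_pop, tw)
    n_neurons * exp(f + q[1])
  } else if (group == "local-1") {
    n_neurons * exp(drop(basis$B %*% tm$beta_loc1))
  } else if (group == "local-2") {
    rep(n_neurons * exp(tm$beta_loc2), basis$n_bins)
  } else stop("unknown group label: ", group)
}

#' Per-neuron log-likelihood under each group template
#'
#' Scores one neuron's spike trains (exposure 1) under the three competing
#' intensity models, summing over trials. The interacting-population score
#' warps the neuron's spikes into template time with the trial's peak shifts
#' and adds the trial gain; the warped spike train is scored against the
#' unwarped template, exactly as in the sampler's membership update.
#'
#' @param trial_times list over trials of the neuron's spike-time vectors (ms).
#' @param templates a [template_set()].
#' @param area,condition labels.
#' @param q matrix (`n_trials` x 3) of trial features `(gain, peak1, peak2)`.
#' @return named numeric triple `c(pop=, local1=, local2=)`.
#' @export
neuron_loglik_by_group <- function(trial_times, templates, area, condition, q) {
  tm <- .tmpl(templates, area, condition)
  basis <- templates$basis
  q <- matrix(q, ncol = 3)
  f_pop <- drop(basis$B %*% tm$beta_pop)
  f_l1 <- drop(basis$B %*% tm$beta_loc1)
  f_l2 <- rep(tm$beta_loc2, basis$n_bins)
  id <- c(0, basis$T)
  out <- c(pop = 0, local1 = 0, local2 = 0)
  for (r in seq_along(trial_times)) {
    y <- bin_counts_cpp(as.numeric(trial_times[[r]]), basis$n_bins,
                        basis$bin_width)
    w <- build_warp(tm$spec, q[r, 2], q[r, 3])
    out["pop"] <- out["pop"] + group_loglik_cpp(
      y, w$y, w$x, f_pop, q[r, 1], 1, basis$bin_width)
    out["local1"] <- out["local1"] + group_loglik_cpp(
      y, id, id, f_l1, 0, 1, basis$bin_width)
    out["local2"] <- out["local2"] + group_loglik_cpp(
      y, id, id, f_l2, 0, 1, basis$bin_width)
  }
  out
}
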