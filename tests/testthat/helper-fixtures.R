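# Shared fixtures, built in code at test time.

# tiny hand-made spike table: 2 areas x 2 conditions x 2 trials
tiny_table <- function() {
  data.frame(
    neuron_id = c("v1.a", "v1.a", "v1.b", "lm.a", "lm.a", "v1.a", "lm.a"),
    area = c("V1", "V1", "V1", "LM", "LM", "V1", "LM"),
    condition_id = c(1, 1, 1, 1, 1, 2, 2),
    trial_id = c(1, 1, 1, 1, 2, 1, 2),
    time_ms = c(10, 250, 100, 40, 450, 33, 77))
}

tiny_dataset <- function() spike_dataset(tiny_table(), T = 500)

# small simulated dataset, memoised per session (several tests reuse it)
.sim_cache <- new.env()
small_sim <- function(C = 2, seed = 42) {
  key <- paste0("s", C, "_", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_iprf(C = C, seed = seed)
  .sim_cache[[key]]
}

# default two-peak warp landmarks used in several warp tests
demo_spec <- function() warp_spec(40, 57, 80, 150, 216, 300, T = 500)
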