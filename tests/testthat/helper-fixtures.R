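# Shared fixtures, all generated in code.

tiny_trials <- function() {
  psy_trials(tibble::tibble(
    subject = rep(c("s1", "s2"), each = 4),
    stimulus = rep(c(1, 2, 3, 4), 2),
    condition = "c0",
    successes = c(1, 3, 7, 9, 0, 4, 6, 10),
    trials = 10
  ), study = "tiny", reference = 2.5)
}

# a small two-condition study simulated from a fixed truth
small_truth <- function(beta0 = 0.8, beta1 = 0.5) {
  tibble::tibble(group = "all", condition = c("c0", "c1"),
                 pse = 2.5, beta = c(beta0, beta1),
                 tau_pse = 16, tau_beta = 100)
}

small_design <- function(n_subjects = 4, repetitions = 8) {
  design_spec(n_subjects, stimulus_levels = c(0.5, 1.5, 2.5, 3.5, 4.5),
              repetitions = repetitions, conditions = c("c0", "c1"),
              reference = 2.5)
}

small_sim <- function(seed = 1, ...) {
  simulate_study(small_design(...), small_truth(), seed = seed)$data
}

quick_config <- function(seed = 1, n_iter = 300, n_warmup = 300,
                         n_chains = 2) {
  chain_config(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
               seed = seed)
}

# a fit object with externally supplied draws, for metric tests
fake_fit <- function(bound, draw_array) {
  structure(list(draws = draw_array, spec = bound, data = bound$data,
                 config = NULL, power = NULL, provenance = list()),
            class = "psy_fit")
}

# draws array [iter, chain, P] filled with one constant state per name
constant_draws <- function(bound, params, n_iter = 4, n_chains = 2) {
  arr <- array(rep(params[bound$param_names],
                   each = n_iter * n_chains),
               dim = c(n_iter, n_chains, length(bound$param_names)),
               dimnames = list(NULL, NULL, bound$param_names))
  arr
}

# draw a structurally valid random parameter vector from the hyperpriors
init_params_for_test <- function(bound) {
  psyborrow:::init_from_prior(bound)
}
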