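# Shared fixture builders: every fixture is generated in code, seeded.

# The standard simulation study: n items on a 1-d feature line, a bimodal
# target over the line, a b-regular ring over the feature ordering.
fixture_study <- function(n = 50L, b = 6L, seed = 101L, width = 0.3,
                          gamma = 1) {
  stimuli <- make_stimuli(n, 1L, seed = seed)
  modes <- matrix(stats::quantile(stimuli$features[, 1L], c(0.25, 0.75)),
                  2L, 1L)
  target <- make_target_distribution(stimuli, "bimodal", modes = modes,
                                     widths = width, gamma = gamma)
  graph <- ring_graph(stimuli, b)
  list(stimuli = stimuli, target = target, graph = graph)
}

# A tiny connected graph fixture: 6-node ring, b = 2.
fixture_ring6 <- function() ring_graph(6L, 2L)

# A short simulated session log on a small fixture.
fixture_log <- function(seed = 7L, trials = 60L, n_catch = 6L,
                        n_practice = 4L, chains_per_category = 1L,
                        categories = "cat") {
  fx <- fixture_study(n = 12L, b = 2L, seed = seed)
  cfg <- session_config(categories, chains_per_category,
                        trials_per_chain = trials, n_practice = n_practice,
                        n_catch = n_catch, catch_pass_threshold = 0L,
                        seed = seed)
  log <- run_session(cfg, fx$graph, luce_chooser(fx$target))
  list(log = log, config = cfg, fx = fx)
}

# Random symmetric weight matrix with zero diagonal.
random_similarity <- function(n, seed) {
  set.seed(seed)
  S <- matrix(stats::rnorm(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  S
}
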