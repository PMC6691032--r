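test_that("empirical_distribution normalizes visit counts over the universe", {
  lg <- fixture_log(seed = 3, trials = 80, n_catch = 5, n_practice = 4)
  ids <- lg$fx$stimuli$item_ids
  ed <- empirical_distribution(lg$log, item_ids = ids)
  expect_equal(sum(ed$frequencies), 1, tolerance = 1e-9)
  expect_true(all(ed$frequencies >= 0))
  expect_identical(ed$n_samples, 80L)

  # practice/catch never counted: frequencies recomputed from chain rows only
  chain_rows <- lg$log[lg$log$trial_type == "chain", ]
  oracle <- table(factor(chain_rows$chosen_id, levels = ids))
  expect_equal(unname(ed$frequencies), as.numeric(oracle) / 80)

  # choices and states modes coincide (state after a trial = chosen item)
  expect_equal(empirical_distribution(lg$log, ids,
                                      count_mode = "states")$frequencies,
               ed$frequencies)

  # burn-in drops early trials; order-invariance over chain concatenation
  ed2 <- empirical_distribution(lg$log, ids, burn_in = 30)
  expect_identical(ed2$n_samples, 50L)
  shuffled <- lg$log[sample(nrow(lg$log)), ]
  expect_equal(empirical_distribution(shuffled, ids, burn_in = 30)$frequencies,
               ed2$frequencies)

  expect_error(empirical_distribution(lg$log, ids, burn_in = 1000),
               "burn-in")
  stuck <- chain_rows[1:5, ]
  stuck$chosen_id <- stuck$current_id[1]
  expect_equal(max(empirical_distribution(stuck)$frequencies), 1)
})

test_that("sliding cumulative averages window the chosen items' features", {
  lg <- fixture_log(seed = 9, trials = 60, n_catch = 0, n_practice = 0)
  feats <- lg$fx$stimuli$features
  trials <- lg$log[lg$log$trial_type == "chain", ]
  avg <- sliding_cumulative_average(lg$log, feats, window = 10,
                                    eval_points = c(3, 10, 25, 60))
  # t < window: average over all trials so far
  expect_equal(avg["3", ], colMeans(feats[trials$chosen_id[1:3], , drop = FALSE]),
               ignore_attr = TRUE)
  # t >= window: only the last `window` choices contribute
  expect_equal(avg["25", ], colMeans(feats[trials$chosen_id[16:25], , drop = FALSE]),
               ignore_attr = TRUE)
  # window = 1 returns the t-th chosen item's features
  w1 <- sliding_cumulative_average(lg$log, feats, window = 1,
                                   eval_points = c(7, 40))
  expect_equal(w1["40", ], feats[trials$chosen_id[40], ], ignore_attr = TRUE)
  expect_error(sliding_cumulative_average(lg$log, feats, eval_points = 100),
               "eval points")

  # default grid: unique log-spaced integers ending at the chain length
  pts <- log_spaced_points(60)
  expect_equal(pts[1], 1)
  expect_equal(pts[length(pts)], 60)
  expect_true(all(diff(pts) > 0))
})

test_that("l1_histogram_distance is the L1 metric on histograms", {
  expect_identical(l1_histogram_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(l1_histogram_distance(c(1, 0, 0), c(0, 0.5, 0.5)), 2)
  expect_identical(l1_histogram_distance(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)),
                   1.0)
  expect_error(l1_histogram_distance(1:3, 1:4), "lengths")
  # metric properties on random normalized triples
  set.seed(2)
  for (i in 1:20) {
    h <- matrix(runif(15), 3)
    h <- h / rowSums(h)
    d12 <- l1_histogram_distance(h[1, ], h[2, ])
    d13 <- l1_histogram_distance(h[1, ], h[3, ])
    d23 <- l1_histogram_distance(h[2, ], h[3, ])
    expect_equal(d12, l1_histogram_distance(h[2, ], h[1, ]))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("within/between convergence separates distinct category targets", {
  # two categories with targets on opposite ends of the feature line
  stim <- make_stimuli(30, 1, seed = 77)
  q <- stats::quantile(stim$features[, 1], c(0.15, 0.85))
  tgt_a <- make_target_distribution(stim, "unimodal",
                                    modes = matrix(q[1], 1, 1), widths = 0.25)
  tgt_b <- make_target_distribution(stim, "unimodal",
                                    modes = matrix(q[2], 1, 1), widths = 0.25)
  graph <- ring_graph(stim, 4)
  cfg <- session_config("a", 2, trials_per_chain = 400, n_practice = 0,
                        n_catch = 0, catch_pass_threshold = 0, seed = 17)
  log_a <- run_session(cfg, graph, luce_chooser(tgt_a, seed = 1))
  cfg_b <- session_config("b", 2, trials_per_chain = 400, n_practice = 0,
                          n_catch = 0, catch_pass_threshold = 0, seed = 18)
  log_b <- run_session(cfg_b, graph, luce_chooser(tgt_b, seed = 2))
  log <- rbind(as.data.frame(log_a), as.data.frame(log_b))

  curves <- within_between_convergence(log, frequency_histogram(stim$item_ids))
  final <- curves[nrow(curves), ]
  expect_lt(final$within, final$between)
  # within-chain distance decreases over time
  expect_lt(final$within, curves$within[1])

  # identical logs for every chain: both distances are exactly 0
  one <- as.data.frame(log_a)[log_a$chain_id == "a-1" &
                                log_a$trial_type == "chain", ]
  same <- do.call(rbind, lapply(list(c("a-1", "a"), c("a-2", "a"),
                                     c("b-1", "b"), c("b-2", "b")),
                                function(cc) {
                                  d <- one
                                  d$chain_id <- cc[1]
                                  d$category <- cc[2]
                                  d
                                }))
  curves0 <- within_between_convergence(same,
                                        frequency_histogram(stim$item_ids),
                                        eval_points = c(10, 100))
  expect_equal(unname(unlist(curves0[, c("within", "between")])),
               rep(0, 4))

  expect_error(within_between_convergence(as.data.frame(log_a),
                                          frequency_histogram(stim$item_ids)),
               "2 categories")
})

test_that("category frequencies are normalized choice proportions", {
  lg <- fixture_log(seed = 5, trials = 40, n_catch = 0, n_practice = 0)
  ids <- lg$fx$stimuli$item_ids
  tags <- stats::setNames(rep(c("A", "B", "C"), length.out = length(ids)), ids)
  cf <- category_frequency(lg$log, tags)
  expect_equal(sum(cf), 1, tolerance = 1e-12)
  # independent recount
  chosen <- lg$log$chosen_id[lg$log$trial_type == "chain"]
  expect_equal(unname(cf["B"]), mean(tags[chosen] == "B"))

  # hand-countable toy log: choices tagged A, A, B, C
  toy <- lg$log[lg$log$trial_type == "chain", ][1:4, ]
  toy_tags <- stats::setNames(c("A", "A", "B", "C"), toy$chosen_id)
  # make chosen ids distinct so the map is well-defined
  toy$chosen_id <- names(toy_tags) <- paste0("w", 1:4)
  expect_equal(unname(category_frequency(toy, toy_tags)),
               c(0.5, 0.25, 0.25))

  # permuting the tag alphabet permutes the output identically
  perm_tags <- stats::setNames(c(A = "C", B = "A", C = "B")[tags], ids)
  cf_perm <- category_frequency(lg$log, perm_tags)
  expect_equal(unname(cf_perm[c("C", "A", "B")]), unname(cf[c("A", "B", "C")]))

  untagged <- tags[-1]
  expect_error(category_frequency(lg$log, untagged), ids[1])
})

test_that("top_k_items ranks by count with id tie-breaking", {
  lg <- fixture_log(seed = 21, trials = 100, n_catch = 0, n_practice = 0)
  top <- top_k_items(lg$log, 5)
  # independent count-and-sort oracle
  chosen <- lg$log$chosen_id[lg$log$trial_type == "chain"]
  tab <- sort(table(chosen), decreasing = TRUE)
  expect_identical(top$count, as.integer(tab[1:5]))
  expect_identical(top$item_id[1], names(which.max(table(chosen))))
  expect_true(all(diff(top$count) <= 0))
  # ties broken by ascending id
  ties <- which(top$count[-1] == top$count[-5])
  for (i in ties) expect_true(top$item_id[i] < top$item_id[i + 1])

  expect_identical(nrow(top_k_items(lg$log, 1)), 1L)
  all_items <- top_k_items(lg$log, 500)
  expect_true(isTRUE(attr(all_items, "short_list")))
  expect_identical(nrow(all_items), length(unique(chosen)))
})
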