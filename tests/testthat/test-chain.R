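test_that("session arithmetic matches the configured design", {
  fx <- fixture_study(n = 20, b = 4, seed = 3)
  ch <- luce_chooser(fx$target)

  # 4 chains x 100 + 12 practice + 40 catch = 452
  cfg <- session_config(c("happy", "sad"), 2, trials_per_chain = 100,
                        n_practice = 12, n_catch = 40, seed = 5)
  expect_identical(cfg$total_trials, 452L)
  log <- run_session(cfg, fx$graph, ch)
  expect_identical(nrow(log), 452L)
  expect_identical(sum(log$trial_type == "chain"), 400L)
  expect_identical(sum(log$trial_type == "practice"), 12L)
  expect_identical(sum(log$trial_type == "catch"), 40L)
  # practice trials all precede the first chain or catch trial
  expect_identical(which(log$trial_type == "practice"), 1:12)

  # 4 chains x 100 + 12 practice, no catch = 412
  cfg2 <- session_config("morality", 4, trials_per_chain = 100,
                         n_practice = 12, n_catch = 0, seed = 5)
  expect_identical(cfg2$total_trials, 412L)
  expect_identical(nrow(run_session(cfg2, fx$graph, ch)), 412L)

  expect_error(session_config("c", 1, trials_per_chain = 0,
                              n_practice = 0, n_catch = 0), "empty")
})

test_that("run_trial moves exactly as the oracle dictates", {
  fx <- fixture_study(n = 12, b = 2, seed = 13)
  spec <- proposal_spec(jump_prob = 0.1)
  always_prop <- structure(list(stochastic = FALSE),
                           class = c("take_proposal", "chooser"))
  always_cur <- structure(list(stochastic = FALSE),
                          class = c("take_current", "chooser"))
  assign("choose_item.take_proposal",
         function(chooser, current, proposal, ...) proposal,
         envir = globalenv())
  assign("choose_item.take_current",
         function(chooser, current, proposal, ...) current,
         envir = globalenv())
  on.exit(rm("choose_item.take_proposal", "choose_item.take_current",
             envir = globalenv()))

  set.seed(1)
  st <- list(chain_id = "c1", category = "cat",
             current = fx$stimuli$item_ids[1], history = character(0))
  for (i in 1:20) {
    out <- run_trial(st, fx$graph, spec, always_prop)
    expect_identical(out$record$chosen_id, out$record$proposal_id)
    expect_false(identical(out$state$current, st$current))
    expect_false(identical(out$record$proposal_id, out$record$current_id))
    st <- out$state
  }
  st2 <- list(chain_id = "c1", category = "cat",
              current = fx$stimuli$item_ids[5], history = character(0))
  for (i in 1:20) {
    out <- run_trial(st2, fx$graph, spec, always_cur)
    expect_identical(out$state$current, fx$stimuli$item_ids[5])
    st2 <- out$state
  }
  expect_true(all(st2$history == fx$stimuli$item_ids[5]))
})

test_that("per-pair acceptance rates follow the Luce closed form", {
  fx <- fixture_study(n = 10, b = 2, seed = 23, width = 0.5)
  ch <- luce_chooser(fx$target, seed = 23)
  cfg <- session_config("cat", 1, trials_per_chain = 12000, n_practice = 0,
                        n_catch = 0, catch_pass_threshold = 0, seed = 23)
  log <- run_session(cfg, fx$graph, ch)
  trials <- log[log$trial_type == "chain", ]
  key <- paste(trials$current_id, trials$proposal_id)
  moved <- trials$chosen_id == trials$proposal_id
  counts <- table(key)
  frequent <- names(counts)[counts >= 400]
  expect_gt(length(frequent), 2)
  p <- fx$target$probs
  for (k in frequent) {
    ids <- strsplit(k, " ")[[1]]
    emp <- mean(moved[key == k])
    theo <- p[[ids[2]]] / (p[[ids[2]]] + p[[ids[1]]])
    expect_lt(abs(emp - theo), 0.06)
  }
})

test_that("practice and catch trials never alter chain states", {
  lg <- fixture_log(seed = 31, trials = 50, n_catch = 8, n_practice = 6)
  trials <- lg$log[lg$log$trial_type == "chain", ]
  # log replay of chain continuity: each trial starts where the previous
  # chain trial of the same chain ended, regardless of interleaved
  # practice/catch rows
  for (cid in unique(trials$chain_id)) {
    tr <- trials[trials$chain_id == cid, ]
    expect_identical(tr$current_id[-1], tr$chosen_id[-nrow(tr)])
  }
  expect_identical(unname(attr(lg$log, "final_states")),
                   trials$chosen_id[nrow(trials)])
})

test_that("linking passes final states and accumulates 1000-trial chains", {
  fx <- fixture_study(n = 15, b = 2, seed = 41)
  ch <- luce_chooser(fx$target, seed = 41)
  cfg <- session_config("s", 2, trials_per_chain = 100, n_practice = 2,
                        n_catch = 3, catch_pass_threshold = 0, seed = 41)
  log1 <- run_session(cfg, fx$graph, ch)
  log2 <- link_sessions(log1, cfg, fx$graph, ch)
  finals1 <- attr(log1, "final_states")
  for (cid in names(finals1)) {
    tr2 <- log2[log2$trial_type == "chain" & log2$chain_id == cid, ]
    expect_identical(tr2$current_id[1], unname(finals1[[cid]]))
  }

  # ten linked sessions at 100 trials/chain give 1000 chain trials/chain
  full <- run_linked_sessions(cfg, fx$graph, ch, n_sessions = 10)
  per_chain <- table(full$chain_id[full$trial_type == "chain"])
  expect_true(all(per_chain == 1000L))
  expect_identical(length(unique(full$participant_id)), 10L)

  bad_cfg <- session_config("other", 2, trials_per_chain = 10,
                            n_practice = 0, n_catch = 0, seed = 1)
  expect_error(link_sessions(log1, bad_cfg, fx$graph, ch), "mismatch")
})

test_that("catch exclusion counts correct answers against the threshold", {
  fx <- fixture_study(n = 20, b = 2, seed = 51, width = 0.15)
  ch <- luce_chooser(fx$target, seed = 51)
  cfg <- session_config("cat", 1, trials_per_chain = 20, n_practice = 0,
                        n_catch = 40, catch_pass_threshold = 27, seed = 51)
  log <- run_session(cfg, fx$graph, ch)
  verdict <- catch_exclusion(log)
  expect_identical(verdict$n_catch, 40L)
  expect_identical(verdict$pass, verdict$n_correct >= 27)

  # boundary behavior on a synthetic log
  fake <- log[log$trial_type == "catch", ]
  fake$chosen_id <- fake$correct_id
  fake$chosen_id[1:14] <- ifelse(fake$current_id[1:14] == fake$correct_id[1:14],
                                 fake$proposal_id[1:14], fake$current_id[1:14])
  expect_false(catch_exclusion(fake, 27)$pass)   # 26 correct
  fake$chosen_id[1] <- fake$correct_id[1]
  expect_true(catch_exclusion(fake, 27)$pass)    # 27 correct
  expect_true(catch_exclusion(fake, 0)$pass)
  expect_error(catch_exclusion(log[log$trial_type == "chain", ], 27),
               "no catch trials")
})

test_that("binomial_catch_threshold matches exact tail summation", {
  # hand-checkable cases
  expect_identical(binomial_catch_threshold(1, 0.6), 1L)
  expect_identical(binomial_catch_threshold(2, 0.3), 2L)
  # oracle: direct tail summation with choose()/2^n
  tail_sum <- function(n, k) sum(choose(n, k:n)) / 2^n
  for (n in c(10, 25, 40)) {
    k <- binomial_catch_threshold(n, 0.01)
    expect_lt(tail_sum(n, k), 0.01)
    expect_gte(tail_sum(n, k - 1), 0.01)
  }
  # the conventional in-lab threshold of 27/40 is more lenient than the
  # exact alpha = .01 tail, which first drops below .01 at k = 28
  k40 <- binomial_catch_threshold(40, 0.01)
  expect_identical(k40, 28L)
  expect_lt(tail_sum(40, 28), 0.01)
  expect_gt(tail_sum(40, 27), 0.01)
})
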