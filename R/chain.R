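# The d-MCMCP engine: sessions of pairwise-choice trials ----------------------

#' Configure a d-MCMCP session
#'
#' A session is what one participant completes: a block of practice trials,
#' then the chain trials of all chains interleaved round-robin, with catch
#' trials inserted at seeded random positions. Practice and catch trials
#' never advance any chain. The defaults mirror a standard in-lab session:
#' 100 trials per chain, 12 practice trials, 40 catch trials with a
#' pass threshold of 27 correct.
#'
#' @param categories Character vector of category labels.
#' @param chains_per_category Chains run for each category.
#' @param trials_per_chain Chain trials per chain per session.
#' @param n_practice Practice trials (excluded from analysis).
#' @param n_catch Catch trials (objectively correct answer recorded).
#' @param catch_pass_threshold Minimum correct catch trials to keep the
#'   session; see [binomial_catch_threshold()] for the exact binomial-tail
#'   computation.
#' @param proposal A [proposal_spec()].
#' @param seed Session RNG seed.
#' @return Object of class `session_config`. Field `chains` is a data frame
#'   (chain_id, category); `total_trials` is
#'   `n_chains * trials_per_chain + n_practice + n_catch`.
#' @export
session_config <- function(categories, chains_per_category = 1L,
                           trials_per_chain = 100L, n_practice = 12L,
                           n_catch = 40L, catch_pass_threshold = 27L,
                           proposal = proposal_spec(), seed = 1L) {
  categories <- as.character(categories)
  if (!length(categories)) stop("need at least one category")
  if (trials_per_chain < 0L || n_practice < 0L || n_catch < 0L)
    stop("trial counts must be nonnegative")
  chains <- do.call(rbind, lapply(categories, function(cat)
    data.frame(chain_id = paste0(cat, "-", seq_len(chains_per_category)),
               category = cat, stringsAsFactors = FALSE)))
  total <- nrow(chains) * trials_per_chain + n_practice + n_catch
  if (total == 0L) stop("empty session: no chain, practice or catch trials")
  structure(
    list(categories = categories, chains = chains,
         trials_per_chain = as.integer(trials_per_chain),
         n_practice = as.integer(n_practice),
         n_catch = as.integer(n_catch),
         catch_pass_threshold = as.integer(catch_pass_threshold),
         proposal = proposal, seed = seed,
         total_trials = as.integer(total)),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config> ", nrow(x$chains), " chains x ", x$trials_per_chain,
      " trials + ", x$n_practice, " practice + ", x$n_catch,
      " catch = ", x$total_trials, " trials\n", sep = "")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  print(x$proposal)
  invisible(x)
}

new_chain_state <- function(chain_id, category, current) {
  list(chain_id = chain_id, category = category, current = current,
       history = character(0))
}

#' Run one chain trial
#'
#' Draws a proposal from the current state (re-drawing while the proposal
#' equals the current item, up to `max_retries` — two identical options
#' would make the question meaningless), presents the pair in a random
#' left/right order, asks the oracle, and moves the chain to the chosen
#' item. Consumes the ambient RNG stream.
#'
#' @param state Chain state as produced by [run_session()] internals: a
#'   list with `chain_id`, `category`, `current`, `history`.
#' @param graph A [proposal_graph()].
#' @param spec A [proposal_spec()].
#' @param oracle A chooser (see [choose_item()]).
#' @param max_retries Re-draw limit for proposal == current (default 100).
#' @return List with `record` (one trial's fields) and `state` (updated).
#' @export
run_trial <- function(state, graph, spec, oracle, max_retries = 100L) {
  x <- state$current
  proposal <- mixture_proposal(graph, spec, x)
  tries <- 1L
  while (identical(proposal, x)) {
    if (tries >= max_retries)
      stop("could not draw a proposal distinct from the current state ",
           "after ", max_retries, " tries")
    proposal <- mixture_proposal(graph, spec, x)
    tries <- tries + 1L
  }
  lr <- if (stats::runif(1L) < 0.5) c(x, proposal) else c(proposal, x)
  chosen <- choose_item(oracle, x, proposal, category = state$category)
  state$current <- chosen
  state$history <- c(state$history, chosen)
  list(
    record = list(trial_type = "chain", chain_id = state$chain_id,
                  category = state$category, current_id = x,
                  proposal_id = proposal, left_id = lr[1L],
                  right_id = lr[2L], chosen_id = chosen, correct_id = ""),
    state = state
  )
}

#' Run a full d-MCMCP session
#'
#' Executes the session a configuration describes: `n_practice` practice
#' trials first, then the chain trials interleaved round-robin over chains
#' with `n_catch` catch trials inserted at seeded random positions.
#' Practice and catch trials never advance chain states.
#'
#' @param config A [session_config()].
#' @param graph A [proposal_graph()].
#' @param oracle A chooser (see [choose_item()]).
#' @param init_states Named character vector mapping chain_id to a start
#'   item, or `NULL` for seeded uniform-random starts ("initialized at an
#'   arbitrary value").
#' @param catch_trials Data frame with columns `correct_id`, `foil_id` (one
#'   row per catch trial, recycled if short). If `NULL` and the oracle is a
#'   [luce_chooser()], pairs are generated from the extremes of its target
#'   via [make_catch_trials()].
#' @param participant_id,session_index Identifiers stamped on the log.
#' @param seed Session seed; defaults to `config$seed`.
#' @return A trial log: data frame of class `dmcmcp_log` with one row per
#'   trial in presentation order and attributes `final_states` (named
#'   vector, last state per chain) and `config`.
#' @export
run_session <- function(config, graph, oracle, init_states = NULL,
                        catch_trials = NULL, participant_id = "p1",
                        session_index = 1L, seed = config$seed) {
  stopifnot(inherits(config, "session_config"),
            inherits(graph, "proposal_graph"))
  chains <- config$chains
  n_chain_trials <- nrow(chains) * config$trials_per_chain
  if (config$n_catch > 0L && is.null(catch_trials)) {
    if (inherits(oracle, "luce_chooser")) {
      catch_trials <- make_catch_trials(oracle$target, config$n_catch,
                                        seed = seed)
    } else if (inherits(oracle, "replay_chooser")) {
      # replay presents the catch pairs the log recorded, in order
      rl <- oracle$state$log
      ct <- rl[rl$trial_type == "catch", , drop = FALSE]
      if (!nrow(ct))
        stop("replay log has no catch trials but config$n_catch > 0")
      foil <- ifelse(ct$current_id == ct$correct_id, ct$proposal_id,
                     ct$current_id)
      catch_trials <- data.frame(correct_id = ct$correct_id,
                                 foil_id = foil,
                                 stringsAsFactors = FALSE)
    } else {
      stop("catch trials requested but no catch_trials given and the ",
           "oracle has no target to derive them from")
    }
  }
  with_seed(seed, {
    # chain initialization
    states <- vector("list", nrow(chains))
    names(states) <- chains$chain_id
    for (k in seq_len(nrow(chains))) {
      cid <- chains$chain_id[k]
      start <- if (!is.null(init_states)) {
        if (is.na(match(cid, names(init_states))))
          stop("init_states is missing chain ", cid)
        init_states[[cid]]
      } else {
        graph$item_ids[sample.int(length(graph$item_ids), 1L)]
      }
      if (is.na(match(start, graph$item_ids)))
        stop("start item ", start, " for chain ", cid,
             " is not in the graph")
      states[[k]] <- new_chain_state(cid, chains$category[k], start)
    }

    total <- config$total_trials
    n_post <- n_chain_trials + config$n_catch
    # slot types after the practice block
    slot_type <- rep("chain", n_post)
    if (config$n_catch > 0L)
      slot_type[sort(sample.int(n_post, config$n_catch))] <- "catch"

    cols <- c("trial_type", "chain_id", "category", "current_id",
              "proposal_id", "left_id", "right_id", "chosen_id",
              "correct_id")
    rec <- sapply(cols, function(.) character(total), simplify = FALSE)

    put <- function(t, r) for (nm in cols) rec[[nm]][t] <<- r[[nm]]

    all_items <- graph$item_ids
    practice_cat <- rep_len(config$categories, max(config$n_practice, 1L))
    t <- 0L
    for (j in seq_len(config$n_practice)) {
      t <- t + 1L
      pr <- all_items[sample.int(length(all_items), 2L)]
      lr <- if (stats::runif(1L) < 0.5) pr else rev(pr)
      chosen <- choose_item(oracle, pr[1L], pr[2L],
                            category = practice_cat[j])
      put(t, list(trial_type = "practice", chain_id = "",
                  category = practice_cat[j], current_id = pr[1L],
                  proposal_id = pr[2L], left_id = lr[1L], right_id = lr[2L],
                  chosen_id = chosen, correct_id = ""))
    }

    chain_order <- rep(seq_len(nrow(chains)),
                       length.out = max(n_chain_trials, 1L))
    ci <- 0L   # chain trials executed
    ki <- 0L   # catch trials executed
    for (s in seq_len(n_post)) {
      t <- t + 1L
      if (slot_type[s] == "catch") {
        ki <- ki + 1L
        row <- catch_trials[((ki - 1L) %% nrow(catch_trials)) + 1L, ]
        pair <- c(row$correct_id, row$foil_id)
        if (stats::runif(1L) < 0.5) pair <- rev(pair)
        lr <- if (stats::runif(1L) < 0.5) pair else rev(pair)
        chosen <- choose_item(oracle, pair[1L], pair[2L],
                              category = config$categories[1L])
        put(t, list(trial_type = "catch", chain_id = "",
                    category = config$categories[1L],
                    current_id = pair[1L], proposal_id = pair[2L],
                    left_id = lr[1L], right_id = lr[2L], chosen_id = chosen,
                    correct_id = row$correct_id))
      } else {
        ci <- ci + 1L
        k <- chain_order[ci]
        out <- run_trial(states[[k]], graph, config$proposal, oracle)
        states[[k]] <- out$state
        put(t, out$record)
      }
    }

    log <- data.frame(
      participant_id = participant_id,
      session_index = as.integer(session_index),
      trial_index = seq_len(total),
      rec,
      stringsAsFactors = FALSE
    )
    class(log) <- c("dmcmcp_log", "data.frame")
    attr(log, "final_states") <- vapply(states, function(s) s$current, "")
    attr(log, "config") <- config
    log
  })
}

#' @export
print.dmcmcp_log <- function(x, ...) {
  tt <- table(x$trial_type)
  cat("<dmcmcp_log> ", nrow(x), " trials (",
      paste(names(tt), as.integer(tt), sep = ": ", collapse = ", "),
      "), ", length(unique(x$participant_id)), " participant(s)\n", sep = "")
  invisible(x)
}

#' Link a new session onto a previous one
#'
#' Chain linking passes each chain's final state to the next participant as
#' that chain's first non-practice state, so consecutive sessions form one
#' long chain per chain id.
#'
#' @param prev_log Log of the previous session (same graph and chain
#'   structure).
#' @param config,graph,oracle,catch_trials As in [run_session()].
#' @param participant_id Id for the new participant; default derived from
#'   the session index.
#' @return The new session's log (attributes as in [run_session()]).
#' @export
link_sessions <- function(prev_log, config, graph, oracle,
                          catch_trials = NULL, participant_id = NULL) {
  finals <- attr(prev_log, "final_states")
  if (is.null(finals)) {
    chain_rows <- prev_log[prev_log$trial_type == "chain", ]
    if (!nrow(chain_rows)) stop("previous log has no chain trials to link")
    finals <- vapply(split(chain_rows, chain_rows$chain_id),
                     function(d) d$chosen_id[nrow(d)], "")
  }
  if (!setequal(names(finals), config$chains$chain_id))
    stop("chain structure mismatch between previous log and config")
  session_index <- max(prev_log$session_index) + 1L
  if (is.null(participant_id)) participant_id <- paste0("p", session_index)
  run_session(config, graph, oracle, init_states = finals,
              catch_trials = catch_trials, participant_id = participant_id,
              session_index = session_index,
              seed = config$seed + session_index * 131L)
}

#' Run a sequence of linked sessions
#'
#' Convenience driver: runs `n_sessions` sessions, linking each chain's
#' final state into the next session, and returns the row-bound log.
#'
#' @inheritParams run_session
#' @param n_sessions Number of participants/sessions to link.
#' @return Combined `dmcmcp_log` with `final_states` of the last session.
#' @export
run_linked_sessions <- function(config, graph, oracle, n_sessions,
                                catch_trials = NULL) {
  log <- run_session(config, graph, oracle, catch_trials = catch_trials,
                     participant_id = "p1", session_index = 1L)
  logs <- list(log)
  for (s in seq_len(n_sessions - 1L)) {
    log <- link_sessions(log, config, graph, oracle,
                         catch_trials = catch_trials)
    logs[[s + 1L]] <- log
  }
  out <- do.call(rbind, lapply(logs, as.data.frame))
  class(out) <- c("dmcmcp_log", "data.frame")
  attr(out, "final_states") <- attr(log, "final_states")
  attr(out, "config") <- config
  out
}

#' Catch-trial exclusion rule
#'
#' Counts catch trials answered correctly and passes the session iff the
#' count reaches the threshold. Sessions failing the rule are excluded from
#' analysis and not linked into a chain.
#'
#' @param log A trial log containing catch trials with `correct_id` set.
#' @param threshold Minimum correct count (default from the log's config,
#'   else 27).
#' @return List with `pass`, `n_correct`, `n_catch`, `threshold`.
#' @export
catch_exclusion <- function(log, threshold = NULL) {
  if (is.null(threshold)) {
    cfg <- attr(log, "config")
    threshold <- if (!is.null(cfg)) cfg$catch_pass_threshold else 27L
  }
  catch <- log[log$trial_type == "catch", ]
  if (!nrow(catch) && threshold > 0L)
    stop("log has no catch trials but the threshold is positive")
  n_correct <- sum(catch$chosen_id == catch$correct_id)
  list(pass = n_correct >= threshold, n_correct = n_correct,
       n_catch = nrow(catch), threshold = threshold)
}

#' Exact binomial catch threshold
#'
#' Smallest k such that a random guesser (Binomial(n_catch, 1/2)) reaches k
#' or more correct with probability below `alpha` — the exclusion criterion
#' "p < alpha under random guessing" made exact.
#'
#' @param n_catch Number of catch trials.
#' @param alpha Tail probability bound in (0, 1).
#' @return Integer k in `[0, n_catch + 1]`.
#' @export
binomial_catch_threshold <- function(n_catch, alpha = 0.01) {
  stopifnot(n_catch >= 1L, alpha > 0, alpha < 1)
  for (k in 0:(n_catch + 1L)) {
    tail <- stats::pbinom(k - 1L, n_catch, 0.5, lower.tail = FALSE)
    if (tail < alpha) return(as.integer(k))
  }
  as.integer(n_catch + 1L)
}
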