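# Choice oracles: the acceptance step of the chain ----------------------------

#' Exponentiated Luce choice probability
#'
#' Probability of choosing the proposal over the current item when response
#' strengths are the target probabilities raised to an exponent gamma:
#' `p_proposal^gamma / (p_proposal^gamma + p_current^gamma)`. With gamma = 1
#' this is the Barker acceptance function, so a chain accepting by this rule
#' has the target as its stationary distribution; with general gamma the
#' chain converges to the target raised to gamma and renormalized.
#'
#' If exactly one option has probability 0 it is never chosen; both zero is
#' an error (a degenerate target should surface, not silently coin-flip).
#'
#' @param p_current,p_proposal Nonnegative response strengths.
#' @param gamma Nonnegative choice exponent; 0 (with both strengths
#'   positive) gives indifference.
#' @return Probability of choosing the proposal.
#' @export
luce_choice_prob <- function(p_current, p_proposal, gamma = 1) {
  if (p_current < 0 || p_proposal < 0)
    stop("choice strengths must be nonnegative")
  if (p_current == 0 && p_proposal == 0)
    stop("both options have probability 0: undefined choice")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (p_proposal == 0) return(0)
  if (p_current == 0) return(1)
  a <- p_proposal ^ gamma
  b <- p_current ^ gamma
  a / (a + b)
}

#' Simulated chooser obeying the exponentiated Luce rule
#'
#' The in-silico stand-in for a human responder: offered two items, it
#' chooses by a Bernoulli draw with [luce_choice_prob()] under its target
#' distribution. gamma lives on the chooser, not the chain — the engine
#' never needs to know it, which is exactly why an unknown response
#' exponent still yields a usable (power-transformed) estimate.
#'
#' The chooser draws from its own private RNG stream (seeded at creation),
#' not the ambient one, so the engine's stream of proposal and ordering
#' draws is identical whether choices come from this chooser or from a
#' replayed log — which is what makes exact session replay possible.
#'
#' @param target A [target_distribution()] giving p(x | c).
#' @param gamma Choice exponent (defaults to the target's).
#' @param seed Seed of the chooser's private stream.
#' @return Object of class `c("luce_chooser", "chooser")`.
#' @export
luce_chooser <- function(target, gamma = target$gamma, seed = 1L) {
  stopifnot(inherits(target, "target_distribution"))
  rng <- new.env(parent = emptyenv())
  rng$state <- NULL
  structure(list(target = target, gamma = gamma, seed = seed, rng = rng,
                 stochastic = TRUE),
            class = c("luce_chooser", "chooser"))
}

#' Replay chooser over a recorded trial log
#'
#' Re-issues the choices of a recorded session in order. Each call must be
#' offered the same (unordered) pair the log recorded at that position;
#' a mismatch raises a replay-desync error naming both positions. Replaying
#' a log through the engine under the original configuration reproduces the
#' original chain trajectory exactly.
#'
#' @param log A trial log data frame (see [read_log()]).
#' @return Object of class `c("replay_chooser", "chooser")`; its cursor
#'   advances internally with each choice.
#' @export
replay_chooser <- function(log) {
  log <- as.data.frame(log)
  env <- new.env(parent = emptyenv())
  env$cursor <- 1L
  env$log <- log
  structure(list(state = env, stochastic = FALSE),
            class = c("replay_chooser", "chooser"))
}

#' Ask a chooser to pick one of two items
#'
#' The contract every acceptance oracle satisfies: given the current item
#' and the proposal, return one of the two.
#'
#' @param chooser A chooser object.
#' @param current,proposal Item ids offered.
#' @param ... Passed to methods.
#' @return The chosen item id (always one of the two offered).
#' @export
choose_item <- function(chooser, current, proposal, ...) {
  UseMethod("choose_item")
}

#' @export
choose_item.luce_chooser <- function(chooser, current, proposal, ...) {
  if (identical(current, proposal)) return(current)
  probs <- chooser$target$probs
  pc <- probs[match(current, names(probs))]
  pp <- probs[match(proposal, names(probs))]
  if (is.na(pc)) stop("item outside the chooser's universe: ", current)
  if (is.na(pp)) stop("item outside the chooser's universe: ", proposal)
  p_acc <- luce_choice_prob(pc, pp, chooser$gamma)
  u <- private_draw(chooser$rng, chooser$seed, stats::runif(1L))
  if (u < p_acc) proposal else current
}

#' @export
choose_item.replay_chooser <- function(chooser, current, proposal, ...) {
  env <- chooser$state
  if (env$cursor > nrow(env$log))
    stop("replay log exhausted at position ", env$cursor)
  rec <- env$log[env$cursor, ]
  offered <- sort(c(current, proposal))
  logged <- sort(c(rec$current_id, rec$proposal_id))
  if (!identical(offered, logged))
    stop("replay desync at log position ", env$cursor,
         ": offered {", paste(offered, collapse = ", "),
         "} but log has {", paste(logged, collapse = ", "), "}")
  env$cursor <- env$cursor + 1L
  rec$chosen_id
}
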