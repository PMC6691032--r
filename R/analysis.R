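# Distribution estimates and convergence diagnostics from trial logs ----------

chain_trials <- function(log) log[log$trial_type == "chain", , drop = FALSE]

# Apply per-chain burn-in: drop the first `burn_in` chain trials of each
# chain (ordered by participant session then trial index).
drop_burn_in <- function(trials, burn_in) {
  if (burn_in <= 0L) return(trials)
  keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$chain_id),
                        function(idx) {
                          ord <- idx[order(trials$session_index[idx],
                                           trials$trial_index[idx])]
                          if (length(ord) > burn_in)
                            ord[-seq_len(burn_in)] else integer(0)
                        }), use.names = FALSE)
  trials[sort(keep), , drop = FALSE]
}

#' Empirical distribution of a chain run
#'
#' Normalized visit counts over post-burn-in chain trials: once a chain has
#' converged, items are visited with their stationary probabilities, so
#' these frequencies estimate the subjective category distribution (up to
#' the chooser's exponent). `count_mode = "choices"` counts each trial's
#' chosen item (the default, matching per-trial averaging of selected
#' items); `"states"` counts the chain state after each trial — the two
#' coincide because the state after a trial is the chosen item, but only
#' chain trials are ever counted in either mode.
#'
#' @param log A trial log.
#' @param item_ids Item universe for the estimate (defaults to items seen).
#' @param burn_in Chain trials discarded from the start of each chain.
#' @param count_mode `"choices"` or `"states"`.
#' @return Object of class `empirical_distribution`: list with
#'   `frequencies` (named, sums to 1), `n_samples`, `burn_in`.
#' @export
empirical_distribution <- function(log, item_ids = NULL, burn_in = 0L,
                                   count_mode = c("choices", "states")) {
  count_mode <- match.arg(count_mode)
  trials <- drop_burn_in(chain_trials(log), burn_in)
  if (!nrow(trials))
    stop("no chain trials remain after burn-in = ", burn_in)
  visited <- trials$chosen_id   # state after a trial == chosen item
  if (is.null(item_ids)) item_ids <- sort(unique(visited))
  counts <- table(factor(visited, levels = item_ids))
  freq <- stats::setNames(as.numeric(counts) / sum(counts), item_ids)
  structure(
    list(frequencies = freq, n_samples = nrow(trials),
         burn_in = as.integer(burn_in), count_mode = count_mode),
    class = "empirical_distribution"
  )
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat("<empirical_distribution> ", length(x$frequencies), " items from ",
      x$n_samples, " samples (burn-in ", x$burn_in, ")\n", sep = "")
  top <- sort(x$frequencies, decreasing = TRUE)
  top <- top[seq_len(min(5L, length(top)))]
  cat("  top:", paste(sprintf("%s=%.3f", names(top), top),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Log-spaced evaluation points
#'
#' `n_points` unique integers on a logarithmic grid from 1 to `n_trials`
#' (duplicates after rounding removed) — the trial counts at which
#' cumulative diagnostics are evaluated.
#'
#' @param n_trials Chain length.
#' @param n_points Grid size before deduplication (default 40).
#' @return Increasing integer vector ending at `n_trials`.
#' @export
log_spaced_points <- function(n_trials, n_points = 40L) {
  stopifnot(n_trials >= 1L)
  unique(round(exp(seq(0, log(n_trials), length.out = n_points))))
}

#' Sliding cumulative feature average along a chain
#'
#' At each evaluation point t, the mean feature vector of the items chosen
#' in the last `window` chain trials up to t (all trials up to t when
#' t < window). With image stimuli this is the "average image so far";
#' generically it is a windowed running mean in feature space.
#'
#' @param log A trial log (one chain, or chains to pool in log order).
#' @param features Numeric matrix of item features with item ids as
#'   rownames.
#' @param window Window length (>= 1); default 50.
#' @param eval_points Trial counts at which to evaluate; default 40
#'   log-spaced points over the chain length.
#' @return Matrix with one row per eval point (rownames = trial counts).
#' @export
sliding_cumulative_average <- function(log, features, window = 50L,
                                       eval_points = NULL) {
  stopifnot(window >= 1L)
  trials <- chain_trials(log)
  n <- nrow(trials)
  if (!n) stop("no chain trials in log")
  if (is.null(eval_points)) eval_points <- log_spaced_points(n)
  if (any(eval_points < 1L | eval_points > n))
    stop("eval points must lie in [1, ", n, "]")
  idx <- match(trials$chosen_id, rownames(features))
  if (anyNA(idx))
    stop("features missing for item(s): ",
         paste(unique(trials$chosen_id[is.na(idx)]), collapse = ", "))
  X <- features[idx, , drop = FALSE]
  out <- matrix(NA_real_, length(eval_points), ncol(features),
                dimnames = list(eval_points, colnames(features)))
  for (i in seq_along(eval_points)) {
    t <- eval_points[i]
    lo <- max(1L, t - window + 1L)
    out[i, ] <- colMeans(X[lo:t, , drop = FALSE])
  }
  out
}

#' L1 distance between histograms or frequency vectors
#'
#' `sum(|h1 - h2|)`: 0 for identical histograms, 2 for disjoint normalized
#' ones. The convergence metric for cumulative color-histogram curves.
#'
#' @param h1,h2 Equal-length numeric vectors (both normalized or both raw).
#' @return Nonnegative scalar.
#' @export
l1_histogram_distance <- function(h1, h2) {
  h1 <- as.numeric(h1); h2 <- as.numeric(h2)
  if (length(h1) != length(h2)) stop("histogram lengths differ")
  sum(abs(h1 - h2))
}

#' Within- versus between-category convergence curves
#'
#' For every chain, computes a cumulative histogram at each evaluation
#' point by applying `histogram_fn` to the items chosen up to that point;
#' then averages pairwise L1 distances between chains of the same category
#' (within) and across categories (between). A converging procedure shows
#' the within-category curve dropping below the between-category one.
#'
#' @param log A trial log with >= 2 chains in >= 2 categories.
#' @param histogram_fn Function: character vector of chosen item ids ->
#'   numeric histogram (fixed length). E.g. normalized item-frequency or a
#'   color histogram over the items' pixels.
#' @param eval_points Trial counts (per chain); default log-spaced over the
#'   shortest chain.
#' @return Data frame (eval_point, within, between) of class
#'   `convergence_curves`.
#' @export
within_between_convergence <- function(log, histogram_fn,
                                       eval_points = NULL) {
  trials <- chain_trials(log)
  by_chain <- split(trials, trials$chain_id)
  by_chain <- lapply(by_chain, function(d)
    d[order(d$session_index, d$trial_index), , drop = FALSE])
  chain_cat <- vapply(by_chain, function(d) d$category[1L], "")
  if (length(unique(chain_cat)) < 2L)
    stop("need chains in at least 2 categories")
  if (any(table(chain_cat) < 2L))
    stop("within-category curve undefined: some category has a single chain")
  n_min <- min(vapply(by_chain, nrow, 0L))
  if (is.null(eval_points)) eval_points <- log_spaced_points(n_min)
  if (any(eval_points > n_min))
    stop("eval points exceed the shortest chain (", n_min, " trials)")

  hists <- lapply(eval_points, function(t)
    lapply(by_chain, function(d) histogram_fn(d$chosen_id[seq_len(t)])))
  pairs <- utils::combn(length(by_chain), 2L)
  same <- chain_cat[pairs[1L, ]] == chain_cat[pairs[2L, ]]
  res <- t(vapply(hists, function(hh) {
    d <- apply(pairs, 2L, function(pr)
      l1_histogram_distance(hh[[pr[1L]]], hh[[pr[2L]]]))
    c(within = mean(d[same]), between = mean(d[!same]))
  }, c(within = 0, between = 0)))
  out <- data.frame(eval_point = eval_points, res)
  class(out) <- c("convergence_curves", "data.frame")
  out
}

#' Normalized choice frequency histogram over an item universe
#'
#' Convenience histogram function for [within_between_convergence()]:
#' counts chosen ids over a fixed item universe and normalizes.
#'
#' @param item_ids The fixed item universe.
#' @return Function mapping a character vector of chosen ids to a
#'   normalized frequency vector over `item_ids`.
#' @export
frequency_histogram <- function(item_ids) {
  force(item_ids)
  function(chosen) {
    counts <- table(factor(chosen, levels = item_ids))
    as.numeric(counts) / max(1L, sum(counts))
  }
}

#' Category choice proportions
#'
#' The proportion of chain-trial choices falling in each category tag —
#' e.g. the relevance profile of moral foundations, as the share of choices
#' landing on words of each foundation.
#'
#' @param log A trial log.
#' @param item_category_map Named character vector: item id -> tag (or a
#'   [stimulus_set()] with category tags).
#' @return Named numeric vector of proportions summing to 1, ordered by
#'   first appearance of each tag in the map.
#' @export
category_frequency <- function(log, item_category_map) {
  if (inherits(item_category_map, "stimulus_set")) {
    if (is.null(item_category_map$category_tags))
      stop("stimulus set has no category tags")
    item_category_map <- item_category_map$category_tags
  }
  chosen <- chain_trials(log)$chosen_id
  if (!length(chosen)) stop("no chain trials in log")
  tags <- item_category_map[match(chosen, names(item_category_map))]
  if (anyNA(tags))
    stop("untagged item(s) encountered: ",
         paste(unique(chosen[is.na(tags)]), collapse = ", "))
  levels <- unique(unname(item_category_map))
  counts <- table(factor(tags, levels = levels))
  out <- as.numeric(counts) / sum(counts)
  names(out) <- levels
  out
}

#' Most frequently chosen items
#'
#' Items ranked by descending choice count over chain trials; ties broken
#' by ascending item id. Asking for more items than were ever chosen
#' returns all of them with attribute `short_list = TRUE`.
#'
#' @param log A trial log.
#' @param k Number of items to return (>= 1).
#' @return Data frame (item_id, count) with `k` (or fewer) rows.
#' @export
top_k_items <- function(log, k = 10L) {
  stopifnot(k >= 1L)
  chosen <- chain_trials(log)$chosen_id
  if (!length(chosen)) stop("no chain trials in log")
  counts <- table(chosen)
  ord <- order(-as.numeric(counts), names(counts))
  out <- data.frame(item_id = names(counts)[ord],
                    count = as.integer(counts)[ord],
                    stringsAsFactors = FALSE)
  short <- k > nrow(out)
  out <- utils::head(out, k)
  rownames(out) <- NULL
  if (short) attr(out, "short_list") <- TRUE
  out
}
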