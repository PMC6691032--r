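# Synthetic stimulus sets and ground-truth targets ----------------------------

#' Construct a stimulus set
#'
#' A stimulus set is the discrete universe a chain walks over: unique item
#' ids, optionally a numeric feature vector per item (one fixed dimension),
#' optionally a category tag per item (e.g. a moral foundation or a season).
#'
#' @param item_ids Character vector of unique identifiers. Iteration order is
#'   the order given here and is deterministic.
#' @param features Optional numeric matrix, one row per item; row order
#'   matches `item_ids`.
#' @param category_tags Optional character vector of per-item labels, same
#'   length as `item_ids`.
#' @return An object of class `stimulus_set`.
#' @export
stimulus_set <- function(item_ids, features = NULL, category_tags = NULL) {
  item_ids <- as.character(item_ids)
  if (length(item_ids) < 2L)
    stop("a stimulus set needs at least 2 items (a chain needs >= 2 states)")
  if (anyDuplicated(item_ids))
    stop("item_ids must be unique")
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != length(item_ids))
      stop("features must have one row per item")
    if (!is.numeric(features) || anyNA(features))
      stop("features must be numeric with no missing values")
    rownames(features) <- item_ids
  }
  if (!is.null(category_tags)) {
    category_tags <- as.character(category_tags)
    if (length(category_tags) != length(item_ids))
      stop("category_tags must have one entry per item")
    names(category_tags) <- item_ids
  }
  structure(
    list(item_ids = item_ids, features = features,
         category_tags = category_tags),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> ", length(x$item_ids), " items", sep = "")
  if (!is.null(x$features))
    cat(", ", ncol(x$features), "-d features", sep = "")
  if (!is.null(x$category_tags))
    cat(", ", length(unique(x$category_tags)), " categories", sep = "")
  cat("\n")
  invisible(x)
}

#' Generate a synthetic stimulus set
#'
#' Items get standard-normal features, one coordinate per dimension. Output
#' is bit-reproducible for a given seed.
#'
#' @param n Number of items (>= 2).
#' @param d Feature dimension (>= 1).
#' @param seed Integer RNG seed.
#' @param prefix Prefix for the generated item ids.
#' @return A [stimulus_set()] with an `n` by `d` feature matrix.
#' @export
make_stimuli <- function(n, d = 2L, seed = 1L, prefix = "item") {
  if (n < 2L) stop("n must be >= 2 (a chain needs >= 2 states)")
  if (d < 1L) stop("d must be >= 1")
  ids <- sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
  feats <- with_seed(seed, matrix(stats::rnorm(n * d), nrow = n, ncol = d))
  stimulus_set(ids, features = feats)
}

#' Construct a target distribution over a stimulus set
#'
#' The target p(x | c) encodes how strongly each item belongs to the
#' category; the simulated chooser responds according to it and convergence
#' tests compare against it. `gamma` is the choice exponent carried along
#' for convenience: a chain driven by an exponentiated-Luce chooser
#' converges to `probs^gamma` renormalized.
#'
#' @param item_ids Item identifiers (order defines the probability vector).
#' @param probs Nonnegative weights, normalized internally.
#' @param gamma Nonnegative choice exponent (default 1).
#' @return An object of class `target_distribution`.
#' @export
target_distribution <- function(item_ids, probs, gamma = 1) {
  item_ids <- as.character(item_ids)
  probs <- as.numeric(probs)
  if (length(probs) != length(item_ids))
    stop("probs must have one entry per item")
  if (anyNA(probs) || any(probs < 0))
    stop("probs must be nonnegative and finite")
  s <- sum(probs)
  if (s <= 0) stop("probs must have positive total mass")
  if (gamma < 0) stop("gamma must be nonnegative")
  probs <- probs / s
  names(probs) <- item_ids
  structure(list(item_ids = item_ids, probs = probs, gamma = gamma),
            class = "target_distribution")
}

#' @export
print.target_distribution <- function(x, ...) {
  cat("<target_distribution> ", length(x$probs), " items, gamma = ",
      x$gamma, "\n", sep = "")
  top <- sort(x$probs, decreasing = TRUE)[seq_len(min(5L, length(x$probs)))]
  cat("  top mass:", paste(sprintf("%s=%.3f", names(top), top),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Exponentiate and renormalize a target distribution
#'
#' Returns the distribution proportional to `probs^gamma` — the stationary
#' distribution of a chain whose chooser has exponent `gamma`.
#'
#' @param target A [target_distribution()].
#' @param gamma Exponent; defaults to the one stored on the target.
#' @return A `target_distribution` with `gamma = 1` and exponentiated probs.
#' @export
exponentiate_target <- function(target, gamma = target$gamma) {
  stopifnot(inherits(target, "target_distribution"))
  p <- target$probs ^ gamma
  target_distribution(target$item_ids, p / sum(p), gamma = 1)
}

#' Build a synthetic target distribution over item features
#'
#' Subjective category distributions over real stimuli can be multimodal
#' (two distinct looks can both be typical of a category), so the mixture
#' kinds place isotropic Gaussian kernels at given mode centers in feature
#' space and evaluate the mixture density at each item's features.
#'
#' @param stimuli A [stimulus_set()]; must carry features unless
#'   `kind = "uniform"`.
#' @param kind One of `"uniform"`, `"unimodal"`, `"bimodal"`.
#' @param modes Numeric matrix of mode centers (one row per mode, `d`
#'   columns). `"unimodal"` requires exactly 1 row, `"bimodal"` exactly 2.
#' @param widths Kernel standard deviations, one per mode (recycled).
#' @param mode_weights Nonnegative mixture weights, one per mode (recycled,
#'   normalized).
#' @param gamma Choice exponent stored on the result.
#' @return A [target_distribution()] over the stimulus set.
#' @export
make_target_distribution <- function(stimuli,
                                     kind = c("uniform", "unimodal", "bimodal"),
                                     modes = NULL, widths = 1,
                                     mode_weights = 1, gamma = 1) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  kind <- match.arg(kind)
  n <- length(stimuli$item_ids)
  if (kind == "uniform")
    return(target_distribution(stimuli$item_ids, rep(1 / n, n), gamma = gamma))
  if (is.null(stimuli$features))
    stop("mixture targets need item features")
  if (is.null(modes) || NROW(modes) == 0L)
    stop("mixture kinds need a nonempty mode list")
  modes <- matrix(as.numeric(modes), ncol = ncol(stimuli$features))
  k <- nrow(modes)
  if (kind == "unimodal" && k != 1L) stop("unimodal needs exactly 1 mode")
  if (kind == "bimodal" && k != 2L) stop("bimodal needs exactly 2 modes")
  widths <- rep_len(as.numeric(widths), k)
  if (any(widths <= 0)) stop("kernel widths must be positive")
  w <- rep_len(as.numeric(mode_weights), k)
  if (any(w < 0) || sum(w) <= 0) stop("mode_weights must be nonnegative")
  w <- w / sum(w)
  dens <- numeric(n)
  for (j in seq_len(k)) {
    d2 <- colSums((t(stimuli$features) - modes[j, ])^2)
    dens <- dens + w[j] * exp(-d2 / (2 * widths[j]^2))
  }
  if (sum(dens) <= 0) stop("density vanished at every item; widen the kernels")
  target_distribution(stimuli$item_ids, dens, gamma = gamma)
}

#' Perturb a similarity matrix with symmetric noise
#'
#' Degrades an assumed similarity matrix to emulate a mismatch between the
#' similarities used to build the proposal graph and the ones people
#' perceive. Adds zero-mean Gaussian noise, symmetrized, scaled by
#' `noise_level` times the standard deviation of the off-diagonal entries,
#' so `noise_level` is unit-free. The diagonal is left untouched.
#'
#' @param S Symmetric numeric similarity matrix.
#' @param noise_level Nonnegative scalar; 0 returns `S` unchanged.
#' @param seed Integer RNG seed.
#' @return A perturbed matrix of the same shape, still symmetric.
#' @export
perturb_similarity <- function(S, noise_level, seed = 1L) {
  S <- as.matrix(S)
  check_symmetric(S, "S")
  if (!is.numeric(noise_level) || length(noise_level) != 1L || noise_level < 0)
    stop("noise_level must be a nonnegative scalar")
  if (noise_level == 0) return(S)
  n <- nrow(S)
  off_sd <- stats::sd(S[upper.tri(S)])
  noise <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
  noise <- (noise + t(noise)) / sqrt(2)   # keep per-entry variance at 1
  out <- S + noise_level * off_sd * noise
  diag(out) <- diag(S)
  out
}

#' Build catch-trial pairs from a target distribution
#'
#' Catch trials pair an item of very high target probability with one of
#' very low probability, so the correct answer is unambiguous; the correct
#' item is recorded on the trial.
#'
#' @param target A [target_distribution()].
#' @param n_catch Number of catch pairs.
#' @param seed Integer RNG seed for shuffling the extreme pools.
#' @param pool_frac Fraction of items forming the high- and low-probability
#'   pools (default 0.2 each).
#' @return Data frame with columns `correct_id` and `foil_id`.
#' @export
make_catch_trials <- function(target, n_catch, seed = 1L, pool_frac = 0.2) {
  stopifnot(inherits(target, "target_distribution"))
  if (n_catch < 1L) stop("n_catch must be >= 1")
  ord <- order(target$probs, decreasing = TRUE)
  ids <- target$item_ids[ord]
  k <- max(1L, floor(length(ids) * pool_frac))
  hi <- ids[seq_len(k)]
  lo <- ids[seq.int(length(ids) - k + 1L, length(ids))]
  with_seed(seed, data.frame(
    correct_id = sample(hi, n_catch, replace = TRUE),
    foil_id    = sample(lo, n_catch, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# Serialization: a stimulus directory is ids.txt (one id per line),
# features.tsv (row i = item i) and optionally tags.tsv (id <TAB> tag).

#' Write / read a stimulus set as plain text
#'
#' @param stimuli A [stimulus_set()].
#' @param dir Directory to hold `ids.txt`, `features.tsv`, `tags.tsv`.
#' @return `write_stimuli` returns `dir` invisibly; `read_stimuli` returns a
#'   [stimulus_set()].
#' @export
write_stimuli <- function(stimuli, dir) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(stimuli$item_ids, file.path(dir, "ids.txt"))
  if (!is.null(stimuli$features))
    utils::write.table(stimuli$features, file.path(dir, "features.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(stimuli$category_tags))
    utils::write.table(
      data.frame(id = stimuli$item_ids, tag = stimuli$category_tags),
      file.path(dir, "tags.tsv"),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(dir) {
  ids <- readLines(file.path(dir, "ids.txt"))
  feats <- NULL
  fpath <- file.path(dir, "features.tsv")
  if (file.exists(fpath)) {
    feats <- as.matrix(utils::read.table(fpath, sep = "\t"))
    dimnames(feats) <- NULL
  }
  tags <- NULL
  tpath <- file.path(dir, "tags.tsv")
  if (file.exists(tpath)) {
    tt <- utils::read.table(tpath, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("id", "tag"))
    tags <- tt$tag[match(ids, tt$id)]
  }
  stimulus_set(ids, features = feats, category_tags = tags)
}
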