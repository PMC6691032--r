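# Pairwise similarity matrices ------------------------------------------------

#' Pairwise similarity from item features
#'
#' Computes the symmetric similarity matrix S that feeds the b-matching
#' step. Distance-based metrics are negated (larger = more similar) so that
#' maximizing total edge similarity prefers near pairs; any strictly
#' decreasing transform of distance yields the same matching on distinct
#' weights, so negation is the minimal choice.
#'
#' Metrics: `neg_euclidean` and `neg_l1` use the item feature vectors;
#' `histogram_l1` treats each feature row as a histogram (normalized
#' internally) and uses negated L1 distance between histograms.
#'
#' @param stimuli A [stimulus_set()] with features for every item.
#' @param metric One of `"neg_euclidean"`, `"neg_l1"`, `"histogram_l1"`.
#' @return Symmetric numeric matrix with item ids as dimnames; diagonal 0.
#' @export
pairwise_similarity <- function(stimuli,
                                metric = c("neg_euclidean", "neg_l1",
                                           "histogram_l1")) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  metric <- match.arg(metric)
  X <- stimuli$features
  if (is.null(X))
    stop("pairwise_similarity needs item features")
  bad <- which(apply(X, 1L, function(r) anyNA(r) | any(!is.finite(r))))
  if (length(bad))
    stop("missing or non-finite features for item(s): ",
         paste(stimuli$item_ids[bad], collapse = ", "))
  if (metric == "histogram_l1") {
    rs <- rowSums(X)
    if (any(rs <= 0))
      stop("histogram_l1 needs nonnegative rows with positive sums; item(s): ",
           paste(stimuli$item_ids[rs <= 0], collapse = ", "))
    X <- X / rs
  }
  D <- switch(metric,
    neg_euclidean = as.matrix(stats::dist(X, method = "euclidean")),
    neg_l1        = as.matrix(stats::dist(X, method = "manhattan")),
    histogram_l1  = as.matrix(stats::dist(X, method = "manhattan"))
  )
  S <- -D
  dimnames(S) <- list(stimuli$item_ids, stimuli$item_ids)
  S
}

#' Combine similarity matrices from different descriptors
#'
#' Each input's off-diagonal entries are scaled to unit variance, then the
#' matrices are summed entrywise, so descriptors on different scales (say a
#' color-histogram similarity and a local-feature similarity) contribute
#' comparably. The diagonal is set to 0 — consumers ignore it.
#'
#' @param matrices List of symmetric matrices of identical shape and item
#'   ordering.
#' @return Symmetric combined matrix.
#' @export
combine_similarities <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need a nonempty list of matrices")
  n <- nrow(as.matrix(matrices[[1L]]))
  out <- matrix(0, n, n)
  for (k in seq_along(matrices)) {
    M <- as.matrix(matrices[[k]])
    if (!all(dim(M) == c(n, n)))
      stop("matrix ", k, " has a different shape")
    check_symmetric(M, paste0("matrix ", k))
    off <- M[upper.tri(M)]
    s <- stats::sd(off)
    if (!is.finite(s) || s == 0)
      stop("matrix ", k, " has zero off-diagonal variance; cannot normalize")
    out <- out + M / s
  }
  diag(out) <- 0
  dimnames(out) <- dimnames(as.matrix(matrices[[1L]]))
  out
}

# The 11 basic color anchors (RGB in 0..255). Fixed, documented constants:
# nearest-prototype assignment in RGB is a stated simplification of
# published basic-color-histogram boundaries.
basic_colors <- function() {
  rbind(
    black  = c(0, 0, 0),
    white  = c(255, 255, 255),
    gray   = c(128, 128, 128),
    red    = c(255, 0, 0),
    orange = c(255, 165, 0),
    yellow = c(255, 255, 0),
    green  = c(0, 128, 0),
    blue   = c(0, 0, 255),
    purple = c(128, 0, 128),
    pink   = c(255, 192, 203),
    brown  = c(139, 69, 19)
  )
}

#' Basic color histogram of an RGB raster
#'
#' Assigns every pixel to the nearest of 11 basic colors (black, white,
#' gray, red, orange, yellow, green, blue, purple, pink, brown) by Euclidean
#' distance in RGB space and counts per bin. Color histograms are one of the
#' stock similarity descriptors for image stimulus sets.
#'
#' @param pixels RGB raster: an `n x 3` matrix of pixels, or an
#'   `h x w x 3` array; values in \[0, 255\].
#' @param normalize If `TRUE`, counts are divided by the pixel count.
#' @return Named numeric vector of length 11 (class `color_histogram`), with
#'   attribute `normalized`.
#' @export
color_histogram <- function(pixels, normalize = FALSE) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    stopifnot(dim(pixels)[3L] == 3L)
    pixels <- matrix(pixels, ncol = 3L)
  }
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty raster")
  if (ncol(pixels) != 3L) stop("pixels must be RGB triples")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  proto <- basic_colors()
  # squared Euclidean distance pixel -> each prototype
  d2 <- outer(rowSums(pixels^2), rowSums(proto^2), "+") -
    2 * pixels %*% t(proto)
  bin <- max.col(-d2, ties.method = "first")
  counts <- tabulate(bin, nbins = nrow(proto))
  names(counts) <- rownames(proto)
  if (normalize) counts <- counts / nrow(pixels)
  structure(as.numeric(counts), names = names(counts),
            normalized = normalize, class = "color_histogram")
}

#' Count unordered item pairs covered by all-pairs similarity
#'
#' The number of distinct pairs an all-pairs similarity computation covers:
#' `n (n - 1) / 2`.
#'
#' @param n Item count.
#' @return Number of unordered pairs.
#' @export
n_unordered_pairs <- function(n) {
  stopifnot(n >= 0)
  choose(n, 2)
}

# Serialization: delimited numeric text with a header row of item ids.

#' Write / read a similarity matrix as delimited text
#'
#' The file is tab-separated with a header row of item ids. On read, strict
#' symmetry is validated to 1e-9; `symmetrize = TRUE` instead averages
#' `(S + t(S)) / 2` and warns.
#'
#' @param S Symmetric similarity matrix with item-id dimnames.
#' @param path File path.
#' @param symmetrize Repair mild asymmetry on read by averaging (with a
#'   warning) instead of erroring.
#' @return `write_similarity` returns `path` invisibly; `read_similarity`
#'   returns the matrix.
#' @export
write_similarity <- function(S, path) {
  S <- as.matrix(S)
  check_symmetric(S, "S")
  if (is.null(colnames(S)))
    colnames(S) <- rownames(S) <- paste0("item", seq_len(nrow(S)))
  utils::write.table(S, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path, symmetrize = FALSE) {
  S <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(S) <- colnames(S)
  asym <- max(abs(S - t(S)))
  if (asym > 1e-9) {
    if (!symmetrize)
      stop("matrix in ", path, " is asymmetric (max |S - t(S)| = ",
           format(asym), "); use symmetrize = TRUE to average")
    warning("symmetrizing ", path, " by averaging (max asymmetry ",
            format(asym), ")")
    S <- (S + t(S)) / 2
  }
  S
}
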