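# Random-walk proposal distributions on the graph -----------------------------

#' Specify a proposal distribution
#'
#' Proposals q(x'; x) are random walks on the proposal graph, mixed with a
#' small uniform jump over all items. `uniform_neighbor` proposes one of the
#' current node's neighbors uniformly; `geometric_walk` first draws a step
#' count from a geometric distribution on \{1, 2, ...\} with success
#' probability `geom_param`, walks that many uniform-neighbor steps, and
#' proposes the endpoint (which widens exploration and may return to the
#' start). The jump branch is drawn first: with probability `jump_prob` the
#' proposal is uniform over all items, guaranteeing irreducibility and
#' aperiodicity and allowing escape from local modes.
#'
#' @param kind `"uniform_neighbor"` or `"geometric_walk"`.
#' @param geom_param Success probability in (0, 1\] of the geometric
#'   step-count distribution (`geometric_walk` only; 1 degenerates to a
#'   single step).
#' @param jump_prob Uniform-jump probability in \[0, 1\] (default 0.1).
#' @return Object of class `proposal_spec`.
#' @export
proposal_spec <- function(kind = c("uniform_neighbor", "geometric_walk"),
                          geom_param = 0.5, jump_prob = 0.1) {
  kind <- match.arg(kind)
  if (jump_prob < 0 || jump_prob > 1) stop("jump_prob must be in [0, 1]")
  if (kind == "geometric_walk" &&
      (geom_param <= 0 || geom_param > 1))
    stop("geom_param must be in (0, 1]")
  structure(list(kind = kind, geom_param = geom_param,
                 jump_prob = jump_prob),
            class = "proposal_spec")
}

#' @export
print.proposal_spec <- function(x, ...) {
  cat("<proposal_spec> ", x$kind,
      if (x$kind == "geometric_walk")
        sprintf(" (geom_param = %g)", x$geom_param),
      sprintf(", jump_prob = %g\n", x$jump_prob), sep = "")
  invisible(x)
}

neighbors_of <- function(G, x_idx) which(G$adjacency[x_idx, ] == 1L)

#' Draw a uniform-neighbor proposal
#'
#' Returns one of `x`'s neighbors, each with probability 1/deg(x). Consumes
#' the ambient RNG stream (seed the session, not the trial).
#'
#' @param G A [proposal_graph()].
#' @param x Current item id.
#' @return Proposed item id.
#' @export
uniform_neighbor_proposal <- function(G, x) {
  xi <- match(x, G$item_ids)
  if (is.na(xi)) stop("unknown item: ", x)
  nb <- neighbors_of(G, xi)
  if (!length(nb))
    stop("item ", x, " is isolated; validate the graph before running")
  G$item_ids[nb[sample.int(length(nb), 1L)]]
}

#' Draw a geometric-walk proposal
#'
#' Draws a step count k from Geometric(`geom_param`) on \{1, 2, ...\},
#' performs k uniform-neighbor steps and returns the endpoint, which may be
#' `x` itself.
#'
#' @inheritParams uniform_neighbor_proposal
#' @param geom_param Success probability of the step-count distribution.
#' @return Proposed item id.
#' @export
geometric_walk_proposal <- function(G, x, geom_param = 0.5) {
  k <- stats::rgeom(1L, geom_param) + 1L   # support {1, 2, ...}
  cur <- x
  for (step in seq_len(k)) cur <- uniform_neighbor_proposal(G, cur)
  cur
}

#' Draw a proposal under a full proposal spec
#'
#' Draws the jump branch first: with probability `jump_prob`, a uniform
#' draw over all items (possibly `x` itself); otherwise the configured
#' base walk from `x`.
#'
#' @param G A [proposal_graph()].
#' @param spec A [proposal_spec()].
#' @param x Current item id.
#' @return Proposed item id.
#' @export
mixture_proposal <- function(G, spec, x) {
  stopifnot(inherits(spec, "proposal_spec"))
  n <- length(G$item_ids)
  if (n < 2L) stop("need at least 2 items")
  if (spec$jump_prob > 0 && stats::runif(1L) < spec$jump_prob)
    return(G$item_ids[sample.int(n, 1L)])
  if (spec$kind == "uniform_neighbor") uniform_neighbor_proposal(G, x)
  else geometric_walk_proposal(G, x, spec$geom_param)
}

#' Exact proposal transition matrix
#'
#' Enumerates Q\[x, x'\] under a proposal spec, for checking the symmetry
#' the Barker/Metropolis correspondence requires. For the geometric walk the
#' series over step counts is truncated: Q_base = sum_k p (1-p)^(k-1) P^k up
#' to `truncation` steps, leaving untracked mass (1-p)^truncation (reported,
#' and flagged when above 1e-6). The jump mixes in epsilon/n everywhere.
#'
#' @param G A [proposal_graph()] (all nodes must have neighbors).
#' @param spec A [proposal_spec()].
#' @param truncation Maximum walk length enumerated (geometric walk only).
#' @param n_max Enumeration cap on item count (default 100).
#' @return Matrix of class `proposal_matrix` with attributes
#'   `truncation_mass` (geometric mass beyond the truncation) and
#'   `truncated` flag (TRUE when that mass exceeds 1e-6).
#' @export
proposal_distribution <- function(G, spec, truncation = 100L, n_max = 100L) {
  stopifnot(inherits(G, "proposal_graph"), inherits(spec, "proposal_spec"))
  n <- length(G$item_ids)
  if (n > n_max)
    stop("n = ", n, " exceeds the enumeration cap (", n_max, ")")
  deg <- rowSums(G$adjacency)
  if (any(deg == 0)) stop("graph has isolated nodes")
  P <- G$adjacency / deg                  # one-step walk matrix
  if (spec$kind == "uniform_neighbor") {
    Qbase <- P
    rem <- 0
  } else {
    p <- spec$geom_param
    Qbase <- matrix(0, n, n)
    Pk <- diag(n)
    for (k in seq_len(truncation)) {
      Pk <- Pk %*% P
      Qbase <- Qbase + p * (1 - p)^(k - 1L) * Pk
    }
    rem <- (1 - p)^truncation
  }
  eps <- spec$jump_prob
  Q <- (1 - eps) * Qbase + eps / n
  dimnames(Q) <- list(G$item_ids, G$item_ids)
  structure(Q, truncation_mass = rem, truncated = rem > 1e-6,
            class = c("proposal_matrix", "matrix"))
}
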