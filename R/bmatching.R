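# Degree-constrained proposal graphs via maximum-weight b-matching ------------

#' Construct a proposal graph
#'
#' A proposal graph is the support of the random-walk proposal: an
#' undirected simple graph over the items, ideally b-regular so that
#' uniform-neighbor proposals are symmetric.
#'
#' @param adjacency Binary symmetric matrix with zero diagonal.
#' @param b Target degree the graph was built for.
#' @param item_ids Item ordering; defaults to adjacency dimnames.
#' @param converged For approximate solvers, whether message passing
#'   converged; `NA` for constructions with no iteration.
#' @param method Label of the construction method.
#' @return Object of class `proposal_graph` with fields `adjacency`, `b`,
#'   `item_ids`, `degree_report` (min/mean/max observed degree),
#'   `converged`, `method`.
#' @export
proposal_graph <- function(adjacency, b, item_ids = NULL,
                           converged = NA, method = "manual") {
  A <- as.matrix(adjacency)
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  check_symmetric(A, "adjacency", tol = 0)
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  storage.mode(A) <- "integer"
  if (is.null(item_ids)) item_ids <- rownames(A)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(nrow(A)))
  item_ids <- as.character(item_ids)
  stopifnot(length(item_ids) == nrow(A))
  dimnames(A) <- list(item_ids, item_ids)
  deg <- rowSums(A)
  structure(
    list(adjacency = A, b = as.integer(b), item_ids = item_ids,
         degree_report = c(min = min(deg), mean = mean(deg), max = max(deg)),
         converged = converged, method = method),
    class = "proposal_graph"
  )
}

#' @export
print.proposal_graph <- function(x, ...) {
  n <- length(x$item_ids)
  dr <- x$degree_report
  cat("<proposal_graph> ", n, " nodes, ", sum(x$adjacency) / 2L,
      " edges (b = ", x$b, ", method = ", x$method, ")\n", sep = "")
  cat(sprintf("  degree min/mean/max: %d / %.2f / %d\n",
              as.integer(dr["min"]), dr["mean"], as.integer(dr["max"])))
  if (!is.na(x$converged))
    cat("  converged:", x$converged, "\n")
  invisible(x)
}

# BFS 2-coloring; bipartite iff no edge joins same-colored nodes. A
# connected non-bipartite graph has an odd cycle, hence an aperiodic walk.
is_bipartite_adj <- function(A) {
  n <- nrow(A)
  color <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    if (!is.na(color[s])) next
    color[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] != 0L)
      clash <- nb[!is.na(color[nb]) & color[nb] == color[v]]
      if (length(clash)) return(FALSE)
      fresh <- nb[is.na(color[nb])]
      color[fresh] <- 1L - color[v]
      queue <- c(queue, fresh)
    }
  }
  TRUE
}

as_igraph <- function(G) {
  igraph::graph_from_adjacency_matrix(G$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Exact maximum-weight b-matching by branch and bound
#'
#' Finds, among all simple b-regular graphs on the items, one maximizing the
#' total similarity over edges. Depth-first search over edges in
#' lexicographic order with degree-feasibility pruning and an optimistic
#' weight bound; exploring the include-branch first and replacing the
#' incumbent only on strict improvement makes the returned optimum the
#' lexicographically smallest optimal edge set. Intended as a small-instance
#' solver and test oracle — exact b-matching does not scale, which is why a
#' message-passing solver exists.
#'
#' @param S Symmetric similarity matrix (diagonal ignored).
#' @param b Required degree, `1 <= b <= n - 1`; `n * b` must be even.
#' @param n_max Small-instance cap (default 12).
#' @return A [proposal_graph()] that is exactly b-regular.
#' @export
bmatch_exact <- function(S, b, n_max = 12L) {
  S <- as.matrix(S)
  check_symmetric(S, "S")
  n <- nrow(S)
  if (n > n_max)
    stop("n = ", n, " exceeds the exact-solver cap (", n_max,
         "); use bmatch_message_passing()")
  if (b < 1L || b > n - 1L) stop("need 1 <= b <= n - 1")
  if ((n * b) %% 2L != 0L)
    stop("infeasible: a b-regular graph on n nodes needs n * b even")

  pairs <- which(upper.tri(S), arr.ind = TRUE)
  ord <- order(pairs[, 1L], pairs[, 2L])   # lexicographic edge order
  pairs <- pairs[ord, , drop = FALSE]
  w <- S[pairs]
  m <- nrow(pairs)
  # per-node suffix tables: topk[[i]][e, k] is the sum of the k largest
  # weights among edges incident to i with index >= e. Gives both the
  # feasibility check (need_i edges must remain) and the optimistic bound
  # value + (1/2) sum_i topk[[i]][e, need_i].
  touch <- matrix(0L, m + 1L, n)
  topk <- vector("list", n)
  for (i in seq_len(n)) {
    inc <- which(pairs[, 1L] == i | pairs[, 2L] == i)
    tk <- matrix(-Inf, m + 1L, b)
    cur <- numeric(0)
    for (e in m:1) {
      if (any(inc == e)) cur <- sort(c(cur, w[e]), decreasing = TRUE)
      kk <- min(b, length(cur))
      if (kk > 0L) tk[e, seq_len(kk)] <- cumsum(cur[seq_len(kk)])
      touch[e, i] <- length(cur)
    }
    topk[[i]] <- tk
  }

  deg <- integer(n)
  chosen <- logical(m)
  best <- list(value = -Inf, edges = NULL)

  recurse <- function(e, value) {
    if (e > m) {
      if (all(deg == b) && value > best$value)
        best <<- list(value = value, edges = which(chosen))
      return(invisible(NULL))
    }
    need <- b - deg
    if (any(need > touch[e, ])) return(invisible(NULL))
    if (best$value > -Inf) {
      bnd <- 0
      for (i in seq_len(n))
        if (need[i] > 0L) bnd <- bnd + topk[[i]][e, need[i]]
      if (value + bnd / 2 <= best$value) return(invisible(NULL))
    }
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    if (deg[i] < b && deg[j] < b) {       # include branch first
      deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
      chosen[e] <<- TRUE
      recurse(e + 1L, value + w[e])
      chosen[e] <<- FALSE
      deg[i] <<- deg[i] - 1L; deg[j] <<- deg[j] - 1L
    }
    recurse(e + 1L, value)                # exclude branch
    invisible(NULL)
  }
  recurse(1L, 0)
  if (is.null(best$edges) && best$value == -Inf && !(n == 0L))
    stop("no b-regular graph found (should not happen for feasible n, b)")

  A <- matrix(0L, n, n)
  for (e in best$edges) {
    A[pairs[e, 1L], pairs[e, 2L]] <- 1L
    A[pairs[e, 2L], pairs[e, 1L]] <- 1L
  }
  proposal_graph(A, b, item_ids = rownames(S), method = "exact")
}

#' Approximate maximum-weight b-matching by max-product message passing
#'
#' Synchronous max-product belief updates on the complete graph of items:
#' each message is the edge weight minus the b-th best competing offer at
#' the sender, iterated with damping. At convergence every node selects its
#' b best partners by belief and mutual selections become edges, so the
#' output can be mildly degree-irregular — the attached degree report
#' records the observed min/mean/max, and the proposal module walks the
#' actual neighbor sets.
#'
#' Ties in the weights are broken by a seeded jitter of magnitude 1e-12
#' added to the weights before iterating.
#'
#' @param S Symmetric similarity matrix (diagonal ignored).
#' @param b Target degree, `1 <= b <= n - 1`.
#' @param max_iters Iteration cap.
#' @param damping In `[0, 1)`: weight on the previous message (default 0.5).
#' @param tol Max-change threshold declaring convergence.
#' @param seed Seed for the tie-breaking jitter.
#' @return A [proposal_graph()] with `converged` set accordingly.
#' @export
bmatch_message_passing <- function(S, b, max_iters = 500L, damping = 0.5,
                                   tol = 1e-10, seed = 1L) {
  S <- as.matrix(S)
  check_symmetric(S, "S")
  n <- nrow(S)
  if (b < 1L || b > n - 1L) stop("need 1 <= b <= n - 1")
  if (damping < 0 || damping >= 1) stop("damping must be in [0, 1)")
  W <- S + with_seed(seed, {
    J <- matrix(stats::runif(n * n, -1, 1), n, n)
    (J + t(J)) * 0.5e-12
  })
  diag(W) <- -Inf                        # no self-edges
  M <- matrix(0, n, n)                   # M[i, j]: message i -> j

  kth_largest_excl <- function(v, k) {
    # for each j: k-th largest of v[-j]; computed from the top k + 1 values
    top <- sort(v, decreasing = TRUE)[seq_len(min(k + 1L, length(v)))]
    thr_in <- top[k]                     # if v[j] not among top k
    thr_out <- top[k + 1L]               # if v[j] among top k
    ifelse(v >= thr_in, thr_out, thr_in)
  }

  extract <- function(M) {
    offers <- W + t(M)
    A <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      sel <- order(offers[i, ], decreasing = TRUE)[seq_len(b)]
      A[i, sel] <- 1L
    }
    A <- A * t(A)                        # mutual selections only
    diag(A) <- 0L
    A
  }

  # converged when messages settle below tol, or when the extracted edge
  # set has been stable across several successive checks (messages can
  # keep drifting by tiny amounts long after the selection has locked in)
  converged <- FALSE
  check_every <- 10L
  stable_needed <- 3L
  stable <- 0L
  A_prev <- NULL
  for (it in seq_len(max_iters)) {
    offers <- W + t(M)                   # offers[i, k] = W[i,k] + M[k -> i]
    Mnew <- matrix(0, n, n)
    for (i in seq_len(n))
      Mnew[i, ] <- W[i, ] - kth_largest_excl(offers[i, ], b)
    Mnew[!is.finite(Mnew)] <- 0          # diagonal bookkeeping only
    diag(Mnew) <- 0
    Mnew <- damping * M + (1 - damping) * Mnew
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
    if (it %% check_every == 0L) {
      A_now <- extract(M)
      if (!is.null(A_prev) && identical(A_now, A_prev)) {
        stable <- stable + 1L
        if (stable >= stable_needed) { converged <- TRUE; break }
      } else stable <- 0L
      A_prev <- A_now
    }
  }

  A <- extract(M)
  proposal_graph(A, b, item_ids = rownames(S),
                 converged = converged, method = "message_passing")
}

#' Largest connected component of a proposal graph
#'
#' A maximal b-matching need not be connected; chains are run on the largest
#' connected component. Ties between equal-sized components go to the one
#' containing the smallest original item index. The mapping back to the
#' original items is retained as attribute `original_index`.
#'
#' @param G A [proposal_graph()].
#' @return A [proposal_graph()] induced on the largest component.
#' @export
largest_connected_component <- function(G) {
  stopifnot(inherits(G, "proposal_graph"))
  comp <- igraph::components(as_igraph(G))
  if (comp$no == 1L) return(G)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    first_idx <- vapply(cand, function(k)
      min(which(comp$membership == k)), integer(1))
    cand <- cand[which.min(first_idx)]
  }
  keep <- unname(which(comp$membership == cand[1L]))
  out <- proposal_graph(G$adjacency[keep, keep, drop = FALSE], G$b,
                        item_ids = G$item_ids[keep],
                        converged = G$converged, method = G$method)
  attr(out, "original_index") <- keep
  out
}

#' Validate a proposal graph for use as MCMC proposal support
#'
#' Checks the structural conditions convergence rests on: symmetry, zero
#' diagonal, connectivity, degree regularity, and aperiodicity of the
#' effective chain. With a positive uniform-jump probability the proposal
#' support is all items, so the chain is irreducible and aperiodic
#' regardless of graph quality; without it, aperiodicity holds iff the graph
#' is non-bipartite.
#'
#' @param G A [proposal_graph()].
#' @param jump_prob Uniform-jump probability the graph will be used with.
#' @return A list of class `graph_validation` with logical flags
#'   `symmetric`, `zero_diagonal`, `connected`, `regular`, `aperiodic`,
#'   plus `degree_range`, `component_sizes`, and `asymmetric_pairs` /
#'   `loop_nodes` when violations exist.
#' @export
validate_graph <- function(G, jump_prob = 0.1) {
  stopifnot(inherits(G, "proposal_graph"))
  A <- G$adjacency
  asym <- which(A != t(A), arr.ind = TRUE)
  loops <- which(diag(A) != 0)
  comp <- igraph::components(as_igraph(G))
  deg <- rowSums(A)
  bip <- is_bipartite_adj(A)
  res <- list(
    symmetric = nrow(asym) == 0L,
    zero_diagonal = length(loops) == 0L,
    connected = comp$no == 1L,
    regular = length(unique(deg)) == 1L,
    degree_range = range(deg),
    component_sizes = sort(comp$csize, decreasing = TRUE),
    aperiodic = jump_prob > 0 || !bip,
    jump_prob = jump_prob
  )
  if (nrow(asym) > 0L)
    res$asymmetric_pairs <- asym[asym[, 1L] < asym[, 2L], , drop = FALSE]
  if (length(loops)) res$loop_nodes <- G$item_ids[loops]
  class(res) <- "graph_validation"
  res
}

#' @export
print.graph_validation <- function(x, ...) {
  mark <- function(ok) if (isTRUE(ok)) "ok" else "FAIL"
  cat("<graph_validation>\n")
  cat("  symmetric:     ", mark(x$symmetric), "\n")
  cat("  zero diagonal: ", mark(x$zero_diagonal), "\n")
  cat("  connected:     ", mark(x$connected),
      if (!x$connected) paste0("  components: ",
                               paste(x$component_sizes, collapse = ", ")),
      "\n")
  cat("  regular:       ", mark(x$regular), "  degrees in [",
      x$degree_range[1L], ", ", x$degree_range[2L], "]\n", sep = "")
  cat("  aperiodic:     ", mark(x$aperiodic),
      sprintf("  (jump_prob = %g)\n", x$jump_prob))
  invisible(x)
}

#' Deterministic b-regular ring lattice
#'
#' The circulant graph connecting each item to its `b/2` nearest neighbors
#' on either side of a ring (item order as given). A deterministic,
#' connected, exactly b-regular graph — the standard baseline proposal
#' support for simulation studies; when items are ordered by a 1-d feature,
#' it is the similarity-optimal b-regular graph on that line.
#'
#' @param n Number of items, or a [stimulus_set()] (items ordered by their
#'   first feature coordinate when features exist).
#' @param b Even degree with `b <= n - 2`.
#' @return A [proposal_graph()].
#' @export
ring_graph <- function(n, b) {
  ids <- NULL
  if (inherits(n, "stimulus_set")) {
    stim <- n
    ids <- stim$item_ids
    if (!is.null(stim$features)) ids <- ids[order(stim$features[, 1L])]
    n <- length(ids)
  }
  n <- as.integer(n)
  b <- as.integer(b)
  if (b %% 2L != 0L) stop("ring_graph needs an even b")
  if (b > n - 2L) stop("need b <= n - 2")
  A <- matrix(0L, n, n)
  for (k in seq_len(b / 2L)) {
    idx <- cbind(seq_len(n), ((seq_len(n) - 1L + k) %% n) + 1L)
    A[idx] <- 1L
    A[idx[, 2:1]] <- 1L
  }
  proposal_graph(A, b, item_ids = ids, method = "ring")
}

# Serialization: one-line header "n <TAB> b", then one "id_i <TAB> id_j"
# per undirected edge with i < j in item order.

#' Write / read a proposal graph as an edge list
#'
#' @param G A [proposal_graph()].
#' @param path File path.
#' @return `write_graph_file` returns `path` invisibly; `read_graph_file`
#'   returns a validated [proposal_graph()].
#' @export
write_graph_file <- function(G, path) {
  stopifnot(inherits(G, "proposal_graph"))
  idx <- which(G$adjacency == 1L & upper.tri(G$adjacency), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(G$item_ids), G$b, sep = "\t"), con)
  if (nrow(idx))
    writeLines(paste(G$item_ids[idx[, 1L]], G$item_ids[idx[, 2L]],
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty graph file: ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != 2L) stop("bad graph header in ", path)
  n <- as.integer(hdr[1L]); b <- as.integer(hdr[2L])
  edges <- if (length(lines) > 1L)
    do.call(rbind, strsplit(lines[-1L], "\t", fixed = TRUE)) else
    matrix(character(), 0L, 2L)
  ids <- unique(c(t(edges)))
  if (length(ids) > n) stop("edge list names more than n items in ", path)
  if (length(ids) < n)
    ids <- c(ids, setdiff(paste0("item", seq_len(n)), ids))[seq_len(n)]
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    A[edges] <- 1L
    A[edges[, 2:1, drop = FALSE]] <- 1L
  }
  proposal_graph(A, b, item_ids = ids, method = "file")
}
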