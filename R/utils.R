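# Internal helpers ------------------------------------------------------------

# Evaluate expr under a local RNG seed, restoring the caller's stream after.
# NULL seed means: consume the ambient stream (used by per-trial internals).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Evaluate expr on a private RNG stream kept in env$state (initialized from
# seed on first use), restoring the ambient stream afterwards. Lets a
# stochastic component own its randomness so the engine's stream is
# unaffected by how (or whether) the component draws.
private_draw <- function(env, seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(env$state)) set.seed(seed)
  else assign(".Random.seed", env$state, envir = globalenv())
  val <- expr
  env$state <- get(".Random.seed", envir = globalenv())
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  val
}

check_symmetric <- function(M, name = "matrix", tol = 1e-9) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(name, " must be a square matrix")
  if (max(abs(M - t(M))) > tol)
    stop(name, " must be symmetric (tolerance ", tol, ")")
  invisible(TRUE)
}

# Total variation distance between two probability vectors on the same
# support ordering: half the L1 distance.
#' Total variation distance
#'
#' Half the L1 distance between two probability vectors over the same item
#' ordering — the convergence metric used by the recovery diagnostics.
#'
#' @param p,q Numeric probability vectors of equal length (or
#'   `target_distribution` / `empirical_distribution` objects; named entries
#'   are aligned by name).
#' @return Scalar in \[0, 1\].
#' @export
total_variation <- function(p, q) {
  p <- as_prob_vector(p)
  q <- as_prob_vector(q)
  if (!is.null(names(p)) && !is.null(names(q))) {
    ids <- union(names(p), names(q))
    p <- ifelse(is.na(match(ids, names(p))), 0, p[match(ids, names(p))])
    q <- ifelse(is.na(match(ids, names(q))), 0, q[match(ids, names(q))])
  }
  if (length(p) != length(q)) stop("p and q must cover the same items")
  0.5 * sum(abs(p - q))
}

as_prob_vector <- function(x) {
  if (inherits(x, "target_distribution")) return(x$probs)
  if (inherits(x, "empirical_distribution")) return(x$frequencies)
  stopifnot(is.numeric(x))
  x
}
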