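# Plain-text formats: trial logs and session configs --------------------------

log_columns <- c("participant_id", "session_index", "trial_index",
                 "trial_type", "chain_id", "category", "current_id",
                 "proposal_id", "left_id", "right_id", "chosen_id",
                 "correct_id")

validate_log <- function(log, where = "log") {
  miss <- setdiff(log_columns, names(log))
  if (length(miss))
    stop(where, " is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(log$chosen_id != log$left_id & log$chosen_id != log$right_id)
  if (length(bad))
    stop(where, ": chosen_id not among offered ids at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!(paste(pmin(log$left_id, log$right_id),
                       pmax(log$left_id, log$right_id)) ==
                 paste(pmin(log$current_id, log$proposal_id),
                       pmax(log$current_id, log$proposal_id))))
  if (length(bad))
    stop(where, ": {left,right} != {current,proposal} at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  for (pid in unique(log$participant_id)) {
    ti <- log$trial_index[log$participant_id == pid]
    if (any(diff(ti) <= 0))
      stop(where, ": trial_index not strictly increasing for participant ",
           pid)
  }
  invisible(TRUE)
}

#' Write / read a trial log
#'
#' Tab-separated, UTF-8, Unix newlines, one header line then one record per
#' trial in presentation order. `read_log(write_log(log))` reproduces the
#' log field-for-field; invariants (chosen among offered, left/right pair
#' equals current/proposal pair, strictly increasing trial index per
#' participant) are validated on both ends.
#'
#' @param log A `dmcmcp_log` data frame.
#' @param path File path.
#' @return `write_log` returns `path` invisibly; `read_log` returns the
#'   validated `dmcmcp_log`.
#' @export
write_log <- function(log, path) {
  validate_log(log, "log")
  utils::write.table(as.data.frame(log)[, log_columns], path, sep = "\t",
                     row.names = FALSE, col.names = TRUE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  log <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c(participant_id = "character",
                                     session_index = "integer",
                                     trial_index = "integer",
                                     trial_type = "character",
                                     chain_id = "character",
                                     category = "character",
                                     current_id = "character",
                                     proposal_id = "character",
                                     left_id = "character",
                                     right_id = "character",
                                     chosen_id = "character",
                                     correct_id = "character"),
                      na.strings = character(0), quote = "",
                      fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse trial log ", path, ": ",
                             conditionMessage(e)))
  log$correct_id[is.na(log$correct_id)] <- ""
  log$chain_id[is.na(log$chain_id)] <- ""
  validate_log(log, path)
  class(log) <- c("dmcmcp_log", "data.frame")
  log
}

#' Write / read a session configuration
#'
#' Flat `key=value` text with dotted namespaces (e.g.
#' `proposal.jump_prob=0.1`) — diffable, greppable, and easy to audit.
#' Categories are comma-separated.
#'
#' @param config A [session_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [session_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  lines <- c(
    paste0("categories=", paste(config$categories, collapse = ",")),
    paste0("chains_per_category=",
           nrow(config$chains) / length(config$categories)),
    paste0("trials_per_chain=", config$trials_per_chain),
    paste0("n_practice=", config$n_practice),
    paste0("n_catch=", config$n_catch),
    paste0("catch_pass_threshold=", config$catch_pass_threshold),
    paste0("proposal.kind=", config$proposal$kind),
    paste0("proposal.geom_param=", config$proposal$geom_param),
    paste0("proposal.jump_prob=", config$proposal$jump_prob),
    paste0("seed=", config$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed config line ", bad[1L], " in ", path, ": ",
         lines[bad[1L]])
  vals <- stats::setNames(vapply(kv, `[`, "", 2L),
                          trimws(vapply(kv, `[`, "", 1L)))
  need <- function(key) {
    if (is.na(match(key, names(vals))))
      stop("config ", path, " is missing key: ", key)
    trimws(vals[[key]])
  }
  opt <- function(key, default)
    if (is.na(match(key, names(vals)))) default else trimws(vals[[key]])
  session_config(
    categories = strsplit(need("categories"), ",", fixed = TRUE)[[1L]],
    chains_per_category = as.integer(need("chains_per_category")),
    trials_per_chain = as.integer(need("trials_per_chain")),
    n_practice = as.integer(opt("n_practice", "12")),
    n_catch = as.integer(opt("n_catch", "40")),
    catch_pass_threshold = as.integer(opt("catch_pass_threshold", "27")),
    proposal = proposal_spec(
      kind = opt("proposal.kind", "uniform_neighbor"),
      geom_param = as.numeric(opt("proposal.geom_param", "0.5")),
      jump_prob = as.numeric(opt("proposal.jump_prob", "0.1"))
    ),
    seed = as.integer(opt("seed", "1"))
  )
}

#' Write / read a target distribution
#'
#' Two-column tab-separated text: item id, probability. Probabilities are
#' renormalized on read.
#'
#' @param target A [target_distribution()].
#' @param path File path.
#' @param gamma Exponent attached on read (default 1).
#' @return `write_target` returns `path` invisibly; `read_target` returns a
#'   [target_distribution()].
#' @export
write_target <- function(target, path) {
  stopifnot(inherits(target, "target_distribution"))
  utils::write.table(
    data.frame(item_id = target$item_ids, prob = unname(target$probs)),
    path, sep = "\t", row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_target
#' @export
read_target <- function(path, gamma = 1) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "numeric"))
  target_distribution(d$item_id, d$prob, gamma = gamma)
}
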