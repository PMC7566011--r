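#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules: seeded RNG scoping, seed fan-out,
# stratified fold construction and lightweight logging.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' package functions never clobber the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Fans a single master seed out to independent per-stage seeds by hashing
#' the stage name, so that adding a stage never shifts the draws of another.
#'
#' @param seed master seed (integer).
#' @param stage character tag naming the consumer.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% (2^31 - 2) + 1)
}

# Stratified fold assignment: each class is split as evenly as possible
# across `k` folds. When `groups` is given (e.g., sample identifiers of a
# bootstrap draw), all replicates of a group land in the same fold, so a
# duplicated sample can never sit in both the training and validation part
# of a fold. Returns an integer fold id per observation.
stratified_folds <- function(labels, k, seed = NULL, groups = NULL) {
  labels <- as.character(labels)
  if (is.null(groups)) groups <- seq_along(labels)
  u <- !duplicated(groups)
  u_groups <- groups[u]
  u_labels <- labels[u]
  if (any(table(u_labels) < k)) {
    stop("cannot build ", k, " stratified folds: a class has fewer than ",
         k, " distinct samples", call. = FALSE)
  }
  run <- function() {
    fold_of <- integer(length(u_groups))
    for (cl in unique(u_labels)) {
      idx <- which(u_labels == cl)
      fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold_of[match(groups, u_groups)]
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Minimal leveled logger; silenced via options(treeDEG.verbose = FALSE).
td_log <- function(..., level = "INFO") {
  if (isFALSE(getOption("treeDEG.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[treeDEG %s] %s", level, paste0(...)))
}

# Fraction-in-[0,1] check used by several validators.
is_prob <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)
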