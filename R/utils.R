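# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All package randomness funnels through this so that
# experiments are pure functions of (inputs, seeds).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive named sub-seeds from a master seed
#'
#' Every stage of an experiment (chromosome split, tuning/training partition,
#' subsampling, label shuffling, ...) draws its own seed from the master seed,
#' so runs are bit-reproducible and stages can be replayed in isolation.
#'
#' @param master Master seed (integer).
#' @param names Character vector naming the sub-seeds wanted.
#' @return Named integer vector of seeds, all below 2^31.
#' @export
#' @examples
#' derive_seeds(1, c("split", "subsample"))
derive_seeds <- function(master, names) {
  stopifnot(length(names) >= 1L)
  s <- with_seed(master, sample.int(2147483646L, length(names)))
  stats::setNames(s, names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
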