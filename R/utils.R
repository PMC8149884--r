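#' Derive a child seed from a base seed and a label
#'
#' All randomness in multi-stage pipelines flows from one top-level seed;
#' stage seeds are derived deterministically from the base seed and a short
#' stage name, so runs are reproducible and stages are decoupled.
#'
#' @param seed integer base seed.
#' @param name character label of the consumer (e.g. `"restart-3"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "restart-1")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  val <- (abs(seed) * 48271 + h * 16807 + 12345) %% 2147483587
  as.integer(val %% 2147483646 + 1)
}

# local, restoring RNG scope
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))
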