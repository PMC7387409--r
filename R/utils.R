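#' Derive a reproducible sub-seed from a master seed
#'
#' Fans a single master seed out to per-arm / per-mouse / per-cell sub-seeds
#' with a multiplicative-congruential mixing rule, so any subset of a cohort
#' can be regenerated without simulating the rest. The result always lies in
#' \code{[0, 2^31 - 2]}.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the sub-stream (e.g. arm, mouse,
#'   cell), mixed in order.
#' @return a single integer sub-seed.
#' @examples
#' subSeed(1, 2, 3) == subSeed(1, 2, 3)
#' subSeed(1, 2, 3) != subSeed(1, 3, 2)
#' @export
subSeed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1; products stay exact in doubles
  s <- as.numeric(master) %% m
  for (k in as.numeric(c(...))) {
    s <- (s * 69069 + k + 1) %% m
  }
  as.integer(s)
}

# run expr under a local, restored RNG state
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
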