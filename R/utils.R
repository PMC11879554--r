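#' @importFrom stats rnbinom rpois rbinom rbeta rnorm runif t.test wilcox.test
#'   ppois cor cor.test sd median quantile hclust cutree as.dist prcomp
#'   kmeans pt
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a child seed from a master seed
#'
#' One master seed drives the whole simulation; each submodule uses a child
#' seed at a fixed offset so that any stage can be regenerated independently
#' of the others. Kept below 2^31 - 1 so it is always a valid R integer.
#'
#' @param seed master integer seed
#' @param offset fixed per-submodule offset
#' @return integer seed
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147483629)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# shared tissue naming used across the simulator and readers
tissue_names <- function(n) sprintf("tissue%02d", seq_len(n))
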