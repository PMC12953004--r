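# internal helpers

#' @useDynLib crustnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Derive a reproducible child seed from a parent seed and a string key.
# Keeps sub-generators decoupled: changing how many draws one component
# makes never perturbs another component's stream.
split_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cs <- utf8ToInt(key)
  h <- sum(cs * seq_along(cs)) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 69621 + 1) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_arg <- function(...) stop(..., call. = FALSE)
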