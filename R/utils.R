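# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so package operations never perturb the user's random
#' stream. `seed = NULL` uses (and advances) the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stream index.
# Kept below 2^31 - 1 so it is always a valid R integer.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483629L)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

assert_binary_matrix <- function(m, what = "presence matrix") {
  stop_if_not(is.matrix(m) && is.numeric(m), sprintf("%s must be a numeric matrix", what))
  stop_if_not(all(m %in% c(0, 1)), sprintf("%s must contain only 0/1", what))
  invisible(m)
}

# Deterministic, locale-independent ordering for ids.
id_order <- function(x) order(as.character(x), method = "radix")
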