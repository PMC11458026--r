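# Internal helpers: reproducible seed streams and small numerics.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the Mersenne-Twister stream seeded at `seed`, then
#' restores the caller's RNG state, so library randomness never leaks into
#' or out of pipeline computations.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Lehmer-style fold of integers/strings into a 31-bit seed. All products stay
# below 2^53 so double arithmetic is exact.
.SEED_MOD <- 2147483647
.SEED_MUL <- 48271

derive_seed <- function(...) {
  parts <- list(...)
  acc <- 12345
  for (p in parts) {
    if (is.character(p)) {
      p <- utf8ToInt(paste(p, collapse = "\r"))
    }
    for (x in as.numeric(p)) {
      x <- abs(x) %% .SEED_MOD
      acc <- (acc * .SEED_MUL + x + 1) %% .SEED_MOD
    }
  }
  as.integer(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot with a formatted message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

.is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
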