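`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an independent per-case seed from a master seed
#'
#' Counter-based scheme: each (index, stream) pair maps to a distinct 31-bit
#' seed so that cases drawn from one master seed are reproducible and mutually
#' independent of how many other cases were generated before them.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter (e.g. case number).
#' @param stream small integer distinguishing draws within one case.
#' @return An integer seed in `[1, 2^31 - 22)`.
#' @export
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483629 # large prime < 2^31
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(index) * 104729 +
    as.numeric(stream) * 7919
  as.integer(s %% m) + 1L
}

# evaluate `code` under a temporary RNG state; the caller's state is restored
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  code
}

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
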