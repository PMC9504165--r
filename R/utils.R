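`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus a string key to a new seed in
#' `[1, 2^31 - 2]`, so that per-subject, per-method and per-fold random streams
#' can be re-derived from a single run seed.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric key components identifying the consumer.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647L
  as.integer(h %% 2147483562L + 1L)
}

# Evaluate expr under a given seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
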