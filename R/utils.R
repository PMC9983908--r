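#' @keywords internal
"_PACKAGE"

#' Derive a substream seed from a root seed
#'
#' All stochastic stages (simulate, augment, split, train) draw their
#' seeds through this fold of the root seed with stage labels and
#' indices, so a single integer reproduces a whole run and any stage
#' can be regenerated in isolation.  Results stay below 2^31 - 1.
#'
#' @param seed root integer seed.
#' @param ... stage labels (character) and indices (numeric) to fold in.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "|")) else as.double(p)
  }))
  h <- as.double(seed) %% 2147483647
  for (ci in parts) h <- (h * 31 + abs(ci) + 7) %% 2147483647
  as.integer(max(1, h))
}

## Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_arg <- function(...) stop(..., call. = FALSE)

## geometric (log-spaced) sequence used for TI vectors and T1/T2 grids
log_seq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}
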