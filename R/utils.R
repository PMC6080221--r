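# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one explicit integer seed.
#' Substreams (per subject, per session, per model initialization) use
#' seeds derived deterministically with this multiplicative scheme, so
#' results do not depend on evaluation order.
#'
#' @param seed master seed (integer-valued scalar).
#' @param index non-negative integer identifying the substream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  # modular affine map; modulus 2^31 - 1 keeps the result a valid R integer
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + index * 16807 + 1) %% m)
}

# Run expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("myograsp_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("myograsp_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
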