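# internal helpers shared across modules

gn_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "gennas_error", "error", "condition")))
}

gn_assert <- function(ok, msg, class = "gennas_argument_error") {
  if (!isTRUE(ok)) gn_stop(msg, class)
}

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds so that each pipeline stage
#' (data synthesis, evolution, full training, ...) is independently
#' reproducible. The derivation is a fixed affine map modulo a Mersenne
#' prime, kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. "evolve").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  gn_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "`seed` must be a single finite number")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647L)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
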