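#' Derive a stage-local random seed from a global seed
#'
#' All stochastic stages of the pipeline draw their randomness from one
#' user-supplied integer seed. Stage-local seeds are derived by hashing the
#' stage name into the global seed, so adding a stage never perturbs the
#' random stream of another.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "detect")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state. Every exported stochastic function funnels through this, so no
# global RNG state leaks in or out.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  expr
}
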