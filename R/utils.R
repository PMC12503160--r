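# internal helpers

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Likert observation: latent -> clamp to scale then round to integer grid
likert_observe <- function(latent, scale = c(1L, 5L)) {
  as.integer(round(clamp(latent, scale[1], scale[2])))
}

col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2, mu)^2) / (n - 1))
}

`%||%` <- rlang::`%||%`
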