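# shared fixtures, built in code

# memoised default test atlas (small but fully featured)
test_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_silhouette(c(174, 64))
    cache
  }
})

# minimal rectangular atlas: every pixel in-mask, one region; lets map
# statistics be checked against dense brute-force oracles
flat_atlas <- function(rows, cols, masked_cols = NULL) {
  mask <- matrix(TRUE, rows, cols)
  if (!is.null(masked_cols)) mask[, masked_cols] <- FALSE
  regions <- matrix(ifelse(mask, "chest", NA_character_), rows, cols)
  structure(
    list(mask = mask, regions = regions,
         dims = c(rows = rows, cols = cols)),
    class = "groove_atlas"
  )
}

# wrap a list of matrices as a paint-map tibble
as_maps <- function(grids, ...) {
  meta <- tibble::tibble(...)
  if (nrow(meta) == 0) {
    meta <- tibble::tibble(
      participant_id = sprintf("p%03d", seq_along(grids))
    )
  }
  meta$grid <- grids
  meta
}

# random per-subject-per-cell map collection (global-null Gaussian noise)
null_cell_maps <- function(n_subj, atlas, levels_a = c("wanting_to_move", "pleasure"),
                           levels_b = c("funk", "jazz_funk", "rock")) {
  rows <- tidyr::expand_grid(
    participant_id = sprintf("p%03d", seq_len(n_subj)),
    component = levels_a, genre = levels_b
  )
  rows$grid <- lapply(seq_len(nrow(rows)), function(i) {
    g <- matrix(0, atlas$dims[1], atlas$dims[2])
    g[atlas$mask] <- rnorm(sum(atlas$mask))
    g
  })
  rows
}
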