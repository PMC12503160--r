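stroke_row <- function(x, y, brush, t = 0, pid = "p001", sid = "funk_1",
                       comp = "wanting_to_move") {
  tibble::tibble(
    participant_id = pid, stimulus_id = sid, component = comp,
    t_ms = t, x_px = x, y_px = y, brush_px = brush
  )
}

test_that("an empty stroke log rasterizes to an all-zero map", {
  atlas <- flat_atlas(30, 30)
  maps <- rasterize_strokes(
    tibble::tibble(), atlas,
    trials = tibble::tibble(participant_id = "p001", stimulus_id = "s1",
                            component = "pleasure")
  )
  expect_equal(nrow(maps), 1)
  expect_true(all(maps$grid[[1]] == 0))
  expect_equal(maps$out_of_body_fraction, 0)
})

test_that("a hard-disc stamp paints exactly the pixels within its radius", {
  atlas <- flat_atlas(40, 40)
  for (r in c(2, 5, 7.5)) {
    maps <- rasterize_strokes(stroke_row(19, 19, r), atlas)
    # brute force: enumerate all grid pixels within Euclidean distance r
    expected <- 0L
    for (row in 1:40) for (col in 1:40) {
      if ((row - 20)^2 + (col - 20)^2 <= r^2) expected <- expected + 1L
    }
    expect_equal(sum(maps$grid[[1]] > 0), expected)
    expect_true(all(maps$grid[[1]] %in% c(0, 1)))
  }
})

test_that("clipping makes coincident repainting idempotent", {
  atlas <- flat_atlas(30, 30)
  one <- rasterize_strokes(stroke_row(10, 10, 4), atlas)
  two <- rasterize_strokes(
    dplyr::bind_rows(stroke_row(10, 10, 4, t = 0),
                     stroke_row(10, 10, 4, t = 10)),
    atlas
  )
  expect_equal(two$grid[[1]], one$grid[[1]])
})

test_that("pre-clip deposited mass is samples x kernel mass on separated stamps", {
  atlas <- flat_atlas(60, 200)
  kernel_mass <- length(groovemap:::disc_offsets(3)$dr)
  strokes <- dplyr::bind_rows(lapply(0:4, function(i) {
    stroke_row(20 + 30 * i, 30, 3, t = i * 1000)  # far apart: no overlap,
  }))                                             # gaps treated as pen lifts
  maps <- rasterize_strokes(strokes, atlas, clip = FALSE)
  expect_equal(sum(maps$grid[[1]]), 5 * kernel_mass)
})

test_that("off-canvas samples are skipped and counted, not errors", {
  atlas <- flat_atlas(30, 30)
  strokes <- dplyr::bind_rows(stroke_row(500, 500, 3, t = 0),
                              stroke_row(10, 10, 3, t = 10))
  maps <- rasterize_strokes(strokes, atlas)
  expect_equal(maps$n_skipped, 1L)
  expect_gt(sum(maps$grid[[1]]), 0)
})

test_that("out-of-body mass fraction matches a constructed half-split", {
  # mask covers the left 15 columns; stamp centred on the boundary column
  atlas <- flat_atlas(31, 30, masked_cols = 16:30)
  off <- groovemap:::disc_offsets(5)
  maps <- rasterize_strokes(stroke_row(14, 15, 5), atlas)
  expected_out <- mean(15 + off$dc > 15)  # exact offset enumeration
  expect_equal(maps$out_of_body_fraction, expected_out)
  expect_lt(abs(maps$out_of_body_fraction - 0.5), 0.08)
})

test_that("masking zeroes outside, preserves inside, and is idempotent", {
  atlas <- test_atlas()
  g <- matrix(runif(prod(atlas$dims)), atlas$dims[1], atlas$dims[2])
  maps <- as_maps(list(g))
  m1 <- apply_mask(maps, atlas)
  expect_true(all(m1$grid[[1]][!atlas$mask] == 0))
  expect_equal(m1$grid[[1]][atlas$mask], g[atlas$mask])
  m2 <- apply_mask(m1, atlas)
  expect_identical(m2$grid[[1]], m1$grid[[1]])
  # paint only outside the mask vanishes entirely
  g2 <- matrix(0, atlas$dims[1], atlas$dims[2]); g2[!atlas$mask] <- 1
  expect_true(all(apply_mask(as_maps(list(g2)), atlas)$grid[[1]] == 0))
  expect_error(apply_mask(as_maps(list(matrix(0, 3, 3))), atlas),
               "dimensions")
})

test_that("anomaly screening flags scribble-everything but keeps empty maps", {
  atlas <- test_atlas()
  H <- atlas$dims[1]; W <- atlas$dims[2]
  zero <- matrix(0, H, W)
  full <- matrix(1, H, W)
  grids <- c(replicate(97, {
    g <- zero; px <- which(atlas$mask)[1:50]; g[px] <- 1; g
  }, simplify = FALSE), list(full, full, full))
  maps <- as_maps(grids)
  res <- screen_anomalies(maps, atlas)
  expect_equal(nrow(res$flagged), 3)
  expect_equal(nrow(res$kept), 97)
  expect_true(all(res$report$flagged == c(rep(FALSE, 97), rep(TRUE, 3))))
  # all-zero maps are legal data
  res0 <- screen_anomalies(as_maps(list(zero)), atlas)
  expect_equal(nrow(res0$flagged), 0)
})

test_that("aggregation averages pixel-wise with correct bookkeeping", {
  atlas <- flat_atlas(10, 10)
  g0 <- matrix(0, 10, 10); g1 <- matrix(1, 10, 10)
  maps <- as_maps(list(g0, g1, g1),
                  participant_id = c("p1", "p1", "p2"),
                  genre = c("funk", "funk", "funk"))
  agg <- aggregate_maps(maps, c("participant_id", "genre"))
  expect_equal(nrow(agg), 2)
  expect_equal(agg$grid[[which(agg$participant_id == "p1")]],
               matrix(0.5, 10, 10))
  expect_equal(agg$n_trials, c(2, 1))
  # single-map groups are identities
  one <- aggregate_maps(as_maps(list(g1), participant_id = "p9"),
                        "participant_id")
  expect_identical(one$grid[[1]], g1)
})

test_that("aggregating a partition then the groups equals the grand mean", {
  atlas <- flat_atlas(8, 8)
  set.seed(42)
  grids <- replicate(6, matrix(rnorm(64), 8, 8), simplify = FALSE)
  maps <- as_maps(grids,
                  participant_id = rep("p1", 6),
                  genre = rep(c("funk", "rock"), each = 3))
  by_genre <- aggregate_maps(maps, c("participant_id", "genre"))
  grand_two_step <- Reduce(`+`, by_genre$grid) / nrow(by_genre)
  grand_direct <- Reduce(`+`, grids) / 6
  expect_equal(grand_two_step, grand_direct, tolerance = 1e-12)
})

test_that("simulated trial counts per cell match the design", {
  atlas <- test_atlas()
  des <- study_design(n_participants = 3)
  truth <- simulation_truth()
  strokes <- simulate_strokes(des, truth, atlas, seed = 5)
  maps <- rasterize_strokes(strokes, atlas, trials = trial_grid(des))
  maps <- apply_mask(maps, atlas)
  agg <- aggregate_maps(maps, c("participant_id", "component", "genre"))
  expect_equal(nrow(agg), 3 * 2 * 3)
  expect_true(all(agg$n_trials == 4))
})
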