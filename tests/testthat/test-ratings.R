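make_table <- function(n = 24, seed = 31) {
  simulate_ratings(study_design(n), simulation_truth(), seed = seed)
}

test_that("similarity matrix is a metric on stimulus rating vectors", {
  tab <- make_table(12)
  d <- similarity_matrix(tab, "wanting_to_move")
  expect_equal(dim(d), c(12, 12))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality, spot-checked over all triples
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
  }
})

test_that("similarity distances match hand computation", {
  tab <- tidyr::expand_grid(
    participant_id = c("p1", "p2"),
    stimulus_id = c("s1", "s2"),
    component = "wanting_to_move"
  )
  tab$rating <- c(1, 4, 1, 5)[match(paste(tab$participant_id, tab$stimulus_id),
                                    c("p1 s1", "p1 s2", "p2 s1", "p2 s2"))]
  d <- similarity_matrix(tab, "wanting_to_move")
  expect_equal(d["s1", "s2"], 5)  # sqrt(3^2 + 4^2)
  # identical vectors -> zero distance
  tab2 <- tab; tab2$rating <- c(2, 2, 3, 3)
  expect_equal(similarity_matrix(tab2, "wanting_to_move")["s1", "s2"], 0)
})

test_that("similarity errors on incomplete crossings, naming the cells", {
  tab <- make_table(4)
  expect_error(similarity_matrix(tab[-1, ], "wanting_to_move"), "missing")
})

test_that("genre model recovers noise-free generating coefficients", {
  truth <- simulation_truth(
    random_sd = list(participant_intercept = 0, participant_genre_slope = 0,
                     stimulus_intercept = 0),
    residual_sd = 0,
    familiarity = list(participant_sd = 0.3, noise_sd = 0.4)
  )
  tab <- simulate_ratings(study_design(40), truth, seed = 32)
  # refit on the latent prediction itself (undo the Likert rounding) so the
  # degenerate exact case is testable
  b <- truth$fixed$wanting_to_move
  sel <- tab$component == "wanting_to_move"
  tab$rating[sel] <- b$intercept +
    ifelse(tab$genre[sel] == "jazz_funk", b$genre_jazz_funk,
           ifelse(tab$genre[sel] == "rock", b$genre_rock, 0)) +
    b$familiarity * (tab$familiarity[sel] - 2.3)
  fit <- fit_genre_model(tab, "wanting_to_move")
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "genrejazz_funk"], -1.21,
               tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "genrerock"], -0.91, tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "familiarity"], 0.97, tolerance = 1e-6)
})

test_that("genre model is invariant to row permutation", {
  tab <- make_table(15)
  f1 <- fit_genre_model(tab, "pleasure", random = "intercepts")
  f2 <- fit_genre_model(tab[sample(nrow(tab)), ], "pleasure",
                        random = "intercepts")
  expect_equal(generics::tidy(f1)$estimate, generics::tidy(f2)$estimate,
               tolerance = 1e-6)
})

test_that("the random-effect fallback ladder is logged", {
  tab <- make_table(15)
  fit <- fit_genre_model(tab, "wanting_to_move")
  expect_s4_class(fit$fit, "lmerModLmerTest")
  expect_match(fit$notes[1], "by-stimulus genre slope inestimable")
  gl <- generics::glance(fit)
  expect_true(gl$REML)
  expect_true(all(generics::tidy(fit)$std.error > 0))
})

test_that("identical models compare with chi-square 0 and p 1", {
  tab <- make_table(8)
  f <- fit_genre_model(tab, "wanting_to_move", random = "intercepts")
  cmp <- compare_models(f, f)
  expect_equal(cmp$chisq, 0, tolerance = 1e-6)
  expect_equal(cmp$df, 0)
  expect_equal(cmp$p.value, 1)
})

test_that("adding genre to the null improves fit under the default truth", {
  tab <- make_table(40)
  cmp <- compare_models(
    fit_null_model(tab, "wanting_to_move"),
    fit_genre_model(tab, "wanting_to_move", random = "intercepts")
  )
  expect_equal(cmp$df, 2)
  expect_lt(cmp$p.value, 0.05)
})

test_that("non-nested comparisons are refused", {
  tab <- make_table(8)
  fg <- fit_genre_model(tab, "wanting_to_move", random = "intercepts")
  fe <- fit_entropy_model(tab, "wanting_to_move")
  expect_error(compare_models(fg, fe), "not nested")
})

test_that("post-hoc adjustment never lowers p below the unadjusted value", {
  tab <- make_table(25)
  fit <- fit_genre_model(tab, "wanting_to_move", random = "intercepts")
  adj <- posthoc_pairwise(fit, "genre", adjust = "mvt")
  raw <- posthoc_pairwise(fit, "genre", adjust = "none")
  expect_equal(nrow(adj), 3)
  expect_true(all(adj$p.value >= raw$p.value - 0.01))
  expect_equal(adj$estimate, raw$estimate, tolerance = 1e-9)
  # funk > jazz funk and funk > rock under the default truth
  expect_gt(adj$estimate[grepl("funk - jazz_funk", adj$contrast)], 0)
})

test_that("entropy model needs varying entropy and recovers a parabola", {
  tab <- make_table(6)
  tab$pulse_entropy <- 0.7
  expect_error(fit_entropy_model(tab, "wanting_to_move"), "constant")

  # deterministic parabola on the raw entropy scale, no noise at all
  des <- study_design(6)
  tab2 <- tidyr::expand_grid(
    participant_id = sprintf("p%d", 1:6),
    stimulus_id = des$stimuli$stimulus_id
  )
  tab2 <- dplyr::left_join(tab2, des$stimuli, by = "stimulus_id")
  tab2$component <- "wanting_to_move"
  tab2$formal_training_years <- rep(0:5, each = 12)   # varied, zero effect
  tab2$informal_training_years <- rep(c(0, 2), 36)
  tab2$familiarity <- 3L
  a <- 2; bb <- 3; cc <- -40
  tab2$rating <- a + bb * tab2$pulse_entropy +
    cc * (tab2$pulse_entropy - 0.73)^2
  fit <- fit_entropy_model(tab2, "wanting_to_move")
  pred <- stats::predict(fit$fit, re.form = NA)
  expect_equal(unname(pred), tab2$rating, tolerance = 1e-6)
  td <- generics::tidy(fit)
  expect_lt(td$estimate[td$term == "entropy_quad"], 0)
})
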