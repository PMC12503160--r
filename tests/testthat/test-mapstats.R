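test_that("one-sample t matches the closed form and handles degenerate pixels", {
  atlas <- flat_atlas(1, 3)
  # pixel 1: values 1,2,3 -> t = 2 / (1/sqrt(3)); pixel 2: all zero;
  # pixel 3: constant nonzero (zero variance, nonzero mean)
  grids <- list(
    matrix(c(1, 0, 0.5), 1, 3), matrix(c(2, 0, 0.5), 1, 3),
    matrix(c(3, 0, 0.5), 1, 3)
  )
  sm <- one_sample_t_map(as_maps(grids), atlas)
  expect_equal(sm$stat[1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(sm$stat[1, 1], 3.4641, tolerance = 1e-4)
  expect_equal(sm$df, 2)
  expect_equal(sm$stat[1, 2], 0)
  expect_equal(sm$p[1, 2], 1)
  expect_true(is.infinite(sm$stat[1, 3]) && sm$stat[1, 3] > 0)
  expect_equal(sm$p[1, 3], 0)
  expect_equal(sm$n_flagged, 1L)
})

test_that("all-zero subject maps give a null map with no rejections", {
  atlas <- flat_atlas(5, 5)
  grids <- replicate(4, matrix(0, 5, 5), simplify = FALSE)
  sm <- one_sample_t_map(as_maps(grids), atlas)
  expect_true(all(sm$stat[atlas$mask] == 0))
  expect_equal(sum(sm$sig), 0)
})

test_that("one-sample t is invariant to subject order", {
  atlas <- flat_atlas(4, 4)
  set.seed(7)
  grids <- replicate(6, matrix(rnorm(16), 4, 4), simplify = FALSE)
  maps <- as_maps(grids)
  s1 <- one_sample_t_map(maps, atlas)
  s2 <- one_sample_t_map(maps[sample(6), ], atlas)
  expect_equal(s1$stat, s2$stat, tolerance = 1e-12)
})

test_that("paired t is antisymmetric and zero on identical inputs", {
  atlas <- flat_atlas(4, 4)
  set.seed(8)
  # integer-valued grids keep the constant-difference case exact in floats
  ga <- replicate(5, matrix(sample(0:9, 16, TRUE), 4, 4), simplify = FALSE)
  gb <- replicate(5, matrix(sample(0:9, 16, TRUE), 4, 4), simplify = FALSE)
  a <- as_maps(ga); b <- as_maps(gb)
  ab <- paired_t_map(a, b, atlas)
  ba <- paired_t_map(b, a, atlas)
  expect_equal(ab$stat, -ba$stat, tolerance = 1e-12)
  expect_identical(ab$sig, ba$sig)
  aa <- paired_t_map(a, a, atlas)
  expect_true(all(aa$stat[atlas$mask] == 0))
  # constant nonzero differences hit the infinite-t sentinel
  gc <- lapply(ga, function(g) g + 1)
  s <- paired_t_map(as_maps(gc), a, atlas)
  expect_true(all(is.infinite(s$stat[atlas$mask])))
  expect_equal(s$n_flagged, 16L)
})

test_that("paired t matches subjects by id and rejects mismatches", {
  atlas <- flat_atlas(2, 2)
  set.seed(9)
  ga <- replicate(4, matrix(rnorm(4), 2, 2), simplify = FALSE)
  gb <- replicate(4, matrix(rnorm(4), 2, 2), simplify = FALSE)
  a <- as_maps(ga, participant_id = sprintf("p%d", 1:4))
  b <- as_maps(gb, participant_id = sprintf("p%d", 1:4))
  straight <- paired_t_map(a, b, atlas)
  shuffled <- paired_t_map(a, b[c(3, 1, 4, 2), ], atlas)
  expect_equal(straight$stat, shuffled$stat, tolerance = 1e-12)
  expect_error(
    paired_t_map(a, as_maps(gb, participant_id = sprintf("q%d", 1:4)), atlas),
    "same subjects"
  )
})

test_that("repeated-measures F maps equal the brute-force oracle", {
  atlas <- flat_atlas(2, 2)
  set.seed(10)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    rows <- tidyr::expand_grid(
      participant_id = sprintf("p%d", seq_len(n)),
      component = c("m", "p"), genre = c("f", "j", "r")
    )
    rows$grid <- replicate(nrow(rows), matrix(rnorm(4), 2, 2),
                           simplify = FALSE)
    fs <- rm_anova_map(rows, atlas, c("component", "genre"))
    for (px in 1:4) {
      y <- array(0, c(n, 2, 3))
      for (i in seq_len(nrow(rows))) {
        s <- match(rows$participant_id[i], sprintf("p%d", seq_len(n)))
        a <- match(rows$component[i], c("m", "p"))
        b <- match(rows$genre[i], c("f", "j", "r"))
        y[s, a, b] <- rows$grid[[i]][px]
      }
      o <- oracle_rm_anova(y)
      expect_equal(fs$component$stat[atlas$mask][px], o$f_a, tolerance = 1e-10)
      expect_equal(fs$genre$stat[atlas$mask][px], o$f_b, tolerance = 1e-10)
      expect_equal(fs[["component:genre"]]$stat[atlas$mask][px], o$f_ab,
                   tolerance = 1e-10)
    }
    expect_equal(fs$component$df, c(1, n - 1))
    expect_equal(fs$genre$df, c(2, 2 * (n - 1)))
  }
})

test_that("constant cell maps give F = 0 everywhere and no rejections", {
  atlas <- flat_atlas(3, 3)
  rows <- tidyr::expand_grid(
    participant_id = sprintf("p%d", 1:4),
    component = c("m", "p"), genre = c("f", "j", "r")
  )
  rows$grid <- replicate(nrow(rows), matrix(0.7, 3, 3), simplify = FALSE)
  fs <- rm_anova_map(rows, atlas, c("component", "genre"))
  for (m in fs) {
    expect_true(all(m$stat[atlas$mask] == 0))
    expect_equal(sum(m$sig), 0)
  }
})

test_that("unbalanced designs are rejected with the missing cells named", {
  atlas <- flat_atlas(2, 2)
  rows <- tidyr::expand_grid(
    participant_id = sprintf("p%d", 1:4),
    component = c("m", "p"), genre = c("f", "j", "r")
  )
  rows$grid <- replicate(nrow(rows), matrix(0, 2, 2), simplify = FALSE)
  expect_error(rm_anova_map(rows[-5, ], atlas, c("component", "genre")),
               "missing cells")
})

test_that("Benjamini-Hochberg matches brute force and p.adjust", {
  res <- fdr_threshold(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$reject))
  expect_equal(res$critical_p, 0.04)
  expect_equal(sum(fdr_threshold(rep(1, 10), 0.05)$reject), 0)
  expect_true(fdr_threshold(0.04, 0.05)$reject)   # m = 1: plain test
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    mine <- fdr_threshold(p, q)
    oracle <- oracle_bh(p, q)
    expect_identical(mine$reject, oracle$reject)
    expect_equal(mine$critical_p, oracle$critical_p)
    expect_identical(mine$reject, stats::p.adjust(p, "BH") <= q)
  }
})

test_that("enlarging q never shrinks the BH rejection set", {
  set.seed(12)
  p <- runif(200)^2
  prev <- rep(FALSE, 200)
  for (q in c(0.01, 0.05, 0.1, 0.2, 0.4)) {
    cur <- fdr_threshold(p, q)$reject
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("region summaries reflect indicator significance patterns", {
  atlas <- test_atlas()
  n_px <- sum(atlas$mask)
  stat_vec <- rep(1, n_px)
  # build a map whose significant set is exactly the head region
  p_vec <- ifelse(atlas$regions[atlas$mask] == "head", 1e-6, 1)
  sm <- groovemap:::new_statmap(stat_vec, p_vec, df = 9, atlas, 0.05,
                                "test", "t", 10)
  tab <- summarize_regions(sm, atlas)
  head_row <- tab[tab$region == "head", ]
  expect_equal(head_row$fraction_sig, 1)
  expect_true(all(tab$n_sig[tab$region != "head"] == 0))
  # empty significance mask: all counts zero
  sm0 <- groovemap:::new_statmap(stat_vec, rep(1, n_px), df = 9, atlas,
                                 0.05, "test", "t", 10)
  expect_true(all(summarize_regions(sm0, atlas)$n_sig == 0))
})

test_that("statmap tidy/glance expose per-pixel and per-map summaries", {
  atlas <- flat_atlas(3, 4)
  grids <- replicate(5, matrix(rnorm(12), 3, 4), simplify = FALSE)
  sm <- one_sample_t_map(as_maps(grids), atlas)
  td <- generics::tidy(sm)
  expect_equal(nrow(td), 12)
  expect_true(all(c("row", "col", "stat", "p", "sig") %in% names(td)))
  gl <- generics::glance(sm)
  expect_equal(gl$n_pixels, 12)
  expect_equal(gl$n_subjects, 5)
})

test_that("familiarity median split sends ties low", {
  s <- split_familiarity(tibble::tibble(stimulus_id = letters[1:4],
                                        familiarity = c(1, 2, 3, 4)))
  expect_equal(as.character(s$familiarity_bin), c("low", "low", "high", "high"))
  expect_warning(
    s2 <- split_familiarity(tibble::tibble(stimulus_id = letters[1:4],
                                           familiarity = rep(2, 4))),
    "empty"
  )
  expect_true(all(s2$familiarity_bin == "low"))
  expect_error(split_familiarity(tibble::tibble(stimulus_id = "a",
                                                familiarity = 1)),
               "at least 2")
})

test_that("entropy tertiles are balanced with remainder in the middle", {
  s <- split_entropy(tibble::tibble(stimulus_id = sprintf("s%02d", 1:12),
                                    pulse_entropy = runif(12)))
  expect_equal(as.vector(table(s$entropy_bin)), c(4, 4, 4))
  s3 <- split_entropy(tibble::tibble(stimulus_id = c("a", "b", "c"),
                                     pulse_entropy = c(0.1, 0.2, 0.3)))
  expect_equal(as.character(s3$entropy_bin), c("low", "medium", "high"))
  # rank-based: matches an explicit sort oracle, remainder to medium
  set.seed(13)
  vals <- runif(100)
  s100 <- split_entropy(tibble::tibble(stimulus_id = sprintf("s%03d", 1:100),
                                       pulse_entropy = vals))
  ord <- order(vals)
  expect_true(all(s100$entropy_bin[ord[1:33]] == "low"))
  expect_true(all(s100$entropy_bin[ord[34:67]] == "medium"))
  expect_true(all(s100$entropy_bin[ord[68:100]] == "high"))
  expect_error(split_entropy(tibble::tibble(stimulus_id = c("a", "b"),
                                            pulse_entropy = c(0.1, 0.2))),
               "at least 3")
})
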