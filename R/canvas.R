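#' Expected trial grid of a study design
#'
#' @param design a [study_design()].
#' @return A tibble with one row per participant x stimulus x component,
#'   carrying `genre` and `pulse_entropy`, suitable for the `trials`
#'   argument of [rasterize_strokes()].
#' @export
trial_grid <- function(design) {
  stopifnot(inherits(design, "groove_design"))
  tidyr::expand_grid(
    participant_id = sprintf("p%03d", seq_len(design$n_participants)),
    stimulus_id = design$stimuli$stimulus_id,
    component = factor(design$components, levels = design$components)
  ) |>
    dplyr::left_join(design$stimuli, by = "stimulus_id")
}

disc_offsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dr = s, dc = s)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  list(dr = g$dr, dc = g$dc, w = rep(1, nrow(g)))
}

gaussian_offsets <- function(r) {
  sigma <- r / 2
  ext <- ceiling(3 * sigma)
  s <- seq(-ext, ext)
  g <- expand.grid(dr = s, dc = s)
  d2 <- g$dr^2 + g$dc^2
  keep <- d2 <= (3 * sigma)^2
  list(dr = g$dr[keep], dc = g$dc[keep],
       w = exp(-d2[keep] / (2 * sigma^2)))
}

#' Reconstruct per-trial painting maps from stroke logs
#'
#' Rasterizes mouse painting events onto the silhouette canvas: every
#' sample deposits a brush kernel (hard disc by default, or a Gaussian with
#' sigma = brush/2) centred at its pixel position; deposits accumulate over
#' samples and are clipped at 1 per pixel, so repainting a spot carries no
#' extra signal. Consecutive samples of a trial that are further apart than
#' the brush radius (but not implausibly far, which is treated as a pen
#' lift) are connected by stamping along the line segment, so mouse
#' sampling gaps do not leave dotted strokes. Samples whose centre falls
#' off the canvas are skipped and counted. The fraction of deposited mass
#' falling outside the body mask is recorded before any masking;
#' out-of-body paint itself is removed by [apply_mask()].
#'
#' @param strokes stroke-log tibble (see [simulate_strokes()] for the
#'   column contract; coordinates 0-based, origin top-left).
#' @param atlas a [make_silhouette()] atlas.
#' @param trials optional tibble of expected trials (at least
#'   `participant_id`, `stimulus_id`, `component`; extra columns such as
#'   `genre` are carried through). Trials with no stroke samples yield
#'   all-zero maps. Defaults to the trials present in `strokes`.
#' @param kernel `"disc"` (default) or `"gaussian"`.
#' @param interpolate connect sampling gaps along segments (default TRUE).
#' @param clip clip accumulated paint at 1 per pixel (default TRUE).
#' @return A tibble with one row per trial: the trial identifiers, any
#'   extra `trials` columns, `out_of_body_fraction`, `n_skipped`, and a
#'   `grid` list-column of rows x cols intensity matrices.
#' @export
rasterize_strokes <- function(strokes, atlas, trials = NULL,
                              kernel = c("disc", "gaussian"),
                              interpolate = TRUE, clip = TRUE) {
  stopifnot(inherits(atlas, "groove_atlas"))
  kernel <- match.arg(kernel)
  key <- c("participant_id", "stimulus_id", "component")
  if (nrow(strokes)) {
    need <- c(key, "t_ms", "x_px", "y_px", "brush_px")
    if (!all(need %in% names(strokes))) {
      abort(paste0("`strokes` needs columns ",
                   paste(need, collapse = ", ")))
    }
    if (any(!is.finite(strokes$x_px) | !is.finite(strokes$y_px))) {
      abort("stroke coordinates must be finite.")
    }
    if (any(strokes$brush_px <= 0)) abort("brush radius must be positive.")
  }
  if (is.null(trials)) {
    trials <- dplyr::distinct(strokes[, key, drop = FALSE])
  } else {
    trials <- as_tibble(trials)
    if (!all(key %in% names(trials))) {
      abort("`trials` needs participant_id, stimulus_id, component columns.")
    }
  }
  H <- atlas$dims[1]; W <- atlas$dims[2]
  mask_vec <- as.vector(atlas$mask)
  offset_fn <- if (kernel == "disc") disc_offsets else gaussian_offsets
  off_cache <- new.env(parent = emptyenv())

  idx <- if (nrow(strokes)) {
    split(
      seq_len(nrow(strokes)),
      factor(
        paste(strokes$participant_id, strokes$stimulus_id, strokes$component),
        levels = paste(trials$participant_id, trials$stimulus_id,
                       trials$component)
      )
    )
  } else {
    rep(list(integer(0)), nrow(trials))
  }

  grids <- vector("list", nrow(trials))
  outfrac <- numeric(nrow(trials))
  skipped <- integer(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    ii <- idx[[i]]
    if (length(ii) == 0) {
      grids[[i]] <- matrix(0, H, W)
      next
    }
    samp <- strokes[ii, ]
    samp <- samp[order(samp$t_ms), ]
    res <- rasterize_one(samp, H, W, mask_vec, offset_fn, off_cache,
                         interpolate, clip)
    grids[[i]] <- res$grid
    outfrac[i] <- res$out_of_body_fraction
    skipped[i] <- res$n_skipped
  }
  out <- trials
  out$out_of_body_fraction <- outfrac
  out$n_skipped <- skipped
  out$grid <- grids
  as_tibble(out)
}

rasterize_one <- function(samp, H, W, mask_vec, offset_fn, off_cache,
                          interpolate, clip) {
  # 0-based coordinates -> 1-based matrix indices at pixel centres
  r0 <- round(samp$y_px) + 1
  c0 <- round(samp$x_px) + 1
  b0 <- samp$brush_px
  on <- r0 >= 1 & r0 <= H & c0 >= 1 & c0 <= W
  n_skipped <- sum(!on)
  r0 <- r0[on]; c0 <- c0[on]; b0 <- b0[on]
  if (!length(r0)) {
    return(list(grid = matrix(0, H, W), out_of_body_fraction = 0,
                n_skipped = n_skipped))
  }
  if (interpolate && length(r0) > 1) {
    extra_r <- list(); extra_c <- list(); extra_b <- list()
    gap <- sqrt(diff(r0)^2 + diff(c0)^2)
    br <- pmin(b0[-length(b0)], b0[-1])
    todo <- which(gap > br / 2 & gap <= 6 * br)
    for (j in todo) {
      k <- ceiling(gap[j] / (br[j] / 2)) - 1
      tt <- seq_len(k) / (k + 1)
      extra_r[[length(extra_r) + 1]] <- r0[j] + tt * (r0[j + 1] - r0[j])
      extra_c[[length(extra_c) + 1]] <- c0[j] + tt * (c0[j + 1] - c0[j])
      extra_b[[length(extra_b) + 1]] <- rep(br[j], k)
    }
    if (length(extra_r)) {
      r0 <- c(r0, round(unlist(extra_r)))
      c0 <- c(c0, round(unlist(extra_c)))
      b0 <- c(b0, unlist(extra_b))
    }
  }
  acc <- numeric(H * W)
  for (b in unique(b0)) {
    bkey <- format(b, digits = 10)
    off <- off_cache[[bkey]]
    if (is.null(off)) {
      off <- offset_fn(b)
      off_cache[[bkey]] <- off
    }
    sel <- b0 == b
    ns <- sum(sel); no <- length(off$dr)
    rr <- rep(r0[sel], each = no) + rep(off$dr, times = ns)
    cc <- rep(c0[sel], each = no) + rep(off$dc, times = ns)
    ww <- rep(off$w, times = ns)
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    lin <- (cc[keep] - 1L) * H + rr[keep]
    add <- rowsum(ww[keep], lin)
    at <- as.integer(rownames(add))
    acc[at] <- acc[at] + add[, 1]
  }
  total <- sum(acc)
  outfrac <- if (total > 0) sum(acc[!mask_vec]) / total else 0
  if (clip) acc <- pmin(acc, 1)
  list(grid = matrix(acc, H, W), out_of_body_fraction = outfrac,
       n_skipped = n_skipped)
}

#' Remove paint outside the body silhouette
#'
#' Zeroes every out-of-mask pixel of each paint map; in-mask pixels are
#' unchanged. Applying the mask twice is the same as applying it once.
#'
#' @param maps paint-map tibble from [rasterize_strokes()].
#' @param atlas a [make_silhouette()] atlas with matching dimensions.
#' @return `maps` with masked grids.
#' @export
apply_mask <- function(maps, atlas) {
  stopifnot(inherits(atlas, "groove_atlas"))
  check_grids(maps, atlas)
  maps$grid <- lapply(maps$grid, function(g) {
    g[!atlas$mask] <- 0
    g
  })
  maps
}

check_grids <- function(maps, atlas) {
  if (!"grid" %in% names(maps)) abort("`maps` must carry a `grid` list-column.")
  ok <- vapply(
    maps$grid,
    function(g) is.matrix(g) && all(dim(g) == atlas$dims), logical(1)
  )
  if (!all(ok)) abort("map dimensions do not match the atlas.")
  invisible(TRUE)
}

#' Screen paintings for anomalous coloring patterns
#'
#' Flags trials that look like scribble-everything responses (in-mask
#' painted coverage above `max_coverage`) and, optionally, trials with an
#' excessive out-of-body paint fraction. Nothing is deleted silently: both
#' partitions are returned together with a per-trial report. All-zero
#' (empty) paintings are legal data and are always kept.
#'
#' @param maps paint-map tibble from [rasterize_strokes()].
#' @param atlas a [make_silhouette()] atlas.
#' @param max_coverage flag trials whose painted in-mask fraction exceeds
#'   this threshold (default 0.95).
#' @param max_out_fraction optional threshold on `out_of_body_fraction`;
#'   `NULL` (default) disables that check.
#' @return A list with elements `kept`, `flagged` (both paint-map tibbles)
#'   and `report` (a tibble with per-trial coverage and flag reason).
#' @export
screen_anomalies <- function(maps, atlas, max_coverage = 0.95,
                             max_out_fraction = NULL) {
  stopifnot(inherits(atlas, "groove_atlas"))
  if (max_coverage < 0 || max_coverage > 1) {
    abort("`max_coverage` must lie in [0, 1].")
  }
  check_grids(maps, atlas)
  coverage <- vapply(maps$grid, function(g) mean(g[atlas$mask] > 0),
                     numeric(1))
  reason <- rep(NA_character_, nrow(maps))
  flag <- coverage > max_coverage
  reason[flag] <- "coverage"
  if (!is.null(max_out_fraction)) {
    f2 <- maps$out_of_body_fraction > max_out_fraction
    reason[f2 & !flag] <- "out_of_body"
    flag <- flag | f2
  }
  report <- dplyr::select(maps, -"grid")
  report$in_mask_coverage <- coverage
  report$flagged <- flag
  report$reason <- reason
  list(
    kept = maps[!flag, , drop = FALSE],
    flagged = maps[flag, , drop = FALSE],
    report = as_tibble(report)
  )
}

#' Aggregate paint maps to condition means
#'
#' Pixel-wise mean of member trials per group. For within-subject map
#' statistics, include `participant_id` in `by` so that the result holds
#' one map per subject per cell.
#'
#' @param maps paint-map tibble.
#' @param by character vector of grouping columns present in `maps`
#'   (e.g. `c("participant_id", "component", "genre")`).
#' @return A tibble with the grouping columns, `n_trials`, and the mean
#'   `grid` per group.
#' @export
aggregate_maps <- function(maps, by) {
  if (!all(by %in% names(maps))) {
    abort(paste0("grouping columns absent from `maps`: ",
                 paste(setdiff(by, names(maps)), collapse = ", ")))
  }
  if (nrow(maps) == 0) {
    warn("no maps to aggregate")
    return(maps[0, c(by, "grid")])
  }
  keys <- interaction(maps[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(maps)), keys)
  rows <- lapply(groups, function(ii) {
    g <- Reduce(`+`, maps$grid[ii]) / length(ii)
    out <- maps[ii[1], by, drop = FALSE]
    out$n_trials <- length(ii)
    out$grid <- list(g)
    out
  })
  dplyr::bind_rows(rows)
}

# stack in-mask pixel values of a map collection into an n x P matrix
maps_matrix <- function(maps, atlas) {
  check_grids(maps, atlas)
  m <- vapply(maps$grid, function(g) g[atlas$mask],
              numeric(sum(atlas$mask)))
  t(m)
}

#' Simulate a full painting study as subject-level condition maps
#'
#' Convenience wrapper chaining [simulate_strokes()], [rasterize_strokes()],
#' [apply_mask()] and [aggregate_maps()] subject by subject, so that the
#' full per-trial map stack never has to be held in memory. The result has
#' one masked mean map per participant x component x genre.
#'
#' @inheritParams simulate_strokes
#' @param ... passed to [rasterize_strokes()].
#' @return Aggregated paint-map tibble with columns `participant_id`,
#'   `component`, `genre`, `n_trials`, `grid`.
#' @export
simulate_bsm_study <- function(design, truth, atlas, seed = 1L, ...) {
  full <- trial_grid(design)
  out <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    strokes <- simulate_strokes(design, truth, atlas,
                                seed = seed + 7919L * (p - 1L),
                                participants = p)
    trials <- full[full$participant_id == sprintf("p%03d", p), ]
    maps <- rasterize_strokes(strokes, atlas, trials = trials, ...)
    maps <- apply_mask(maps, atlas)
    out[[p]] <- aggregate_maps(maps, c("participant_id", "component", "genre"))
  }
  dplyr::bind_rows(out)
}
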