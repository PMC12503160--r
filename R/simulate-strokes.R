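#' Simulate painting stroke logs for every trial of a study
#'
#' For each trial (participant x stimulus x component) the generator selects
#' target body regions independently with probability equal to the region's
#' weight for that (component, genre) cell, then paints each selected region
#' with a smooth mean-reverting (Ornstein-Uhlenbeck-style) random walk
#' tethered to the region centroid. The number of brush samples is chosen so
#' that the rasterized stroke covers approximately the region's target
#' coverage fraction. A configurable fraction of samples strays to a random
#' canvas position, which exercises out-of-body removal downstream.
#'
#' Coordinates are 0-based pixel positions with origin at the top-left
#' corner, `x_px` rightward and `y_px` downward, matching the on-disk stroke
#' log format.
#'
#' @param design a [study_design()].
#' @param truth a [simulation_truth()]; its `effect_regions` and
#'   `stray_fraction` drive the spatial ground truth.
#' @param atlas a [make_silhouette()] atlas.
#' @param seed integer seed.
#' @param participants optional integer subset of participant indices to
#'   generate (useful for streaming large studies subject by subject).
#' @return A tibble of stroke samples with columns `participant_id`,
#'   `stimulus_id`, `component`, `t_ms`, `x_px`, `y_px`, `brush_px`.
#'   Trials whose cell has no selected region contribute no rows (an empty
#'   painting is legal data).
#' @export
simulate_strokes <- function(design, truth, atlas, seed = 1L,
                             participants = NULL) {
  stopifnot(
    inherits(design, "groove_design"),
    inherits(truth, "groove_truth"),
    inherits(atlas, "groove_atlas")
  )
  er <- truth$effect_regions
  bad <- setdiff(unique(er$region), unique(atlas$regions[atlas$mask]))
  if (length(bad)) {
    abort(paste0("effect_regions not present in atlas: ",
                 paste(bad, collapse = ", ")))
  }
  participants <- participants %||% seq_len(design$n_participants)

  # per-region geometry; bilateral regions (shoulders, arms, legs, ...) are
  # split into connected lobes so walks are tethered inside one lobe, not
  # to a between-lobe centroid
  reg_idx <- which(atlas$mask, arr.ind = TRUE)
  reg_name <- atlas$regions[atlas$mask]
  geom <- lapply(split(seq_len(nrow(reg_idx)), reg_name), function(ii) {
    rr <- reg_idx[ii, 1]; cc <- reg_idx[ii, 2]
    side <- factor(ifelse(cc <= mean(range(cc)), "l", "r"))
    # treat as bilateral when the two halves do not touch at the midline
    bilateral <- length(unique(side)) == 2 &&
      (min(cc[side == "r"]) - max(cc[side == "l"])) > 1
    lobes <- if (bilateral) split(seq_along(rr), side) else
      list(seq_along(rr))
    list(
      area = length(ii),
      lobes = lapply(lobes, function(jj) {
        member <- matrix(FALSE, atlas$dims[1], atlas$dims[2])
        member[cbind(rr[jj], cc[jj])] <- TRUE
        list(
          rows = rr[jj], cols = cc[jj],
          centroid = c(mean(rr[jj]), mean(cc[jj])),
          spread = c(max(sd(rr[jj]), 1), max(sd(cc[jj]), 1)),
          area = length(jj),
          member = member
        )
      })
    )
  })
  H <- atlas$dims[1]; W <- atlas$dims[2]

  with_seed(seed, {
    # key lookup for cell -> its region rows
    er_split <- split(er, paste(er$component, er$genre))
    out <- vector("list", length(participants) * nrow(design$stimuli) * 2L)
    k <- 0L
    for (p in participants) {
      pid <- sprintf("p%03d", p)
      for (s in seq_len(nrow(design$stimuli))) {
        gen <- as.character(design$stimuli$genre[s])
        sid <- design$stimuli$stimulus_id[s]
        for (comp in design$components) {
          cell <- er_split[[paste(comp, gen)]]
          k <- k + 1L
          if (is.null(cell) || nrow(cell) == 0) next
          sel <- cell[runif(nrow(cell)) < cell$weight, , drop = FALSE]
          if (nrow(sel) == 0) next
          segs <- list()
          t0 <- runif(1, 200, 1500)
          for (j in seq_len(nrow(sel))) {
            g <- geom[[sel$region[j]]]
            for (lobe in g$lobes) {   # both lobes of bilateral regions
              brush <- max(2, round(sqrt(lobe$area) / 7))
              n <- clamp(ceiling(sel$coverage[j] * lobe$area /
                                   (pi * brush^2) * 2.2), 3, 250)
              segs[[length(segs) + 1]] <- ou_walk(lobe, n, brush, t0)
              t0 <- t0 + n * 35 + runif(1, 300, 1200)
            }
          }
          seg <- list(
            t = unlist(lapply(segs, `[[`, "t")),
            x = unlist(lapply(segs, `[[`, "x")),
            y = unlist(lapply(segs, `[[`, "y")),
            brush = unlist(lapply(segs, `[[`, "brush"))
          )
          # stray samples jump to a uniform canvas position
          stray <- runif(length(seg$t)) < truth$stray_fraction
          if (any(stray)) {
            seg$y[stray] <- runif(sum(stray), 0, H - 1)
            seg$x[stray] <- runif(sum(stray), 0, W - 1)
          }
          out[[k]] <- list(
            participant_id = rep(pid, length(seg$t)),
            stimulus_id = rep(sid, length(seg$t)),
            component = rep(comp, length(seg$t)),
            t_ms = seg$t, x_px = seg$x, y_px = seg$y, brush_px = seg$brush
          )
        }
      }
    }
    out <- out[!vapply(out, is.null, logical(1))]
    res <- if (length(out)) {
      tibble(
        participant_id = unlist(lapply(out, `[[`, "participant_id")),
        stimulus_id = unlist(lapply(out, `[[`, "stimulus_id")),
        component = factor(unlist(lapply(out, `[[`, "component")),
                           levels = design$components),
        t_ms = unlist(lapply(out, `[[`, "t_ms")),
        x_px = unlist(lapply(out, `[[`, "x_px")),
        y_px = unlist(lapply(out, `[[`, "y_px")),
        brush_px = unlist(lapply(out, `[[`, "brush_px"))
      )
    } else {
      tibble(
        participant_id = character(0), stimulus_id = character(0),
        component = factor(character(0), levels = design$components),
        t_ms = numeric(0), x_px = numeric(0), y_px = numeric(0),
        brush_px = numeric(0)
      )
    }
    res
  })
}

# mean-reverting walk tethered to a lobe centroid and confined to the lobe
# (a step that would leave the region is not taken); returns 0-based coords
ou_walk <- function(g, n, brush, t0) {
  theta <- 0.15
  sig <- g$spread * sqrt(2 * theta)
  H <- nrow(g$member)
  start <- sample.int(g$area, 1)
  y <- numeric(n); x <- numeric(n)
  y[1] <- g$rows[start]; x[1] <- g$cols[start]
  if (n > 1) {
    ey <- rnorm(n - 1, 0, sig[1]); ex <- rnorm(n - 1, 0, sig[2])
    for (i in 2:n) {
      yy <- y[i - 1] + theta * (g$centroid[1] - y[i - 1]) + ey[i - 1]
      xx <- x[i - 1] + theta * (g$centroid[2] - x[i - 1]) + ex[i - 1]
      ri <- round(yy); ci <- round(xx)
      inside <- ri >= 1 && ri <= H && ci >= 1 && ci <= ncol(g$member) &&
        g$member[ri, ci]
      if (inside) {
        y[i] <- yy; x[i] <- xx
      } else {
        y[i] <- y[i - 1]; x[i] <- x[i - 1]
      }
    }
  }
  list(
    t = t0 + cumsum(c(0, rep(35, n - 1))) + runif(n, 0, 8),
    x = x - 1, y = y - 1,   # matrix index -> 0-based pixel coordinate
    brush = rep(brush, n)
  )
}
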