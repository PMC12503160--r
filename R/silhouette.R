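#' Region names used by the silhouette atlas
#'
#' The fixed set of 14 body regions that partition the in-silhouette pixels.
#' Region names follow the vocabulary used when reporting body-sensation-map
#' results (head, shoulders, upper chest, abdomen, arms, hands, hips, legs,
#' feet, ...).
#'
#' @export
bsm_regions <- c(
  "head", "ears", "neck_throat_mouth", "shoulders", "upper_chest", "chest",
  "abdomen", "arms", "wrists", "hands", "hips", "legs", "ankles", "feet"
)

#' Build a procedural body-silhouette atlas
#'
#' Draws a humanoid silhouette on a pixel grid and assigns every in-mask
#' pixel to exactly one of the 14 regions in [bsm_regions]. The silhouette is
#' a stand-in for the front-facing body outline used in body-sensation-map
#' experiments; it is deterministic for fixed dimensions.
#'
#' Coordinates follow image conventions: row 1 is the top of the head,
#' columns run left to right. The default canvas is 522 rows by 171 columns,
#' the aspect ratio of the classic BSM silhouette.
#'
#' @param dims integer vector `c(rows, cols)`, both at least 64.
#' @return An object of class `groove_atlas`: a list with elements
#'   `mask` (logical rows x cols matrix, `TRUE` inside the body),
#'   `regions` (character matrix, region name inside the body, `NA` outside),
#'   `dims` (`c(rows, cols)`).
#' @examples
#' atlas <- make_silhouette(c(174, 64))
#' table(atlas$regions[atlas$mask])
#' @export
make_silhouette <- function(dims = c(522L, 171L)) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || anyNA(dims)) {
    abort("`dims` must be two integers c(rows, cols).")
  }
  if (any(dims < 64L)) {
    abort("`dims` must be at least 64 x 64 pixels.")
  }
  H <- dims[1]; W <- dims[2]
  # pixel-centre coordinates
  col <- matrix(rep(seq_len(W), each = H), nrow = H)
  row <- matrix(rep(seq_len(H), times = W), nrow = H)
  x <- (col - 0.5) / W   # u in [0,1], left -> right
  y <- (row - 0.5) / H   # v in [0,1], top -> bottom
  px <- col - 0.5        # physical pixel coords for isotropic distances
  py <- row - 0.5

  in_ellipse <- function(cx, cy, rx, ry) {
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  }
  # capsule: distance (in pixels) to a segment, endpoints in (u, v) units
  in_capsule <- function(u0, v0, u1, v1, r_u) {
    ax <- u0 * W; ay <- v0 * H; bx <- u1 * W; by <- v1 * H
    dx <- bx - ax; dy <- by - ay
    tt <- ((px - ax) * dx + (py - ay) * dy) / (dx^2 + dy^2)
    tt <- pmin(pmax(tt, 0), 1)
    (px - (ax + tt * dx))^2 + (py - (ay + tt * dy))^2 <= (r_u * W)^2
  }

  head   <- in_ellipse(0.5, 0.085, 0.115, 0.062)
  ear_l  <- in_ellipse(0.5 - 0.125, 0.085, 0.040, 0.028)
  ear_r  <- in_ellipse(0.5 + 0.125, 0.085, 0.040, 0.028)
  neck   <- abs(x - 0.5) <= 0.05 & y >= 0.125 & y <= 0.175
  torso_hw <- 0.21 - 0.04 * pmin(pmax((y - 0.17) / 0.30, 0), 1)
  torso  <- y >= 0.17 & y <= 0.47 & abs(x - 0.5) <= torso_hw
  hipblk <- y > 0.47 & y <= 0.60 & abs(x - 0.5) <= 0.19
  leg_hw <- 0.085 - 0.03 * pmin(pmax((y - 0.60) / 0.345, 0), 1)
  legs_s <- y > 0.60 & y <= 0.945 &
    (abs(x - 0.40) <= leg_hw | abs(x - 0.60) <= leg_hw)
  feet_s <- y > 0.945 & y <= 0.985 &
    (abs(x - 0.40) <= 0.075 | abs(x - 0.60) <= 0.075)
  arm_l  <- in_capsule(0.5 - 0.185, 0.195, 0.5 - 0.315, 0.52, 0.045)
  arm_r  <- in_capsule(0.5 + 0.185, 0.195, 0.5 + 0.315, 0.52, 0.045)
  hand_l <- in_ellipse(0.5 - 0.325, 0.565, 0.055, 0.035)
  hand_r <- in_ellipse(0.5 + 0.325, 0.565, 0.055, 0.035)
  arms_s  <- arm_l | arm_r
  hands_s <- hand_l | hand_r

  mask <- head | ear_l | ear_r | neck | torso | hipblk | legs_s | feet_s |
    arms_s | hands_s

  regions <- matrix(NA_character_, nrow = H, ncol = W)
  assign_region <- function(where, name) {
    sel <- where & mask & is.na(regions)
    regions[sel] <<- name
  }
  assign_region(head, "head")
  assign_region(ear_l | ear_r, "ears")
  assign_region(neck, "neck_throat_mouth")
  assign_region(torso & y <= 0.245 & abs(x - 0.5) > 0.115, "shoulders")
  assign_region(torso & y <= 0.245, "upper_chest")
  assign_region(torso & y <= 0.35, "chest")
  assign_region(torso, "abdomen")
  assign_region(hipblk, "hips")
  assign_region(legs_s & y <= 0.90, "legs")
  assign_region(legs_s, "ankles")
  assign_region(feet_s, "feet")
  assign_region(hands_s | (arms_s & y > 0.545), "hands")
  assign_region(arms_s & y > 0.49, "wrists")
  assign_region(arms_s, "arms")

  if (any(is.na(regions[mask]))) {
    abort("internal error: silhouette region assignment left unlabeled pixels.")
  }
  counts <- table(factor(regions[mask], levels = bsm_regions))
  if (any(counts == 0)) {
    abort(paste0(
      "dims too small to draw all body regions; empty: ",
      paste(names(counts)[counts == 0], collapse = ", ")
    ))
  }
  structure(
    list(mask = mask, regions = regions, dims = c(rows = H, cols = W)),
    class = "groove_atlas"
  )
}

#' @export
print.groove_atlas <- function(x, ...) {
  cat("<groove_atlas> ", x$dims[1], " x ", x$dims[2], " px, ",
      sum(x$mask), " in-body pixels, ",
      length(unique(x$regions[x$mask])), " regions\n", sep = "")
  invisible(x)
}

#' Tabulate atlas regions
#'
#' @param atlas a [make_silhouette()] atlas.
#' @return A tibble with one row per region: pixel count and centroid
#'   (row/col, pixel-centre coordinates).
#' @export
region_table <- function(atlas) {
  stopifnot(inherits(atlas, "groove_atlas"))
  idx <- which(atlas$mask, arr.ind = TRUE)
  reg <- atlas$regions[atlas$mask]
  tibble(
    region = factor(reg, levels = bsm_regions),
    row = idx[, 1], col = idx[, 2]
  ) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      centroid_row = mean(.data$row),
      centroid_col = mean(.data$col),
      .groups = "drop"
    )
}

#' Logical mask for a set of atlas regions
#'
#' @param atlas a [make_silhouette()] atlas.
#' @param regions character vector of region names (see [bsm_regions]).
#' @return Logical matrix, `TRUE` on pixels belonging to any listed region.
#' @export
region_mask <- function(atlas, regions) {
  stopifnot(inherits(atlas, "groove_atlas"))
  bad <- setdiff(regions, bsm_regions)
  if (length(bad)) {
    abort(paste0("unknown region(s): ", paste(bad, collapse = ", ")))
  }
  out <- !is.na(atlas$regions) & atlas$regions %in% regions
  out
}

# single-connected-component check (4-connectivity), used by tests
connected_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[i] != 0L) next
      lab[i] <- cur
      r <- ((i - 1L) %% H) + 1L
      c <- ((i - 1L) %/% H) + 1L
      nb <- c(
        if (r > 1L) i - 1L, if (r < H) i + 1L,
        if (c > 1L) i - H, if (c < W) i + H
      )
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) stack <- c(stack, nb)
    }
  }
  max(lab)
}
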