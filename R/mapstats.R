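#' Benjamini-Hochberg rejection set
#'
#' Classic step-up false-discovery-rate procedure: sort the p-values
#' ascending, find the largest k with p_(k) <= k q / m, and reject every
#' hypothesis with p <= p_(k).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return A list with `reject` (logical, same order as `p`) and
#'   `critical_p` (0 when nothing is rejected).
#' @examples
#' fdr_threshold(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
#' @export
fdr_threshold <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  if (length(p) == 0) {
    return(list(reject = logical(0), critical_p = 0))
  }
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= q * seq_len(m) / m)
  if (!length(ok)) {
    return(list(reject = rep(FALSE, m), critical_p = 0))
  }
  crit <- p[o][max(ok)]
  list(reject = p <= crit, critical_p = crit)
}

new_statmap <- function(stat_vec, p_vec, df, atlas, q, contrast, statistic,
                        n_subjects, n_flagged = 0L) {
  fdr <- fdr_threshold(p_vec, q)
  H <- atlas$dims[1]; W <- atlas$dims[2]
  stat <- matrix(NA_real_, H, W); stat[atlas$mask] <- stat_vec
  p <- matrix(NA_real_, H, W); p[atlas$mask] <- p_vec
  sig <- matrix(FALSE, H, W); sig[atlas$mask] <- fdr$reject
  structure(
    list(
      stat = stat, p = p, sig = sig, df = df, q = q,
      critical_p = fdr$critical_p, statistic = statistic,
      contrast = contrast, n_subjects = n_subjects,
      n_flagged = n_flagged
    ),
    class = "groove_statmap"
  )
}

#' @export
print.groove_statmap <- function(x, ...) {
  cat("<groove_statmap> ", x$statistic, " map, ", x$contrast,
      "; df ", paste(round(x$df, 2), collapse = ", "),
      "; ", sum(x$sig), " significant px at q = ", x$q, "\n", sep = "")
  invisible(x)
}

#' @describeIn one_sample_t_map tidy a statistical map into a per-pixel tibble.
#' @param x a `groove_statmap`.
#' @param ... unused.
#' @export
tidy.groove_statmap <- function(x, ...) {
  idx <- which(!is.na(x$stat), arr.ind = TRUE)
  tibble(
    row = idx[, 1], col = idx[, 2],
    stat = x$stat[idx], p = x$p[idx], sig = x$sig[idx]
  )
}

#' @export
glance.groove_statmap <- function(x, ...) {
  tibble(
    statistic = x$statistic, contrast = x$contrast,
    n_subjects = x$n_subjects, q = x$q, critical_p = x$critical_p,
    n_pixels = sum(!is.na(x$stat)), n_significant = sum(x$sig),
    n_flagged = x$n_flagged
  )
}

t_from_values <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  s <- col_sds(M)
  tt <- numeric(ncol(M)); pp <- numeric(ncol(M))
  # relative tolerance so floating-point cancellation on constant pixels
  # is treated as zero variance
  zero <- s <= 1e-12 * (abs(mu) + 1)
  reg <- !zero
  tt[reg] <- mu[reg] / (s[reg] / sqrt(n))
  pp[reg] <- 2 * pt(-abs(tt[reg]), df = n - 1)
  null0 <- zero & mu == 0
  tt[null0] <- 0; pp[null0] <- 1
  degen <- zero & mu != 0  # zero variance, nonzero mean: infinite-t sentinel
  tt[degen] <- sign(mu[degen]) * Inf
  pp[degen] <- 0
  list(t = tt, p = pp, n_flagged = sum(degen))
}

#' Mass-univariate one-sample t map
#'
#' For every in-mask pixel, a one-sample t test of the subject-level paint
#' intensities against zero (df = n - 1, two-sided p), followed by
#' Benjamini-Hochberg FDR correction across the in-mask pixels. Pixels
#' where no subject ever painted (zero variance, zero mean) get t = 0,
#' p = 1; zero-variance pixels with a nonzero mean get an infinite-t
#' sentinel (p = 0) and are counted in `n_flagged`.
#'
#' @param maps paint-map tibble with one masked map per subject.
#' @param atlas a [make_silhouette()] atlas.
#' @param q FDR level (default 0.05).
#' @param contrast label stored on the result.
#' @return A `groove_statmap`.
#' @export
one_sample_t_map <- function(maps, atlas, q = 0.05, contrast = "mean > 0") {
  stopifnot(inherits(atlas, "groove_atlas"))
  M <- maps_matrix(maps, atlas)
  n <- nrow(M)
  if (n < 3) abort("at least 3 subjects are required.")
  r <- t_from_values(M)
  new_statmap(r$t, r$p, df = n - 1, atlas, q, contrast, "t", n,
              r$n_flagged)
}

#' Paired post-hoc t map
#'
#' Pixel-wise paired t test on matched per-subject maps; positive values
#' mean condition `a` exceeds condition `b`. Collections are matched on
#' `participant_id`.
#'
#' @param maps_a,maps_b paint-map tibbles with identical subjects.
#' @inheritParams one_sample_t_map
#' @return A `groove_statmap`.
#' @export
paired_t_map <- function(maps_a, maps_b, atlas, q = 0.05,
                         contrast = "a - b") {
  stopifnot(inherits(atlas, "groove_atlas"))
  if (!("participant_id" %in% names(maps_a)) ||
      !setequal(maps_a$participant_id, maps_b$participant_id) ||
      anyDuplicated(maps_a$participant_id) ||
      anyDuplicated(maps_b$participant_id)) {
    abort("`maps_a` and `maps_b` must hold one map each for the same subjects.")
  }
  maps_b <- maps_b[match(maps_a$participant_id, maps_b$participant_id), ]
  D <- maps_matrix(maps_a, atlas) - maps_matrix(maps_b, atlas)
  n <- nrow(D)
  if (n < 3) abort("at least 3 subjects are required.")
  r <- t_from_values(D)
  new_statmap(r$t, r$p, df = n - 1, atlas, q, contrast, "t", n,
              r$n_flagged)
}

#' Pixel-wise repeated-measures ANOVA maps
#'
#' Classic univariate within-subject ANOVA at every in-mask pixel. With two
#' factors (default `component` and `genre`) it returns F maps for both
#' main effects and their interaction; with one factor, the single main
#' effect. Each effect is tested against its own effect-by-subject
#' interaction mean square (no sphericity correction), and each F map is
#' FDR-corrected separately over in-mask pixels.
#'
#' @param maps paint-map tibble with one map per subject per factor cell
#'   (columns `participant_id` plus the factor columns).
#' @param factors character vector of one or two within-subject factor
#'   column names.
#' @inheritParams one_sample_t_map
#' @return A named list of `groove_statmap` objects (one per effect).
#' @export
rm_anova_map <- function(maps, atlas, factors = c("component", "genre"),
                         q = 0.05) {
  stopifnot(inherits(atlas, "groove_atlas"))
  if (!length(factors) %in% 1:2) abort("`factors` must name 1 or 2 columns.")
  if (!all(c("participant_id", factors) %in% names(maps))) {
    abort("`maps` must carry participant_id and the factor columns.")
  }
  subj <- factor(maps$participant_id)
  fac <- lapply(maps[factors], function(f) factor(f))
  n <- nlevels(subj)
  if (n < 3) abort("at least 3 subjects are required.")
  cell <- interaction(fac, drop = FALSE, lex.order = TRUE)
  tab <- table(subj, cell)
  if (any(tab != 1)) {
    missing_cells <- which(tab == 0, arr.ind = TRUE)
    msg <- if (nrow(missing_cells)) {
      paste0(
        "unbalanced design; missing cells: ",
        paste(utils::head(paste(rownames(tab)[missing_cells[, 1]],
                                colnames(tab)[missing_cells[, 2]],
                                sep = ":"), 10), collapse = ", ")
      )
    } else {
      "unbalanced design: duplicated subject-cell maps."
    }
    abort(msg)
  }
  M <- maps_matrix(maps, atlas)
  if (length(factors) == 1L) {
    rm_anova_one(M, subj, fac[[1]], atlas, q, factors)
  } else {
    rm_anova_two(M, subj, fac[[1]], fac[[2]], atlas, q, factors)
  }
}

f_map_from_ss <- function(ss_eff, df_eff, ss_err, df_err, atlas, q,
                          contrast, n, scale = 1) {
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  # mean squares below this are floating-point cancellation residue on
  # no-variance pixels, not real variance
  tol <- 1e-20 * (scale + 1)
  f <- numeric(length(ms_eff)); p <- numeric(length(ms_eff))
  reg <- ms_err > tol
  f[reg] <- ms_eff[reg] / ms_err[reg]
  p[reg] <- pf(f[reg], df_eff, df_err, lower.tail = FALSE)
  null0 <- !reg & ms_eff <= tol
  f[null0] <- 0; p[null0] <- 1
  degen <- !reg & ms_eff > tol
  f[degen] <- Inf; p[degen] <- 0
  new_statmap(f, p, df = c(df_eff, df_err), atlas, q, contrast, "F", n,
              sum(degen))
}

rm_anova_one <- function(M, subj, A, atlas, q, factors) {
  n <- nlevels(subj); a <- nlevels(A)
  G <- colMeans(M)
  M_A <- rowsum(M, A) / as.vector(table(A))
  M_S <- rowsum(M, subj) / as.vector(table(subj))
  iA <- as.integer(A); iS <- as.integer(subj)
  ss_a <- n * colSums(sweep(M_A, 2, G)^2)
  resid <- M - M_A[iA, , drop = FALSE] - M_S[iS, , drop = FALSE] +
    rep(G, each = nrow(M))
  ss_as <- colSums(resid^2)
  scale <- colMeans(M^2)
  out <- list(f_map_from_ss(ss_a, a - 1, ss_as, (a - 1) * (n - 1),
                            atlas, q, factors[1], n, scale))
  names(out) <- factors[1]
  out
}

rm_anova_two <- function(M, subj, A, B, atlas, q, factors) {
  n <- nlevels(subj); a <- nlevels(A); b <- nlevels(B)
  iS <- as.integer(subj); iA <- as.integer(A); iB <- as.integer(B)
  G <- colMeans(M)
  mean_by <- function(g) rowsum(M, g) / as.vector(table(g))
  M_A <- mean_by(iA); M_B <- mean_by(iB); M_S <- mean_by(iS)
  gAB <- (iA - 1L) * b + iB
  gSA <- (iS - 1L) * a + iA
  gSB <- (iS - 1L) * b + iB
  M_AB <- mean_by(gAB); M_SA <- mean_by(gSA); M_SB <- mean_by(gSB)

  ss_a <- n * b * colSums(sweep(M_A, 2, G)^2)
  ss_b <- n * a * colSums(sweep(M_B, 2, G)^2)
  # effect-by-subject error strata
  rA <- M_SA - M_A[rep(seq_len(a), times = n), , drop = FALSE] -
    M_S[rep(seq_len(n), each = a), , drop = FALSE] +
    rep(G, each = n * a)
  ss_as <- b * colSums(rA^2)
  rB <- M_SB - M_B[rep(seq_len(b), times = n), , drop = FALSE] -
    M_S[rep(seq_len(n), each = b), , drop = FALSE] +
    rep(G, each = n * b)
  ss_bs <- a * colSums(rB^2)
  rAB <- M_AB - M_A[rep(seq_len(a), each = b), , drop = FALSE] -
    M_B[rep(seq_len(b), times = a), , drop = FALSE] +
    rep(G, each = a * b)
  ss_ab <- n * colSums(rAB^2)
  rABS <- M - M_AB[gAB, , drop = FALSE] - M_SA[gSA, , drop = FALSE] -
    M_SB[gSB, , drop = FALSE] + M_A[iA, , drop = FALSE] +
    M_B[iB, , drop = FALSE] + M_S[iS, , drop = FALSE] -
    rep(G, each = nrow(M))
  ss_abs <- colSums(rABS^2)

  scale <- colMeans(M^2)
  out <- list(
    f_map_from_ss(ss_a, a - 1, ss_as, (a - 1) * (n - 1), atlas, q,
                  factors[1], n, scale),
    f_map_from_ss(ss_b, b - 1, ss_bs, (b - 1) * (n - 1), atlas, q,
                  factors[2], n, scale),
    f_map_from_ss(ss_ab, (a - 1) * (b - 1), ss_abs,
                  (a - 1) * (b - 1) * (n - 1), atlas, q,
                  paste(factors, collapse = ":"), n, scale)
  )
  names(out) <- c(factors, paste(factors, collapse = ":"))
  out
}

#' Summarize a statistical map by body region
#'
#' @param stat_map a `groove_statmap`.
#' @param atlas the atlas the map was computed on.
#' @return A tibble with, per region: the number and fraction of
#'   FDR-significant pixels, mean and peak statistic among them, and the
#'   dominant sign (for t maps).
#' @export
summarize_regions <- function(stat_map, atlas) {
  stopifnot(inherits(stat_map, "groove_statmap"),
            inherits(atlas, "groove_atlas"))
  if (!all(dim(stat_map$stat) == atlas$dims)) {
    abort("map dimensions do not match the atlas.")
  }
  reg <- factor(atlas$regions[atlas$mask], levels = bsm_regions)
  sig <- stat_map$sig[atlas$mask]
  st <- stat_map$stat[atlas$mask]
  tibble(region = reg, sig = sig, stat = st) |>
    dplyr::group_by(.data$region, .drop = FALSE) |>
    dplyr::summarise(
      region_size = dplyr::n(),
      n_sig = sum(.data$sig),
      fraction_sig = mean(.data$sig),
      mean_stat = ifelse(sum(.data$sig) > 0,
                         mean(.data$stat[.data$sig]), NA_real_),
      peak_stat = ifelse(sum(.data$sig) > 0,
                         .data$stat[.data$sig][which.max(abs(.data$stat[.data$sig]))],
                         NA_real_),
      dominant_sign = ifelse(sum(.data$sig) > 0,
                             sign(sum(sign(.data$stat[.data$sig]))), 0),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_sig))
}

#' Dice overlap between a significance mask and a planted region set
#'
#' 2|A  intersect B| / (|A| + |B|), the standard overlap score used to
#' judge recovery of planted spatial effects.
#'
#' @param sig logical matrix (e.g. `stat_map$sig`).
#' @param target logical matrix of the planted region (see [region_mask()]).
#' @return Dice coefficient in `[0, 1]` (1 when both are empty).
#' @export
dice_coefficient <- function(sig, target) {
  stopifnot(all(dim(sig) == dim(target)))
  denom <- sum(sig) + sum(target)
  if (denom == 0) return(1)
  2 * sum(sig & target) / denom
}
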