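#' Euclidean similarity matrix between stimuli
#'
#' Represents each stimulus by its vector of participant ratings for one
#' groove component and returns the stimulus-by-stimulus Euclidean distance
#' matrix (smaller distance = more similar rating profiles).
#'
#' @param table a rating table (see [simulate_ratings()] for the column
#'   contract).
#' @param component `"wanting_to_move"` or `"pleasure"`.
#' @return A symmetric numeric matrix with zero diagonal, stimulus ids as
#'   dimnames.
#' @export
similarity_matrix <- function(table, component = c("wanting_to_move", "pleasure")) {
  component <- match.arg(component)
  tab <- dplyr::filter(table, .data$component == !!component)
  wide <- tidyr::pivot_wider(
    tab[, c("participant_id", "stimulus_id", "rating")],
    names_from = "participant_id", values_from = "rating"
  )
  m <- as.matrix(wide[, -1])
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    cells <- paste(wide$stimulus_id[miss[, 1]],
                   colnames(m)[miss[, 2]], sep = ":")
    abort(paste0("missing participant x stimulus cells: ",
                 paste(utils::head(cells, 10), collapse = ", ")))
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  dimnames(d) <- list(wide$stimulus_id, wide$stimulus_id)
  d
}

check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("fixed-effect design is rank deficient; collinear term(s): ",
                 paste(dropped, collapse = ", ")))
  }
}

fit_lmer_ladder <- function(formulas, data, reml = TRUE) {
  notes <- character(0)
  fit <- NULL
  converged <- FALSE
  used <- NA_character_
  for (f in formulas) {
    ok <- TRUE
    this <- withCallingHandlers(
      lmerTest::lmer(stats::as.formula(f), data = data, REML = reml),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    singular <- lme4::isSingular(this, tol = 1e-4)
    fit <- this; used <- f
    if (ok && !singular) {
      converged <- TRUE
      break
    }
    notes <- c(notes, paste0(
      "refit after ", if (!ok) "non-convergence" else "singular fit",
      ": ", f
    ))
  }
  list(fit = fit, formula = used, converged = converged, notes = notes)
}

#' Mixed-effects model of ratings on genre, familiarity and training
#'
#' Fits `rating ~ genre + familiarity + formal + informal training` with
#' funk as the reference (treatment) level, by-participant random
#' intercepts and genre slopes, and by-stimulus random intercepts, using
#' restricted maximum likelihood. A by-stimulus genre slope is dropped up
#' front whenever genre is constant within stimulus (each track belongs to
#' one genre), which makes that slope inestimable. When a fit is singular
#' or does not converge, the model is refit down a documented ladder
#' (drop stimulus slopes, then participant slopes); every step is logged
#' on the returned object. Denominator degrees of freedom are
#' Satterthwaite's.
#'
#' @param table a rating table.
#' @param component which groove component to model.
#' @param training_interactions also include genre x training interactions.
#' @param random `"ladder"` (default) starts from the full random
#'   structure and simplifies only on singular/non-converged fits;
#'   `"intercepts"` goes straight to by-participant and by-stimulus random
#'   intercepts (useful for large calibration simulations and for
#'   likelihood-ratio tests against [fit_null_model()], which has the same
#'   random structure); `"participant_only"` keeps only the by-participant
#'   intercept (for calibration studies of data without stimulus-level
#'   heterogeneity, where the chi-square reference of the LRT is exact
#'   asymptotically in rows rather than stimuli).
#' @return A `groove_lmm` object; see [tidy.groove_lmm()] and
#'   [compare_models()].
#' @export
fit_genre_model <- function(table, component = c("wanting_to_move", "pleasure"),
                            training_interactions = FALSE,
                            random = c("ladder", "intercepts",
                                       "participant_only")) {
  component <- match.arg(component)
  random <- match.arg(random)
  tab <- dplyr::filter(table, .data$component == !!component)
  if (nrow(tab) == 0) abort("no rows for the requested component.")
  tab$genre <- stats::relevel(factor(tab$genre), ref = "funk")
  if (nlevels(tab$genre) != 3) abort("`genre` must have 3 levels.")
  fixed <- paste(
    "rating ~ genre + familiarity + formal_training_years +",
    "informal_training_years"
  )
  if (training_interactions) {
    fixed <- paste(fixed,
                   "+ genre:formal_training_years + genre:informal_training_years")
  }
  check_rank(stats::model.matrix(stats::as.formula(fixed), tab))
  genre_in_stim <- tapply(as.character(tab$genre), tab$stimulus_id,
                          function(g) length(unique(g)))
  notes <- character(0)
  ladder <- if (random == "intercepts") {
    paste(fixed, "+ (1 | participant_id) + (1 | stimulus_id)")
  } else if (random == "participant_only") {
    paste(fixed, "+ (1 | participant_id)")
  } else if (all(genre_in_stim == 1)) {
    notes <- "by-stimulus genre slope inestimable (genre constant within stimulus); dropped"
    c(
      paste(fixed, "+ (genre | participant_id) + (1 | stimulus_id)"),
      paste(fixed, "+ (1 | participant_id) + (1 | stimulus_id)")
    )
  } else {
    c(
      paste(fixed, "+ (genre | participant_id) + (genre | stimulus_id)"),
      paste(fixed, "+ (genre | participant_id) + (1 | stimulus_id)"),
      paste(fixed, "+ (1 | participant_id) + (1 | stimulus_id)")
    )
  }
  res <- fit_lmer_ladder(ladder, tab)
  structure(
    list(
      fit = res$fit, component = component, formula_label = res$formula,
      converged = res$converged, notes = c(notes, res$notes),
      model = "genre", data = tab
    ),
    class = "groove_lmm"
  )
}

#' Mixed-effects model of ratings on pulse entropy
#'
#' Regresses ratings on orthogonal-polynomial pulse entropy (linear, or
#' linear + quadratic), with formal and informal musical training as fixed
#' covariates and by-participant and by-stimulus random intercepts. The
#' entropy basis is centred and scaled (orthonormal polynomial columns,
#' stored as `entropy_lin` / `entropy_quad`); the basis coefficients are
#' attached to the returned object so predictions can be mapped back to
#' the raw entropy scale.
#'
#' @inheritParams fit_genre_model
#' @param order `"quadratic"` (default) or `"linear"`.
#' @param with_genre_interaction also include genre and its interaction
#'   with the entropy terms.
#' @return A `groove_lmm` object.
#' @export
fit_entropy_model <- function(table,
                              component = c("wanting_to_move", "pleasure"),
                              order = c("quadratic", "linear"),
                              with_genre_interaction = FALSE) {
  component <- match.arg(component)
  order <- match.arg(order)
  tab <- dplyr::filter(table, .data$component == !!component)
  if (nrow(tab) == 0) abort("no rows for the requested component.")
  if (anyNA(tab$pulse_entropy)) abort("pulse entropy missing for some rows.")
  if (length(unique(tab$pulse_entropy)) < 2) {
    abort("pulse entropy is constant across stimuli; no identifiable slope.")
  }
  deg <- if (order == "quadratic") 2L else 1L
  if (deg == 2L && length(unique(tab$pulse_entropy)) < 3) {
    abort("need at least 3 distinct entropy values for a quadratic term.")
  }
  basis <- stats::poly(tab$pulse_entropy, degree = deg)
  tab$entropy_lin <- basis[, 1]
  if (deg == 2L) tab$entropy_quad <- basis[, 2]
  ent_terms <- c("entropy_lin", if (deg == 2L) "entropy_quad")
  fixed <- paste(
    "rating ~", paste(ent_terms, collapse = " + "),
    "+ formal_training_years + informal_training_years"
  )
  if (with_genre_interaction) {
    tab$genre <- stats::relevel(factor(tab$genre), ref = "funk")
    fixed <- paste(
      fixed, "+ genre +",
      paste(paste0("genre:", ent_terms), collapse = " + ")
    )
  }
  check_rank(stats::model.matrix(stats::as.formula(fixed), tab))
  ladder <- paste(fixed, "+ (1 | participant_id) + (1 | stimulus_id)")
  res <- fit_lmer_ladder(ladder, tab)
  structure(
    list(
      fit = res$fit, component = component, formula_label = res$formula,
      converged = res$converged, notes = res$notes,
      model = "entropy", data = tab,
      poly_coefs = attr(basis, "coefs")
    ),
    class = "groove_lmm"
  )
}

#' Intercept-plus-covariates null model for likelihood-ratio comparisons
#'
#' The genre model of [fit_genre_model()] without the genre fixed effect
#' (random structure reduced to intercepts so the null is nested in any
#' rung of the genre ladder).
#'
#' @inheritParams fit_genre_model
#' @param include_familiarity keep familiarity in the null (default TRUE).
#' @param random `"intercepts"` (by-participant and by-stimulus, default)
#'   or `"participant_only"`.
#' @return A `groove_lmm` object.
#' @export
fit_null_model <- function(table, component = c("wanting_to_move", "pleasure"),
                           include_familiarity = TRUE,
                           random = c("intercepts", "participant_only")) {
  component <- match.arg(component)
  random <- match.arg(random)
  tab <- dplyr::filter(table, .data$component == !!component)
  if (nrow(tab) == 0) abort("no rows for the requested component.")
  tab$genre <- stats::relevel(factor(tab$genre), ref = "funk")
  fixed <- paste(
    "rating ~", if (include_familiarity) "familiarity +" else "",
    "formal_training_years + informal_training_years"
  )
  re <- if (random == "intercepts") {
    "+ (1 | participant_id) + (1 | stimulus_id)"
  } else {
    "+ (1 | participant_id)"
  }
  res <- fit_lmer_ladder(paste(fixed, re), tab)
  structure(
    list(
      fit = res$fit, component = component, formula_label = res$formula,
      converged = res$converged, notes = res$notes,
      model = "null", data = tab
    ),
    class = "groove_lmm"
  )
}

#' @export
print.groove_lmm <- function(x, ...) {
  cat("<groove_lmm> ", x$model, " model, ", x$component,
      if (!x$converged) " (did not fully converge)", "\n  ",
      x$formula_label, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy and glance methods for groove mixed models
#'
#' `tidy()` returns the fixed-effect table (estimate, standard error,
#' Satterthwaite df, t, p); `glance()` returns one-row model metadata.
#'
#' @param x a `groove_lmm`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.groove_lmm <- function(x, ...) {
  cs <- stats::coef(summary(x$fit))
  tibble(
    term = rownames(cs),
    estimate = unname(cs[, "Estimate"]),
    std.error = unname(cs[, "Std. Error"]),
    df = unname(cs[, "df"]),
    statistic = unname(cs[, "t value"]),
    p.value = unname(cs[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.groove_lmm
#' @export
glance.groove_lmm <- function(x, ...) {
  ll <- stats::logLik(x$fit)
  tibble(
    model = x$model, component = x$component,
    formula = x$formula_label, converged = x$converged,
    REML = lme4::isREML(x$fit),
    logLik = as.numeric(ll), df = attr(ll, "df"),
    sigma = stats::sigma(x$fit), nobs = stats::nobs(x$fit)
  )
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Refits both models by maximum likelihood (not REML) on their shared
#' data and returns the likelihood-ratio chi-square, its degrees of
#' freedom (parameter-count difference) and the upper-tail p-value.
#'
#' @param null_fit,full_fit `groove_lmm` objects fit to the same rows,
#'   with the null's terms nested in the full's.
#' @return A one-row tibble `chisq`, `df`, `p.value`.
#' @export
compare_models <- function(null_fit, full_fit) {
  stopifnot(inherits(null_fit, "groove_lmm"), inherits(full_fit, "groove_lmm"))
  if (stats::nobs(null_fit$fit) != stats::nobs(full_fit$fit)) {
    abort("models were not fit to the same data; cannot compare.")
  }
  t0 <- attr(stats::terms(stats::formula(null_fit$fit, fixed.only = TRUE)),
             "term.labels")
  t1 <- attr(stats::terms(stats::formula(full_fit$fit, fixed.only = TRUE)),
             "term.labels")
  if (!all(t0 %in% t1)) {
    abort(paste0("models are not nested; null has terms absent from full: ",
                 paste(setdiff(t0, t1), collapse = ", ")))
  }
  m0 <- refit_ml(null_fit$fit)
  m1 <- refit_ml(full_fit$fit)
  ll0 <- stats::logLik(m0); ll1 <- stats::logLik(m1)
  chisq <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  df <- attr(ll1, "df") - attr(ll0, "df")
  tibble(
    chisq = chisq, df = df,
    p.value = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1
  )
}

refit_ml <- function(fit) {
  if (!lme4::isREML(fit)) return(fit)
  suppressWarnings(suppressMessages(lme4::refitML(fit)))
}

#' Pairwise post-hoc contrasts from a fitted genre model
#'
#' Estimated-marginal-mean differences between all factor levels, with the
#' family-wise adjustment taken from the multivariate-t distribution of
#' the contrast set (the default); if that adjustment fails a Tukey-style
#' adjustment is used and labelled in the output.
#'
#' @param fit a `groove_lmm` from [fit_genre_model()].
#' @param factor_name factor to compare (default `"genre"`).
#' @param adjust `"mvt"` (default), `"tukey"`, or `"none"`.
#' @return A tibble of pairwise contrasts with adjusted p-values and an
#'   `adjust` column recording the method actually used.
#' @export
posthoc_pairwise <- function(fit, factor_name = "genre", adjust = "mvt") {
  stopifnot(inherits(fit, "groove_lmm"))
  if (!factor_name %in% names(fit$data)) {
    abort(paste0("factor `", factor_name, "` not in the model data."))
  }
  emm <- emmeans::emmeans(fit$fit, specs = factor_name,
                          lmer.df = "satterthwaite",
                          data = fit$data)
  used <- adjust
  res <- tryCatch(
    summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust)),
    error = function(e) {
      used <<- "tukey"
      summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
    }
  )
  out <- as_tibble(as.data.frame(res))
  out$adjust <- used
  out
}
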