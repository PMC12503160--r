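#' Simulate a long-format groove rating table
#'
#' Generates one row per participant x stimulus x groove component, the full
#' crossing of the study design. The latent rating is
#' intercept + genre effect + familiarity slope x (familiarity - centre) +
#' orthogonal-polynomial entropy terms + training slopes + by-participant
#' intercept and genre slopes + by-stimulus intercept + Gaussian noise; the
#' observed rating is the latent value clamped to the 1-5 scale and rounded
#' to the Likert grid. Familiarity is itself simulated per
#' (participant, stimulus) on the 1-5 grid, slightly higher for funk.
#' Participant-level random effects are shared between the two components,
#' which induces the strong positive correlation between wanting-to-move
#' and pleasure ratings seen in real data.
#'
#' @param design a [study_design()].
#' @param truth a [simulation_truth()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return A tibble with columns `participant_id`, `stimulus_id`, `genre`,
#'   `component`, `rating`, `familiarity`, `formal_training_years`,
#'   `informal_training_years`, `pulse_entropy`.
#' @examples
#' tab <- simulate_ratings(study_design(12), simulation_truth(), seed = 1)
#' dplyr::count(tab, genre, component)
#' @export
simulate_ratings <- function(design, truth, seed = 1L) {
  stopifnot(inherits(design, "groove_design"), inherits(truth, "groove_truth"))
  with_seed(seed, {
    np <- design$n_participants
    stim <- design$stimuli
    ns <- nrow(stim)
    pid <- sprintf("p%03d", seq_len(np))

    # participant covariates: zero-inflated training years
    # (means ~1.9 formal / ~2.4 informal, sd ~4, as in online samples)
    formal <- ifelse(rbinom(np, 1, 0.4) == 1, pmin(round(rexp(np, 1 / 4.85)), 25), 0)
    informal <- ifelse(rbinom(np, 1, 0.45) == 1, pmin(round(rexp(np, 1 / 5.4)), 25), 0)

    # random effects, shared across the two components
    u_int <- rnorm(np, 0, truth$random_sd$participant_intercept)
    u_jazz <- rnorm(np, 0, truth$random_sd$participant_genre_slope)
    u_rock <- rnorm(np, 0, truth$random_sd$participant_genre_slope)
    w_stim <- rnorm(ns, 0, truth$random_sd$stimulus_intercept)

    # familiarity per participant x stimulus, observed on the Likert grid
    fam_mod <- truth$familiarity
    fam_part <- rnorm(np, 0, fam_mod$participant_sd)
    base_ps <- tidyr::expand_grid(p = seq_len(np), s = seq_len(ns))
    fam_latent <- fam_mod$genre_mean[as.character(stim$genre[base_ps$s])] +
      fam_part[base_ps$p] + rnorm(nrow(base_ps), 0, fam_mod$noise_sd)
    fam_obs <- likert_observe(fam_latent, design$rating_scale)
    fam_centre <- 2.3

    rows <- tidyr::expand_grid(
      component = design$components,
      p = seq_len(np),
      s = seq_len(ns)
    )
    rows$familiarity <- fam_obs[match(
      paste(rows$p, rows$s), paste(base_ps$p, base_ps$s)
    )]
    ent <- stim$pulse_entropy[rows$s]
    genre <- stim$genre[rows$s]
    latent <- numeric(nrow(rows))
    for (comp in design$components) {
      b <- truth$fixed[[comp]]
      sel <- rows$component == comp
      # orthogonal polynomial entropy basis over this component's rows:
      # the same basis poly() builds when the model is fit per component
      ent_poly <- stats::poly(ent[sel], degree = 2)
      latent[sel] <- b$intercept +
        ifelse(genre[sel] == "jazz_funk", b$genre_jazz_funk, 0) +
        ifelse(genre[sel] == "rock", b$genre_rock, 0) +
        b$familiarity * (rows$familiarity[sel] - fam_centre) +
        b$entropy_linear * ent_poly[, 1] +
        b$entropy_quadratic * ent_poly[, 2] +
        b$formal_training * formal[rows$p[sel]] +
        b$informal_training * informal[rows$p[sel]]
    }
    latent <- latent + u_int[rows$p] +
      ifelse(genre == "jazz_funk", u_jazz[rows$p], 0) +
      ifelse(genre == "rock", u_rock[rows$p], 0) +
      w_stim[rows$s] +
      rnorm(nrow(rows), 0, truth$residual_sd)

    tibble(
      participant_id = pid[rows$p],
      stimulus_id = stim$stimulus_id[rows$s],
      genre = genre,
      component = factor(rows$component, levels = design$components),
      rating = likert_observe(latent, design$rating_scale),
      familiarity = rows$familiarity,
      formal_training_years = formal[rows$p],
      informal_training_years = informal[rows$p],
      pulse_entropy = ent
    )
  })
}
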