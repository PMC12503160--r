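#' Study design for a synthetic groove body-sensation-map experiment
#'
#' Describes the factorial layout emulated by the synthetic-data generators:
#' every participant rates every stimulus on both groove components
#' (wanting to move, pleasure) on a 1-5 Likert scale. The default stimulus
#' set is 12 excerpts, four per genre (funk, jazz funk, rock), each carrying
#' a nominal per-track pulse-entropy value. The default entropy values are
#' fixed so that genre means are funk 0.734, jazz funk 0.750, rock 0.722
#' with an overall range of 0.669-0.787, the regime typical of real groove
#' stimuli.
#'
#' @param n_participants number of simulated participants (default 108).
#' @param stimuli optional tibble with columns `stimulus_id`, `genre`
#'   (levels funk, jazz_funk, rock) and `pulse_entropy` in `[0, 1]`;
#'   defaults to the 12-stimulus set described above.
#' @return An object of class `groove_design`.
#' @export
study_design <- function(n_participants = 108L, stimuli = NULL) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    abort("`n_participants` must be a positive count.")
  }
  if (is.null(stimuli)) {
    stimuli <- tibble(
      stimulus_id = paste0(
        rep(c("funk", "jazz_funk", "rock"), each = 4), "_", rep(1:4, 3)
      ),
      genre = factor(
        rep(c("funk", "jazz_funk", "rock"), each = 4),
        levels = c("funk", "jazz_funk", "rock")
      ),
      pulse_entropy = c(
        0.697, 0.726, 0.742, 0.771,   # funk, mean 0.734
        0.713, 0.740, 0.760, 0.787,   # jazz funk, mean 0.750
        0.669, 0.711, 0.731, 0.777    # rock, mean 0.722
      )
    )
  } else {
    stimuli <- as_tibble(stimuli)
    need <- c("stimulus_id", "genre", "pulse_entropy")
    if (!all(need %in% names(stimuli))) {
      abort("`stimuli` needs columns stimulus_id, genre, pulse_entropy.")
    }
    stimuli$genre <- factor(stimuli$genre,
                            levels = c("funk", "jazz_funk", "rock"))
    if (anyNA(stimuli$genre)) {
      abort("`genre` must be one of funk, jazz_funk, rock.")
    }
    if (any(stimuli$pulse_entropy < 0 | stimuli$pulse_entropy > 1)) {
      abort("nominal pulse entropy must lie in [0, 1].")
    }
  }
  structure(
    list(
      n_participants = n_participants,
      stimuli = stimuli,
      components = c("wanting_to_move", "pleasure"),
      rating_scale = c(1L, 5L)
    ),
    class = "groove_design"
  )
}

#' @export
print.groove_design <- function(x, ...) {
  cat("<groove_design> ", x$n_participants, " participants x ",
      nrow(x$stimuli), " stimuli x ", length(x$components),
      " components\n", sep = "")
  invisible(x)
}

default_effect_regions <- function() {
  # Planted spatial ground truth (a clean double dissociation):
  #  * baseline painting everywhere, in every cell;
  #  * groove-component effect confined to arms + legs
  #    (wanting to move > pleasure, identical across genres);
  #  * genre effect confined to hips + shoulders
  #    (funk > jazz funk = rock, identical across components).
  cells <- tidyr::expand_grid(
    component = c("wanting_to_move", "pleasure"),
    genre = c("funk", "jazz_funk", "rock"),
    region = bsm_regions
  )
  cells$weight <- 0.08
  cells$coverage <- 0.10
  move_eff <- cells$component == "wanting_to_move" &
    cells$region %in% c("arms", "legs")
  funk_eff <- cells$genre == "funk" &
    cells$region %in% c("hips", "shoulders")
  cells$weight[move_eff] <- 0.90
  cells$coverage[move_eff] <- 0.50
  cells$weight[funk_eff] <- 0.90
  cells$coverage[funk_eff] <- 0.50
  cells
}

#' Generative ground truth for the synthetic study
#'
#' Collects every parameter of the generative model behind
#' [simulate_ratings()] and [simulate_strokes()]: fixed-effect coefficients
#' per groove component, random-effect standard deviations, the familiarity
#' sub-model, and the planted spatial effect regions for paintings.
#'
#' Ratings are generated from a latent Gaussian linear mixed model and then
#' observed on the 1-5 Likert grid (clamp to the scale, round to integers).
#' The default coefficients place all cell means well inside the scale so
#' that this discretisation is mild. Default genre contrasts and covariate
#' slopes follow the magnitudes reported for real groove studies
#' (jazz funk -1.21 and rock -0.91 below funk for wanting to move, -0.59
#' and -0.61 for pleasure; familiarity slopes near 1); entropy effects
#' default to zero and are switched on for rhythm-predictability studies.
#' Entropy enters through orthogonal (linear + quadratic) polynomial
#' columns computed on the generated table, the same basis used at fit time.
#'
#' @param fixed named list with one element per component
#'   (`wanting_to_move`, `pleasure`); each a named list of coefficients:
#'   `intercept`, `genre_jazz_funk`, `genre_rock`, `familiarity`,
#'   `formal_training`, `informal_training`, `entropy_linear`,
#'   `entropy_quadratic`. Missing entries keep their defaults.
#' @param random_sd named list: `participant_intercept`,
#'   `participant_genre_slope`, `stimulus_intercept` (all >= 0).
#' @param residual_sd residual standard deviation of the latent rating.
#' @param familiarity named list for the familiarity sub-model:
#'   `genre_mean` (named numeric, latent mean per genre),
#'   `participant_sd`, `noise_sd`. Familiarity is itself observed on the
#'   1-5 grid and funk is slightly more familiar by default.
#' @param effect_regions tibble with columns `component`, `genre`, `region`,
#'   `weight` (region selection probability, in `[0, 1]`) and `coverage`
#'   (target painted fraction of the region, in `[0, 1]`). Defaults plant a
#'   component effect in arms/legs and a genre (funk) effect in
#'   hips/shoulders over a uniform painting baseline.
#' @param stray_fraction fraction of stroke samples allowed to stray outside
#'   the silhouette (exercises out-of-body removal).
#' @return An object of class `groove_truth`.
#' @export
simulation_truth <- function(fixed = list(),
                             random_sd = list(),
                             residual_sd = 0.40,
                             familiarity = list(),
                             effect_regions = NULL,
                             stray_fraction = 0.02) {
  def_fixed <- list(
    wanting_to_move = list(
      intercept = 3.55, genre_jazz_funk = -1.21, genre_rock = -0.91,
      familiarity = 0.97, formal_training = 0, informal_training = 0,
      entropy_linear = 0, entropy_quadratic = 0
    ),
    pleasure = list(
      intercept = 3.30, genre_jazz_funk = -0.59, genre_rock = -0.61,
      familiarity = 0.95, formal_training = 0, informal_training = 0,
      entropy_linear = 0, entropy_quadratic = 0
    )
  )
  for (comp in names(fixed)) {
    if (!comp %in% names(def_fixed)) {
      abort(paste0("unknown component in `fixed`: ", comp))
    }
    for (nm in names(fixed[[comp]])) {
      if (!nm %in% names(def_fixed[[comp]])) {
        abort(paste0("unknown coefficient `", nm, "` for component ", comp))
      }
      def_fixed[[comp]][[nm]] <- fixed[[comp]][[nm]]
    }
  }
  def_rand <- list(
    participant_intercept = 0.30,
    participant_genre_slope = 0.15,
    stimulus_intercept = 0.20
  )
  for (nm in names(random_sd)) {
    if (!nm %in% names(def_rand)) {
      abort(paste0("unknown random-effect sd: ", nm))
    }
    def_rand[[nm]] <- random_sd[[nm]]
  }
  def_fam <- list(
    genre_mean = c(funk = 2.47, jazz_funk = 2.09, rock = 2.22),
    participant_sd = 0.15,
    noise_sd = 0.30
  )
  for (nm in names(familiarity)) {
    if (!nm %in% names(def_fam)) {
      abort(paste0("unknown familiarity parameter: ", nm))
    }
    def_fam[[nm]] <- familiarity[[nm]]
  }
  all_coef <- unlist(def_fixed)
  if (any(!is.finite(all_coef))) abort("fixed-effect coefficients must be finite.")
  sds <- c(unlist(def_rand), residual_sd,
           def_fam$participant_sd, def_fam$noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("standard deviations must be finite and non-negative.")
  }
  effect_regions <- if (is.null(effect_regions)) {
    default_effect_regions()
  } else {
    er <- as_tibble(effect_regions)
    need <- c("component", "genre", "region", "weight", "coverage")
    if (!all(need %in% names(er))) {
      abort("`effect_regions` needs columns component, genre, region, weight, coverage.")
    }
    if (any(er$weight < 0)) abort("region weights must be >= 0.")
    if (any(er$coverage < 0 | er$coverage > 1)) {
      abort("coverage fractions must lie in [0, 1].")
    }
    bad <- setdiff(unique(er$region), bsm_regions)
    if (length(bad)) {
      abort(paste0("effect_regions reference unknown regions: ",
                   paste(bad, collapse = ", ")))
    }
    er
  }
  if (stray_fraction < 0 || stray_fraction > 1) {
    abort("`stray_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      fixed = def_fixed,
      random_sd = def_rand,
      residual_sd = residual_sd,
      familiarity = def_fam,
      effect_regions = effect_regions,
      stray_fraction = stray_fraction
    ),
    class = "groove_truth"
  )
}

#' @export
print.groove_truth <- function(x, ...) {
  cat("<groove_truth>\n  genre (wanting to move): jazz_funk ",
      x$fixed$wanting_to_move$genre_jazz_funk, ", rock ",
      x$fixed$wanting_to_move$genre_rock,
      "\n  residual sd ", x$residual_sd, "\n", sep = "")
  invisible(x)
}
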