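#' Median split of stimuli by mean familiarity
#'
#' Groups stimuli into low/high familiarity by a median split on the
#' per-stimulus mean familiarity; stimuli tied with the median go to the
#' low bin.
#'
#' @param stimulus_means tibble with columns `stimulus_id` and
#'   `familiarity` (one mean per stimulus).
#' @return A tibble `stimulus_id`, `familiarity_bin` (factor low/high).
#' @examples
#' split_familiarity(tibble::tibble(stimulus_id = letters[1:4],
#'                                  familiarity = 1:4))
#' @export
split_familiarity <- function(stimulus_means) {
  stimulus_means <- as_tibble(stimulus_means)
  if (!all(c("stimulus_id", "familiarity") %in% names(stimulus_means))) {
    abort("`stimulus_means` needs columns stimulus_id and familiarity.")
  }
  if (anyDuplicated(stimulus_means$stimulus_id)) {
    abort("one familiarity mean per stimulus, please.")
  }
  if (nrow(stimulus_means) < 2) abort("at least 2 stimuli are required.")
  med <- median(stimulus_means$familiarity)
  bin <- ifelse(stimulus_means$familiarity <= med, "low", "high")
  if (all(bin == "low")) {
    warn("all stimulus familiarity means are at or below the median; high bin is empty.")
  }
  tibble(
    stimulus_id = stimulus_means$stimulus_id,
    familiarity_bin = factor(bin, levels = c("low", "high"))
  )
}

#' Tertile split of stimuli by pulse entropy
#'
#' Ranks stimuli by entropy and cuts into three bins (low, medium, high).
#' When the stimulus count is not divisible by three, the remainder goes to
#' the medium bin. Ties are broken by input order.
#'
#' @param stimulus_entropy tibble with columns `stimulus_id` and
#'   `pulse_entropy` (one value per stimulus).
#' @return A tibble `stimulus_id`, `entropy_bin` (factor low/medium/high).
#' @export
split_entropy <- function(stimulus_entropy) {
  stimulus_entropy <- as_tibble(stimulus_entropy)
  if (!all(c("stimulus_id", "pulse_entropy") %in% names(stimulus_entropy))) {
    abort("`stimulus_entropy` needs columns stimulus_id and pulse_entropy.")
  }
  if (anyDuplicated(stimulus_entropy$stimulus_id)) {
    abort("one entropy value per stimulus, please.")
  }
  n <- nrow(stimulus_entropy)
  if (n < 3) abort("at least 3 stimuli are required.")
  k <- n %/% 3
  sizes <- c(low = k, medium = k + n %% 3, high = k)
  rk <- rank(stimulus_entropy$pulse_entropy, ties.method = "first")
  bin <- character(n)
  bin[rk <= sizes["low"]] <- "low"
  bin[rk > sizes["low"] & rk <= sizes["low"] + sizes["medium"]] <- "medium"
  bin[rk > sizes["low"] + sizes["medium"]] <- "high"
  tibble(
    stimulus_id = stimulus_entropy$stimulus_id,
    entropy_bin = factor(bin, levels = c("low", "medium", "high"))
  )
}
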