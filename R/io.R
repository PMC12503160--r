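#' Read and write stroke logs and rating tables
#'
#' Stroke logs are CSV with header columns `participant_id`, `stimulus_id`,
#' `component`, `t_ms`, `x_px`, `y_px`, `brush_px`; pixel coordinates are
#' 0-based with origin at the top-left corner, x rightward, y downward.
#' Rating tables are CSV with the columns produced by
#' [simulate_ratings()].
#'
#' @param path file path.
#' @param strokes,table the tibble to write.
#' @return Readers return a validated tibble; writers return `path`
#'   invisibly.
#' @export
read_stroke_log <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "stimulus_id", "component", "t_ms",
            "x_px", "y_px", "brush_px")
  if (!all(need %in% names(out))) {
    abort(paste0("stroke log must have columns ",
                 paste(need, collapse = ", ")))
  }
  if (any(out$brush_px <= 0)) abort("brush radius must be positive.")
  ord <- order(out$participant_id, out$stimulus_id, out$component, out$t_ms)
  out[ord, need]
}

#' @rdname read_stroke_log
#' @export
write_stroke_log <- function(strokes, path) {
  readr::write_csv(strokes, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_stroke_log
#' @export
read_rating_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "stimulus_id", "genre", "component", "rating",
            "familiarity", "formal_training_years", "informal_training_years",
            "pulse_entropy")
  if (!all(need %in% names(out))) {
    abort(paste0("rating table must have columns ",
                 paste(need, collapse = ", ")))
  }
  out$genre <- factor(out$genre, levels = c("funk", "jazz_funk", "rock"))
  out$component <- factor(out$component,
                          levels = c("wanting_to_move", "pleasure"))
  bad <- !out$rating %in% 1:5 | !out$familiarity %in% 1:5
  if (any(bad)) abort("ratings and familiarity must lie on the 1-5 grid.")
  out[, need]
}

#' @rdname read_stroke_log
#' @export
write_rating_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Write a silhouette atlas as PNG images plus a JSON legend
#'
#' The mask PNG is white inside the body, black outside. The region PNG
#' encodes each region as a distinct gray level, mapped to region names by
#' the JSON legend written alongside.
#'
#' @param atlas a [make_silhouette()] atlas.
#' @param dir output directory (created if missing).
#' @return Paths of the three files, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "groove_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_path <- file.path(dir, "mask.png")
  png::writePNG(atlas$mask * 1, mask_path)
  levels <- seq_along(bsm_regions) / (length(bsm_regions) + 1)
  lab <- matrix(0, atlas$dims[1], atlas$dims[2])
  for (i in seq_along(bsm_regions)) {
    lab[!is.na(atlas$regions) & atlas$regions == bsm_regions[i]] <- levels[i]
  }
  regions_path <- file.path(dir, "regions.png")
  png::writePNG(lab, regions_path)
  legend_path <- file.path(dir, "regions.json")
  jsonlite::write_json(
    setNames(as.list(round(levels * 255)), bsm_regions),
    legend_path, auto_unbox = TRUE
  )
  invisible(c(mask_path, regions_path, legend_path))
}

#' Read a silhouette atlas back from PNGs and legend
#'
#' @param dir directory written by [write_atlas()].
#' @return A `groove_atlas`.
#' @export
read_atlas <- function(dir) {
  mask <- png::readPNG(file.path(dir, "mask.png")) > 0.5
  lab <- round(png::readPNG(file.path(dir, "regions.png")) * 255)
  legend <- jsonlite::read_json(file.path(dir, "regions.json"))
  regions <- matrix(NA_character_, nrow(mask), ncol(mask))
  for (nm in names(legend)) {
    regions[lab == legend[[nm]] & mask] <- nm
  }
  structure(
    list(mask = mask, regions = regions,
         dims = c(rows = nrow(mask), cols = ncol(mask))),
    class = "groove_atlas"
  )
}

#' Write and read a statistical map as TSV matrices plus a JSON sidecar
#'
#' `stat.tsv`, `p.tsv` and `sig.tsv` hold the full pixel grids
#' (tab-separated, one row per pixel row, NA outside the mask); the JSON
#' sidecar records df, q, the critical p, the contrast label and subject
#' count.
#'
#' @param stat_map a `groove_statmap`.
#' @param dir output directory.
#' @return `write_statmap()` returns `dir` invisibly; `read_statmap()`
#'   returns a `groove_statmap`.
#' @export
write_statmap <- function(stat_map, dir) {
  stopifnot(inherits(stat_map, "groove_statmap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) {
    utils::write.table(m, file.path(dir, f), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  wr(stat_map$stat, "stat.tsv")
  wr(stat_map$p, "p.tsv")
  wr(stat_map$sig * 1L, "sig.tsv")
  jsonlite::write_json(
    list(
      statistic = stat_map$statistic, contrast = stat_map$contrast,
      df = stat_map$df, q = stat_map$q, critical_p = stat_map$critical_p,
      n_subjects = stat_map$n_subjects, n_flagged = stat_map$n_flagged
    ),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_statmap
#' @export
read_statmap <- function(dir) {
  rd <- function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  stat <- unname(rd("stat.tsv"))
  p <- unname(rd("p.tsv"))
  sig <- unname(rd("sig.tsv")) == 1
  sig[is.na(sig)] <- FALSE
  structure(
    list(
      stat = stat, p = p, sig = sig, df = meta$df, q = meta$q,
      critical_p = meta$critical_p, statistic = meta$statistic,
      contrast = meta$contrast, n_subjects = meta$n_subjects,
      n_flagged = meta$n_flagged
    ),
    class = "groove_statmap"
  )
}

#' Batch pulse-entropy table for a directory of WAV files
#'
#' Runs [pulse_entropy()] on every `.wav` file and returns (and optionally
#' writes) the per-stimulus entropy table consumed by the rating models.
#'
#' @param audio_dir directory of mono 16-bit PCM WAV files; the stimulus id
#'   is the file name without extension.
#' @param out optional TSV path to write.
#' @param ... passed to [pulse_entropy()].
#' @return A tibble `stimulus_id`, `pulse_entropy`.
#' @export
pulse_entropy_batch <- function(audio_dir, out = NULL, ...) {
  files <- sort(list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE))
  if (!length(files)) abort("no .wav files found.")
  res <- tibble(
    stimulus_id = sub("\\.wav$", "", basename(files)),
    pulse_entropy = vapply(
      files, function(f) pulse_entropy(read_wav(f), ...)$entropy, numeric(1),
      USE.NAMES = FALSE
    )
  )
  if (!is.null(out)) {
    readr::write_tsv(res, out, progress = FALSE)
  }
  res
}
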