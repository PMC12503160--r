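#' Plot a statistical body map
#'
#' Heat map of the statistic over the silhouette, masked to FDR-significant
#' pixels (non-significant in-body pixels are drawn dark, as in standard
#' body-sensation-map figures). t maps use a diverging palette centred on
#' zero so the sign shows the direction of the contrast.
#'
#' @param object a `groove_statmap`.
#' @param only_significant dim non-significant pixels (default TRUE).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.groove_statmap <- function(object, only_significant = TRUE, ...) {
  d <- tidy(object)
  if (only_significant) d$stat[!d$sig] <- NA
  d$stat[is.infinite(d$stat)] <- NA
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$stat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0(object$statistic, " map: ", object$contrast),
      subtitle = paste0("q = ", object$q, ", ", sum(object$sig),
                        " significant px"),
      fill = object$statistic
    ) +
    ggplot2::theme_void()
  if (object$statistic == "t") {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "grey20",
                                      high = "red", na.value = "grey90")
  } else {
    p + ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey90")
  }
}

#' Plot a paint map
#'
#' @param maps a paint-map tibble (one or more rows); each map becomes a
#'   facet labelled by its trial identifiers.
#' @param max_maps upper bound on facets drawn (default 12).
#' @return A ggplot object.
#' @export
plot_paint_maps <- function(maps, max_maps = 12) {
  maps <- utils::head(maps, max_maps)
  key_cols <- intersect(
    c("participant_id", "stimulus_id", "component", "genre"), names(maps)
  )
  d <- purrr::map_dfr(seq_len(nrow(maps)), function(i) {
    g <- maps$grid[[i]]
    idx <- which(g > 0, arr.ind = TRUE)
    lab <- paste(unlist(maps[i, key_cols]), collapse = " / ")
    if (nrow(idx) == 0) {
      return(tibble(row = NA_integer_, col = NA_integer_,
                    value = NA_real_, map = lab))
    }
    tibble(row = idx[, 1], col = idx[, 2], value = g[idx], map = lab)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~map) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_void()
}

#' Plot a stimulus similarity matrix
#'
#' @param sim matrix from [similarity_matrix()].
#' @return A ggplot object; redder cells are more similar (smaller
#'   Euclidean distance).
#' @export
plot_similarity <- function(sim) {
  d <- as.data.frame(as.table(sim))
  names(d) <- c("a", "b", "distance")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b,
                                  fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "red", high = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Euclidean\ndistance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
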