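# ggplot2 displays for annotation and discovery results.

#' Element structure diagram
#'
#' Draws the LTR pair, internal region, PBS, PPT and promoter boxes of an
#' annotated family along the consensus coordinate.
#'
#' @param object A `trim_annotation`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @method autoplot trim_annotation
autoplot.trim_annotation <- function(object, ...) {
  rows <- list(
    tibble(feature = "LTR", start = object$ltr5[1], end = object$ltr5[2]),
    tibble(feature = "internal", start = object$internal[1], end = object$internal[2]),
    tibble(feature = "LTR", start = object$ltr3[1], end = object$ltr3[2])
  )
  if (!is.null(object$pbs)) {
    rows <- c(rows, list(tibble(feature = "PBS",
                                start = object$internal[1] + object$pbs$start,
                                end = object$internal[1] + object$pbs$end)))
  }
  if (!is.null(object$ppt)) {
    rows <- c(rows, list(tibble(feature = "PPT",
                                start = object$internal[1] + object$ppt[1],
                                end = object$internal[1] + object$ppt[2])))
  }
  if (!is.null(object$boxes) && object$boxes$promoter_type != "none") {
    for (bx in intersect(c("boxA", "boxB", "IE", "boxC"), names(object$boxes))) {
      b <- object$boxes[[bx]]
      rows <- c(rows, list(tibble(feature = bx,
                                  start = object$ltr5[1] + b$start,
                                  end = object$ltr5[1] + b$end)))
    }
  }
  df <- bind_rows(rows)
  df$track <- ifelse(df$feature %in% c("LTR", "internal"), 1, 2)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$track - 0.35,
                                    ymax = .data$track + 0.35,
                                    fill = .data$feature)) +
    ggplot2::scale_y_continuous(breaks = c(1, 2),
                                labels = c("element", "features"),
                                limits = c(0.5, 2.5)) +
    ggplot2::labs(x = "consensus position (bp)", y = NULL,
                  title = sprintf("%s (%s)", object$family_id, object$family_class)) +
    ggplot2::theme_minimal()
}

#' Copy-number overview of a discovery run
#'
#' Bar chart of full-length LTR, internal and solo-LTR counts per family.
#'
#' @param object A `trim_discovery`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @method autoplot trim_discovery
autoplot.trim_discovery <- function(object, ...) {
  stopifnot(nrow(object$counts) > 0)
  df <- tidyr::pivot_longer(
    select(object$counts, "family_id", "ltr_full", "internal_full", "solo_ltr"),
    -"family_id", names_to = "category", values_to = "count"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id, y = .data$count,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "copies", fill = NULL) +
    ggplot2::theme_minimal()
}
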