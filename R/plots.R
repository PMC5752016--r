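# Diagnostic plots.

#' Plot a candidate call: DEM against the catalog background
#'
#' Side-by-side bars of the query's distribution of expression maxima and the
#' all-genes background, with flagged categories marked.
#'
#' @param object A `candidate_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_call <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0L) stop("no DEM to plot (no cataloged matches)")
  long <- tidyr::pivot_longer(d, c("dem_pct", "background_pct"),
                              names_to = "series", values_to = "pct")
  long$series <- ifelse(long$series == "dem_pct", "query DEM", "background")
  long$category <- factor(long$category, levels = d$category)
  flagged <- object$flagged_categories
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$pct,
                                     fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(data = d[d$category %in% flagged, ],
                        ggplot2::aes(x = .data$category, y = 2),
                        inherit.aes = FALSE, shape = 8) +
    ggplot2::labs(x = NULL, y = "% of genes", fill = NULL,
                  title = sprintf("%s (%d matching promoters, %d/%d votes)",
                                  object$query, object$n_matches,
                                  object$votes, object$n_backgrounds)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a trained ensemble: positives in feature space by network
#'
#' Positives are drawn in the (Bowley skewness, order p-value) plane, colored
#' by the first network that categorizes them; random training points are
#' shown in grey.
#'
#' @param object A `cng_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cng_ensemble <- function(object, ...) {
  pos <- tibble::as_tibble(object$ts$pos)
  pos$network <- "uncategorized"
  for (i in rev(seq_along(object$members))) {
    pos$network[object$members[[i]]] <- paste0("network ", i)
  }
  rand <- tibble::as_tibble(object$ts$rand)
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$bowley, y = .data$order_p,
                                         colour = .data$network)) +
    ggplot2::geom_point(size = 2)
  if (nrow(rand) > 0L) {
    p <- p + ggplot2::geom_point(data = rand, colour = "grey70", size = 1,
                                 inherit.aes = FALSE,
                                 ggplot2::aes(x = .data$bowley, y = .data$order_p))
  }
  p + ggplot2::labs(x = "Bowley skewness", y = "order-test p-value",
                    colour = NULL) +
    ggplot2::theme_minimal()
}
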