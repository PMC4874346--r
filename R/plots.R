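# Plot-data exports and ggplot2 views of ranks, yearly series and
# dilution profiles.

#' Rank-by-species boxplot
#'
#' @param ranks A `bka_ranks` (the deduplicated view is plotted) or a tibble
#'   with `species` and `rank`.
#' @return A ggplot.
#' @export
plot_rank_by_species <- function(ranks) {
  df <- if (inherits(ranks, "bka_ranks")) ranks$dedup else
    tibble::as_tibble(ranks)
  counts <- dplyr::count(df, .data$species)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$rank)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::geom_text(data = counts,
                       ggplot2::aes(x = .data$species, y = 8.4,
                                    label = .data$n),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 8.6),
                                breaks = seq(0, 8, 2)) +
    ggplot2::labs(x = NULL, y = "BKA rank") +
    ggplot2::theme_minimal()
}

#' Rank-by-sampling-year boxplot for one species
#'
#' @param ranks A `bka_ranks` or tibble with `species`, `sampling_year`,
#'   `rank` (all samples, not deduplicated — the yearly view asks about
#'   storage, not individuals).
#' @param species Species to plot.
#' @return A ggplot.
#' @export
plot_rank_by_year <- function(ranks, species) {
  df <- if (inherits(ranks, "bka_ranks")) ranks$ranks else
    tibble::as_tibble(ranks)
  df <- df[df$species == species, ]
  if (nrow(df) == 0) stop("no samples for species ", species, call. = FALSE)
  counts <- dplyr::count(df, .data$sampling_year)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$sampling_year),
                                   y = .data$rank)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::geom_text(data = counts,
                       ggplot2::aes(x = factor(.data$sampling_year),
                                    y = 8.4, label = .data$n),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = "sampling year", y = "BKA rank", title = species) +
    ggplot2::theme_minimal()
}

#' Species mean dilution-profile curves
#'
#' @param profiles A `bka_profiles` tibble.
#' @return A ggplot of mean capacity against dilution rank index.
#' @export
plot_dilution_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$rank_index,
                               y = .data$mean_capacity,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:8,
                                labels = paste0("1:", RANKED_DILUTIONS)) +
    ggplot2::labs(x = "serum dilution", y = "mean killing capacity (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bka_ranks <- function(object, ...) plot_rank_by_species(object)

#' @export
autoplot.bka_profiles <- function(object, ...) plot_dilution_profiles(object)

#' @export
plot.bka_tree <- function(x, ...) {
  plot(ape::as.phylo(x$hclust), ...)
  invisible(x)
}

#' Boxplot-data export (per species or per year)
#'
#' Emits the five-number summaries and outlier lists that the rank boxplots
#' draw, as a plain tibble suitable for CSV export.
#'
#' @param ranks A `bka_ranks` or tibble with `rank` and the grouping column.
#' @param by Grouping column, `"species"` (default, deduplicated view when
#'   available) or `"sampling_year"`.
#' @return A tibble with n, quartiles, whiskers and outliers per group.
#' @export
boxplot_data <- function(ranks, by = c("species", "sampling_year")) {
  by <- match.arg(by)
  df <- if (inherits(ranks, "bka_ranks")) {
    if (by == "species") ranks$dedup else ranks$ranks
  } else tibble::as_tibble(ranks)
  df %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$rank, 0.25),
      median = stats::median(.data$rank),
      q3 = stats::quantile(.data$rank, 0.75),
      lower_whisker = min(.data$rank[.data$rank >=
        stats::quantile(.data$rank, 0.25) - 1.5 * stats::IQR(.data$rank)]),
      upper_whisker = max(.data$rank[.data$rank <=
        stats::quantile(.data$rank, 0.75) + 1.5 * stats::IQR(.data$rank)]),
      outliers = paste(.data$rank[.data$rank < lower_whisker |
                                    .data$rank > upper_whisker],
                       collapse = ";"),
      .groups = "drop"
    )
}
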