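#' Boxplots of within-gene rate differences against rice
#'
#' Mirrors the classic presentation of lineage-rate comparisons: per-gene
#' rate differences (species minus rice) for each Pooideae species, shown
#' for all genes and for the LTI subset side by side.
#'
#' @param rates Lineage-rate tibble with an `is_lti` column.
#' @param metric `"dN"`, `"dS"` or `"gtr"`.
#' @return A ggplot object.
#' @export
plot_rate_differences <- function(rates, metric = c("dN", "dS", "gtr")) {
  metric <- match.arg(metric)
  species <- c("brachypodium", "wheat", "barley", "lolium", "festuca")
  diffs <- purrr::map_dfr(species, function(sp) {
    d <- rate_difference(rates, sp, metric = metric)
    d$species <- sp
    d
  })
  lti <- rates |> dplyr::distinct(.data$gene_id, .data$is_lti)
  diffs <- dplyr::left_join(diffs, lti, by = "gene_id") |>
    dplyr::mutate(subset = ifelse(.data$is_lti, "LTI", "all"))
  both <- dplyr::bind_rows(diffs,
                           dplyr::mutate(diffs, subset = "all"))
  both <- dplyr::distinct(both)
  ggplot2::ggplot(dplyr::filter(both, !is.na(.data$subset)),
                  ggplot2::aes(x = factor(.data$species, levels = species),
                               y = .data$difference,
                               fill = .data$subset)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::scale_fill_manual(values = c(all = "white", LTI = "grey60")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = paste0(metric, " difference vs rice"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Likelihood-ratio distributions by gene subset
#'
#' Empirical cumulative distributions of the branch-site likelihood ratios
#' for the LTI subset versus all genes, per foreground branch.
#'
#' @param selection Result tibble from [test_selection()].
#' @param labels Tibble `gene_id`, `is_lti`.
#' @return A ggplot object.
#' @export
plot_lr_distributions <- function(selection, labels) {
  d <- selection |>
    dplyr::filter(!.data$skipped) |>
    dplyr::left_join(labels, by = "gene_id") |>
    dplyr::mutate(subset = ifelse(.data$is_lti, "LTI", "all"))
  d <- dplyr::bind_rows(d, dplyr::mutate(d, subset = "all")) |>
    dplyr::distinct()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lr, colour = .data$subset)) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~foreground) +
    ggplot2::labs(x = "likelihood ratio", y = "ECDF", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.grasselect_run <- function(object, ...) {
  plot_rate_differences(object$rates, metric = "dN")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
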