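#' Remove implausible rate estimates
#'
#' Drops (gene, species) rows whose synonymous rate exceeds 2 or whose
#' nonsynonymous rate exceeds 0.5 substitutions per site — strict
#' inequalities, so dS = 2.0 or dN = 0.5 exactly are kept. Such estimates
#' typically indicate saturation or alignment problems. The filter is
#' idempotent.
#'
#' @param rates Tibble with columns `dS` and `dN` (e.g. from
#'   [lineage_rates()]).
#' @param ds_max,dn_max Outlier bounds.
#' @return The kept rows.
#' @examples
#' filter_outliers(tibble::tibble(dS = c(2, 2.1), dN = c(0.5, 0.1)))
#' @export
filter_outliers <- function(rates, ds_max = 2, dn_max = 0.5) {
  dplyr::filter(rates, !(.data$dS > ds_max | .data$dN > dn_max))
}

#' Within-gene rate difference against a reference lineage
#'
#' For each gene, subtracts the reference species' rate from the focal
#' species' rate (or, for `species = "core_pooideae"`, from the mean rate
#' over the core Pooideae species present in that gene). Genes lacking the
#' focal species/group or the reference are skipped. Comparing rates within
#' genes cancels gene-level effects such as functional constraint.
#'
#' @param rates Lineage-rate tibble (`gene_id`, `species`, metric columns).
#' @param species Focal species name, or `"core_pooideae"`.
#' @param reference Reference species (default `"rice"`).
#' @param metric One of `"gtr"`, `"dS"`, `"dN"`.
#' @return Tibble `gene_id`, `difference` (one row per usable gene), with
#'   the focal/reference naming in attributes.
#' @export
rate_difference <- function(rates, species, reference = "rice",
                            metric = c("gtr", "dS", "dN")) {
  metric <- match.arg(metric)
  col <- c(gtr = "gtr_distance", dS = "dS", dN = "dN")[[metric]]
  cp <- c("wheat", "barley", "lolium", "festuca")
  ref <- rates |>
    dplyr::filter(.data$species == reference) |>
    dplyr::select("gene_id", ref_value = dplyr::all_of(col))
  focal <- if (identical(species, "core_pooideae")) {
    rates |>
      dplyr::filter(.data$species %in% cp) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(value = mean(.data[[col]]), .groups = "drop")
  } else {
    rates |>
      dplyr::filter(.data$species == !!species) |>
      dplyr::select("gene_id", value = dplyr::all_of(col))
  }
  out <- dplyr::inner_join(focal, ref, by = "gene_id") |>
    dplyr::transmute(gene_id = .data$gene_id,
                     difference = .data$value - .data$ref_value)
  attr(out, "species") <- species
  attr(out, "reference") <- reference
  attr(out, "metric") <- metric
  out
}

#' Subset-versus-background resampling test
#'
#' Compares a statistic of the values belonging to a gene subset against
#' its distribution over random subsets of the same size drawn (without
#' replacement) from the full gene pool, subset included. The one-sided
#' P-value is the proportion of resamples whose statistic is equal to or
#' more extreme than the observed one.
#'
#' @param values Named numeric vector (names = gene ids), or a numeric
#'   vector with `ids` supplied.
#' @param subset_ids Gene ids forming the subset of interest.
#' @param statistic `"median"`, `"third_quartile"`, or `"proportion_true"`
#'   (for logical values), or a function.
#' @param n_resamples Number of resampled subsets (default 50000).
#' @param tail `"greater"` (default) or `"less"`.
#' @param ids Optional ids when `values` is unnamed.
#' @param plus_one When `TRUE`, uses the (r + 1)/(n + 1) correction instead
#'   of the plain proportion.
#' @param seed Optional seed applied locally.
#' @return A `resampling_result`: list with `statistic`, `observed`,
#'   `n_resamples`, `p_value` and the null `draws`.
#' @examples
#' v <- setNames(c(1, 2, 3, 10, 11, 12), paste0("g", 1:6))
#' resample_pvalue(v, c("g4", "g5"), "median", n_resamples = 1000, seed = 1)
#' @export
resample_pvalue <- function(values, subset_ids,
                            statistic = c("median", "third_quartile",
                                          "proportion_true"),
                            n_resamples = 50000, tail = c("greater", "less"),
                            ids = NULL, plus_one = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(ids)) names(values) <- ids
  stopifnot(!is.null(names(values)))
  stat_name <- if (is.function(statistic)) "custom" else match.arg(statistic)
  stat_fun <- if (is.function(statistic)) statistic else switch(stat_name,
    median = function(x) median(x),
    third_quartile = function(x) unname(quantile(x, 0.75)),
    proportion_true = function(x) mean(as.logical(x)))
  sub <- values[names(values) %in% subset_ids]
  if (length(sub) == 0) stop("empty subset", call. = FALSE)
  k <- length(sub)
  n <- length(values)
  stopifnot(k <= n)
  observed <- stat_fun(as.numeric(sub))
  x <- as.numeric(values)
  draws <- vapply(seq_len(n_resamples),
                  function(i) stat_fun(x[sample.int(n, k)]), numeric(1))
  extreme <- if (tail == "greater") sum(draws >= observed)
             else sum(draws <= observed)
  p <- if (plus_one) (extreme + 1) / (n_resamples + 1)
       else extreme / n_resamples
  structure(list(statistic = stat_name, observed = observed,
                 subset_size = k, pool_size = n,
                 n_resamples = n_resamples, tail = tail,
                 p_value = p, draws = draws),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("Resampling test (", x$statistic, ", ", x$tail, " tail)\n",
      "  subset ", x$subset_size, " of ", x$pool_size,
      ", observed = ", format(x$observed, digits = 5),
      ", mean resampled = ", format(mean(x$draws), digits = 5), "\n",
      "  P = ", format(x$p_value, digits = 4),
      "  (", x$n_resamples, " resamples)\n", sep = "")
  invisible(x)
}

#' @export
glance.resampling_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 resampled_mean = mean(x$draws),
                 subset_size = x$subset_size, pool_size = x$pool_size,
                 n_resamples = x$n_resamples, p_value = x$p_value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()] (`method = "fdr"`), with
#' input validation.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, order-preserving and bounded by 1.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "fdr")
}

#' Enrichment of significant selection tests in a gene subset
#'
#' Calls significance once over all genes jointly (FDR-adjusted p below
#' `alpha`), then compares the proportion of significant genes in the LTI
#' subset against random subsets of the same size via
#' [resample_pvalue()] with the proportion statistic, separately per
#' foreground branch. Optionally the FDR adjustment can be recomputed
#' within every resampled subset instead (`recompute_fdr = TRUE`); the
#' default inherits the global calls, so the null does not depend on
#' subset-specific rank structure.
#'
#' @param results Tibble from [test_selection()] (needs `gene_id`,
#'   `foreground`, `p_value`, `q_value`, `skipped`).
#' @param labels Tibble `gene_id`, `is_lti`.
#' @param alpha Significance level on the adjusted p-values.
#' @param n_resamples,seed Passed to [resample_pvalue()].
#' @param recompute_fdr Recompute FDR within each resample.
#' @return Tibble with one row per foreground branch: counts, proportions
#'   and the resampling P-value.
#' @export
selection_enrichment <- function(results, labels, alpha = 0.05,
                                 n_resamples = 50000, seed = NULL,
                                 recompute_fdr = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  lti_ids <- labels$gene_id[labels$is_lti]
  purrr::map_dfr(unique(results$foreground), function(fgb) {
    res <- dplyr::filter(results, .data$foreground == fgb, !.data$skipped)
    sig <- setNames(res$q_value < alpha, res$gene_id)
    in_lti <- res$gene_id %in% lti_ids
    if (!any(in_lti)) {
      return(tibble::tibble(
        foreground = fgb, n_tested = nrow(res), n_significant = sum(sig),
        n_lti = 0L, n_lti_significant = 0L, prop_lti = NA_real_,
        prop_all = mean(sig), resampling_p = NA_real_))
    }
    if (recompute_fdr) {
      raw <- setNames(res$p_value, res$gene_id)
      k <- sum(in_lti)
      obs <- mean(fdr_adjust(raw[in_lti]) < alpha)
      draws <- vapply(seq_len(n_resamples), function(i) {
        mean(fdr_adjust(raw[sample.int(length(raw), k)]) < alpha)
      }, numeric(1))
      p <- mean(draws >= obs)
      rs <- list(observed = obs, p_value = p)
    } else {
      rs <- resample_pvalue(sig, lti_ids, "proportion_true",
                            n_resamples = n_resamples)
      rs <- list(observed = rs$observed, p_value = rs$p_value)
    }
    tibble::tibble(
      foreground = fgb,
      n_tested = nrow(res),
      n_significant = sum(sig),
      n_lti = sum(in_lti),
      n_lti_significant = sum(sig & in_lti),
      prop_lti = mean(sig[in_lti]),
      prop_all = mean(sig),
      resampling_p = rs$p_value)
  })
}
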