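#' Pipeline configuration
#'
#' Collects the thresholds and sizes used by [run_pipeline()]. The defaults
#' are the canonical analysis settings: long-branch factor 3, outlier
#' bounds dS > 2 / dN > 0.5, significance level 0.05 on FDR-adjusted
#' p-values, posterior cutoff 0.9 for selected sites, four omega2 starting
#' values (0.5, 1, 1.5, 2), and 50000 resamples.
#'
#' @param sim A [sim_config()] describing the synthetic dataset (used by the
#'   simulate stage).
#' @param foregrounds Foreground branches to test.
#' @param long_branch_factor,ds_max,dn_max,alpha Analysis thresholds.
#' @param posterior_cutoff,omega2_starts,n_resamples Analysis settings.
#' @param qc_max_iter Cap on taxon-dropping re-entries of the tree stage.
#' @param seed Seed for the resampling stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       foregrounds = c("BP_ancestral", "CP_stem"),
                       long_branch_factor = 3,
                       ds_max = 2, dn_max = 0.5,
                       alpha = 0.05, posterior_cutoff = 0.9,
                       omega2_starts = c(0.5, 1, 1.5, 2),
                       n_resamples = 50000, qc_max_iter = 5L,
                       seed = 1L) {
  stopifnot(long_branch_factor > 0, ds_max > 0, dn_max > 0,
            alpha > 0, alpha < 1, posterior_cutoff > 0,
            posterior_cutoff <= 1, n_resamples >= 1)
  structure(list(sim = sim, foregrounds = foregrounds,
                 long_branch_factor = long_branch_factor,
                 ds_max = ds_max, dn_max = dn_max, alpha = alpha,
                 posterior_cutoff = posterior_cutoff,
                 omega2_starts = omega2_starts,
                 n_resamples = n_resamples,
                 qc_max_iter = as.integer(qc_max_iter),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full comparative-selection pipeline
#'
#' Executes simulate -> prep -> trees -> rates -> selection -> resample on a
#' synthetic dataset (or a dataset supplied in-memory) and returns every
#' intermediate product plus a manifest of per-stage counts mirroring the
#' attrition a real ortholog pipeline reports.
#'
#' Stages:
#' \describe{
#'   \item{simulate}{[generate_dataset()] under `config$sim`.}
#'   \item{prep}{reciprocal-best-hit ortholog regrouping
#'     ([prep_orthologs()], optional) and the composition filter.}
#'   \item{trees}{[fit_gene_tree()] per gene, topology congruence check
#'     against the species tree, iterative [long_branch_qc()] with taxon
#'     dropping and re-entry (capped), re-checking composition after drops.}
#'   \item{rates}{[lineage_rates()] + [filter_outliers()].}
#'   \item{selection}{[test_selection()] on both foreground branches with
#'     per-branch FDR.}
#'   \item{resample}{rate-difference and enrichment resampling tests
#'     ([resample_pvalue()], [selection_enrichment()]).}
#' }
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-generated dataset (as from
#'   [generate_dataset()]); when `NULL` the simulate stage creates one.
#' @param out_dir Optional directory for per-stage TSV/Newick artifacts and
#'   the JSON manifest.
#' @param topology A [species_topology()].
#' @param use_rbh Re-derive ortholog sets by reciprocal best hit in the prep
#'   stage (the faithful path); disable to trust the dataset's grouping.
#' @param verbose Print per-stage progress.
#' @return List with `dataset`, `kept` (gene ids surviving QC), `trees`,
#'   `qc_log`, `rates`, `selection`, `rate_tests`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         out_dir = NULL, topology = species_topology(),
                         use_rbh = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  t_start <- Sys.time()

  # --- simulate ---------------------------------------------------------
  say("stage simulate")
  if (is.null(dataset)) dataset <- generate_dataset(topology, config$sim)
  n_genes <- length(dataset$alignments)
  if (n_genes == 0)
    stop("pipeline stage 'prep': no genes in input dataset", call. = FALSE)

  # --- prep: orthology regrouping + composition filter ------------------
  say("stage prep")
  if (use_rbh) {
    prep <- prep_orthologs(dataset)
    dataset$alignments <- prep$alignments
    dataset$labels <- prep$labels
  }
  comp_ok <- vapply(dataset$alignments,
                    function(a) composition_filter(rownames(a)), logical(1))
  prep_ids <- names(dataset$alignments)[comp_ok]

  # --- trees: fit, congruence, long-branch QC with re-entry -------------
  say("stage trees")
  trees <- list()
  qc_log <- list()
  for (id in prep_ids) {
    aln <- dataset$alignments[[id]]
    dropped <- character(0)
    action <- NA_character_
    for (iter in seq_len(config$qc_max_iter)) {
      if (!composition_filter(rownames(aln))) {
        action <- "fail_composition"
        break
      }
      gt <- fit_gene_tree(aln)
      if (!check_topology(gt, topology)) {
        action <- "fail_topology"
        break
      }
      qc <- long_branch_qc(gt, factor = config$long_branch_factor)
      if (qc$action == "keep") {
        trees[[id]] <- gt
        action <- "keep"
        break
      } else if (qc$action == "discard_tree") {
        action <- "discard_tree"
        break
      } else {
        dropped <- c(dropped, qc$taxon)
        aln <- aln[setdiff(rownames(aln), qc$taxon), , drop = FALSE]
        action <- "drop_taxon"
      }
    }
    if (identical(action, "drop_taxon")) action <- "qc_iteration_cap"
    qc_log[[id]] <- tibble::tibble(
      gene_id = id, action = action,
      dropped_taxa = paste(dropped, collapse = ","))
    if (identical(action, "keep") && length(dropped) > 0)
      dataset$alignments[[id]] <- aln
  }
  qc_log <- dplyr::bind_rows(qc_log)
  kept <- names(trees)

  # --- rates ------------------------------------------------------------
  say("stage rates")
  rates_raw <- lineage_rates(dataset$alignments[kept], trees,
                             labels = dataset$labels, topology = topology)
  rates <- filter_outliers(rates_raw, ds_max = config$ds_max,
                           dn_max = config$dn_max)

  # --- selection --------------------------------------------------------
  say("stage selection")
  selection <- test_selection(dataset$alignments[kept], trees,
                              foregrounds = config$foregrounds,
                              topology = topology,
                              neb_cutoff = config$posterior_cutoff)

  # --- resample ---------------------------------------------------------
  say("stage resample")
  set.seed(config$seed)
  lti_ids <- dataset$labels$gene_id[dataset$labels$is_lti]
  rate_tests <- purrr::map_dfr(c("gtr", "dS", "dN"), function(metric) {
    purrr::map_dfr(c("brachypodium", "core_pooideae"), function(sp) {
      diffs <- rate_difference(rates, sp, metric = metric)
      if (nrow(diffs) < 2 || sum(diffs$gene_id %in% lti_ids) == 0)
        return(NULL)
      rs <- resample_pvalue(setNames(diffs$difference, diffs$gene_id),
                            lti_ids, "median",
                            n_resamples = config$n_resamples)
      tibble::tibble(metric = metric, comparison = paste0(sp, "-rice"),
                     observed_lti = rs$observed,
                     resampled_mean = mean(rs$draws),
                     p_value = rs$p_value)
    })
  })
  enrichment <- selection_enrichment(selection, dataset$labels,
                                     alpha = config$alpha,
                                     n_resamples = config$n_resamples)
  q3 <- purrr::map_dfr(unique(selection$foreground), function(fgb) {
    res <- dplyr::filter(selection, .data$foreground == fgb, !.data$skipped)
    if (nrow(res) < 2 || !any(res$gene_id %in% lti_ids)) return(NULL)
    rs <- resample_pvalue(setNames(res$lr, res$gene_id), lti_ids,
                          "third_quartile",
                          n_resamples = config$n_resamples)
    tibble::tibble(foreground = fgb, statistic = "third_quartile_lr",
                   observed_lti = rs$observed,
                   resampled_mean = mean(rs$draws), p_value = rs$p_value)
  })

  manifest <- list(
    seed = config$seed,
    n_genes = n_genes,
    n_lti = sum(dataset$labels$is_lti),
    n_pass_composition = length(prep_ids),
    n_kept_trees = length(kept),
    n_fail_topology = sum(qc_log$action == "fail_topology"),
    n_discard_tree = sum(qc_log$action == "discard_tree"),
    n_taxa_dropped = sum(nchar(qc_log$dropped_taxa) > 0),
    n_rate_rows = nrow(rates_raw),
    n_rate_outliers = nrow(rates_raw) - nrow(rates),
    n_selection_tests = sum(!selection$skipped),
    elapsed_sec = as.numeric(Sys.time() - t_start, units = "secs"))

  out <- list(dataset = dataset, kept = kept, trees = trees,
              qc_log = qc_log, rates = rates, rates_raw = rates_raw,
              selection = selection, rate_tests = rate_tests,
              enrichment = enrichment, q3_tests = q3,
              manifest = manifest, config = config)
  class(out) <- "grasselect_run"
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.grasselect_run <- function(x, ...) {
  m <- x$manifest
  cat("grasselect pipeline run\n",
      "  genes simulated: ", m$n_genes, " (", m$n_lti, " LTI)\n",
      "  passed composition: ", m$n_pass_composition,
      "; kept trees: ", m$n_kept_trees, "\n",
      "  selection tests run: ", m$n_selection_tests, "\n", sep = "")
  if (nrow(x$enrichment) > 0) {
    cat("  enrichment (significant selection in LTI vs all):\n")
    print(as.data.frame(x$enrichment), row.names = FALSE)
  }
  invisible(x)
}

# Write per-stage artifacts: TSVs, Newick trees and a JSON manifest.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name, stage) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# stage=%s seed=%d units=substitutions_per_site",
                       stage, run$config$seed), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  tsv(run$qc_log, "qc_log.tsv", "trees")
  tsv(run$rates, "lineage_rates.tsv", "rates")
  tsv(dplyr::select(run$selection, -dplyr::any_of("sites")) |>
        dplyr::mutate(sites = run$selection$sites),
      "selection_tests.tsv", "selection")
  if (nrow(run$rate_tests) > 0)
    tsv(run$rate_tests, "rate_resampling.tsv", "resample")
  if (nrow(run$enrichment) > 0)
    tsv(run$enrichment, "enrichment.tsv", "resample")
  if (nrow(run$q3_tests) > 0)
    tsv(run$q3_tests, "q3_resampling.tsv", "resample")
  trees_path <- file.path(out_dir, "gene_trees.nwk")
  if (length(run$trees) > 0) {
    phys <- lapply(run$trees, function(t) t$tree)
    class(phys) <- "multiPhylo"
    ape::write.tree(phys, trees_path, tree.names = TRUE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
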