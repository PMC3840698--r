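test_that("chi-square LRT p-values are correct", {
  expect_equal(lrt_pvalue(-100, -100), 1)
  expect_equal(lrt_pvalue(0, 3.841 / 2), 0.05, tolerance = 1e-3)
  expect_equal(lrt_pvalue(0, 5), pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lrt_pvalue(0, 5), 1.565e-3, tolerance = 1e-3)
  # numerical noise below the null is clamped
  expect_equal(lrt_pvalue(-50, -50 - 1e-9), 1)
})

test_that("alternative fit dominates the null and every single start", {
  topo <- species_topology()
  cfg <- small_cfg(n_codons = 150, omega2 = 6)
  g <- simulate_gene(topo, cfg, "lti", seed = 31)
  gt <- fit_gene_tree(g$alignment)
  prelim <- codon_branch_lengths(g$alignment, gt)
  full <- fit_branch_site(g$alignment, gt, "BP_ancestral", topo,
                          prelim = prelim)
  expect_gte(full$lnl_alt, full$lnl_null - 1e-6)
  expect_gte(full$lr, 0)
  for (st in c(0.5, 1.5, 2)) {
    single <- fit_branch_site(g$alignment, gt, "BP_ancestral", topo,
                              prelim = prelim, omega2_starts = st)
    expect_gte(full$lnl_alt, single$lnl_alt - 1e-4)
  }
})

test_that("branch-site fit reports tidy, glance and augment views", {
  topo <- species_topology()
  g <- simulate_gene(topo, small_cfg(n_codons = 100), "background",
                     seed = 41)
  gt <- fit_gene_tree(g$alignment)
  fit <- fit_branch_site(g$alignment, gt, "CP_stem", topo, gene_id = "gX")
  td <- tidy(fit)
  expect_setequal(td$term, c("omega0", "omega2", "kappa", "p0", "p1",
                             "p2a", "p2b"))
  # class proportions form a distribution
  expect_equal(sum(td$estimate[td$term %in% c("p0", "p1", "p2a", "p2b")]),
               1, tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(gl$gene_id, "gX")
  expect_equal(gl$lr, fit$lr)
  au <- augment(fit)
  expect_equal(nrow(au), 100L)
  expect_true(all(au$p_selected >= 0 & au$p_selected <= 1))
})

test_that("unidentifiable foreground branches are skipped with a reason", {
  topo <- species_topology()
  g <- simulate_gene(topo, small_cfg(n_codons = 60), "background",
                     seed = 43)
  aln <- g$alignment[c("maize", "rice", "brachypodium", "barley"), ]
  tr <- ape::keep.tip(topo$tree, rownames(aln))
  tr$edge.length <- tr$edge.length / 3
  fit <- fit_branch_site(aln, tr, "CP_stem", topo)
  expect_true(fit$skipped)
  expect_match(fit$skip_reason, "not identifiable")
  expect_true(glance(fit)$skipped)
})

test_that("NEB recovers strongly selected sites with few false positives", {
  # a strong-signal regime: long foreground branch, large omega2 and a
  # sizeable selected-class prior, so selected sites carry enough posterior
  # mass to clear the 0.9 cutoff
  bl <- default_branch_lengths()
  bl[["BP_ancestral"]] <- 0.5
  topo <- species_topology(branch_lengths = bl)
  cfg <- small_cfg(n_codons = 150, omega2 = 20, p0 = 0.55, p1 = 0.08)
  set.seed(57)
  recovered <- false_pos <- total_sel <- total_bg <- 0
  for (i in 1:8) {
    g <- simulate_gene(topo, cfg, "lti")
    tr <- topo$tree
    tr$edge.length <- tr$edge.length / 3
    fit <- fit_branch_site(g$alignment, tr, "BP_ancestral", topo)
    sel <- g$truth$selected_sites[[1]]
    hits <- neb_sites(fit)
    recovered <- recovered + sum(hits %in% sel)
    false_pos <- false_pos + sum(!(hits %in% sel))
    total_sel <- total_sel + length(sel)
    total_bg <- total_bg + (150 - length(sel))
  }
  expect_gte(recovered / total_sel, 0.5)
  expect_lte(false_pos / total_bg, 0.05)
})

test_that("omega2 is recovered within 25% in the median at strong signal", {
  bl <- default_branch_lengths()
  bl[["BP_ancestral"]] <- 0.3
  topo <- species_topology(branch_lengths = bl)
  cfg <- small_cfg(n_codons = 400, omega2 = 8)
  set.seed(8)
  w2 <- replicate(10, {
    g <- simulate_gene(topo, cfg, "lti")
    tr <- topo$tree
    tr$edge.length <- tr$edge.length / 3
    fit_branch_site(g$alignment, tr, "BP_ancestral", topo)$omega2
  })
  expect_lt(abs(median(w2) - 8) / 8, 0.25)
})

test_that("test_selection aggregates genes with per-branch FDR", {
  topo <- species_topology()
  cfg <- small_cfg(n_genes = 4, n_codons = 80, seed = 3,
                   contaminant_rate = 0,
                   dropout_probs = setNames(rep(0, 8),
                                            names(default_dropout_probs())))
  ds <- generate_dataset(topo, cfg)
  trees <- lapply(ds$alignments, fit_gene_tree)
  res <- test_selection(ds$alignments, trees, topology = topo)
  expect_equal(nrow(res), 8L)  # 4 genes x 2 branches
  expect_true(all(res$q_value >= res$p_value - 1e-12, na.rm = TRUE))
  expect_true(all(res$lnl_alt >= res$lnl_null - 1e-6, na.rm = TRUE))
})
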