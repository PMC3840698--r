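test_that("zero branch lengths reproduce the root sequence at every tip", {
  bl <- setNames(rep(0, 14), names(default_branch_lengths()))
  topo0 <- species_topology(branch_lengths = bl)
  g <- simulate_gene(topo0, small_cfg(), "background", seed = 1)
  expect_true(all(apply(g$alignment, 2, function(x) length(unique(x)) == 1)))
  expect_equal(g$truth$fg_syn + g$truth$bg_syn, 0)
  expect_equal(g$truth$fg_nonsyn + g$truth$bg_nonsyn, 0)
})

test_that("invalid simulation requests are rejected", {
  topo <- species_topology()
  expect_error(simulate_gene(topo, small_cfg(), "background", n_codons = 0),
               "zero-length")
  expect_error(sim_config(omega0 = 1.5), "omega0")
  expect_error(sim_config(lti_fraction = 1.2))
})

test_that("realized substitution fluxes match rate-matrix expectations", {
  # oracle: under the shared mixture scale, every class has synonymous flux
  # s1/scale while the nonsynonymous flux is omega_c * n1 / scale, so the
  # expected counts follow in closed form from the branch length
  topo <- species_topology()
  cfg <- small_cfg(n_codons = 50, omega2 = 8)
  nrep <- 200
  set.seed(42)
  fg_s <- fg_n <- 0
  for (i in seq_len(nrep)) {
    g <- simulate_gene(topo, cfg, "lti")
    fg_s <- fg_s + g$truth$fg_syn
    fg_n <- fg_n + g$truth$fg_nonsyn
  }
  pi <- grasselect:::f3x4_from_base_freqs(cfg$base_freqs)
  fl <- grasselect:::codon_flux(cfg$kappa, 1, pi)
  w <- grasselect:::site_class_weights(cfg$p0, cfg$p1)
  scale <- mixture_scale_oracle(cfg$kappa, c(cfg$omega0, 1, cfg$omega0, 1),
                                w, pi)
  t_fg <- default_branch_lengths()[["BP_ancestral"]]
  omega_fg <- c(cfg$omega0, 1, cfg$omega2, cfg$omega2)
  exp_syn <- nrep * 50 * t_fg * fl$s1 / scale
  exp_nonsyn <- nrep * 50 * t_fg * sum(w * omega_fg) * fl$n1 / scale
  # Poisson counts: compare within ~4 standard errors
  expect_lt(abs(fg_s - exp_syn), 4 * sqrt(exp_syn))
  expect_lt(abs(fg_n - exp_nonsyn), 4 * sqrt(exp_nonsyn))
  # the foreground nonsyn/syn ratio clearly exceeds the background one
  expect_gt(fg_n / fg_s, 2)
})

test_that("without branch-specific classes the branches are exchangeable", {
  # p0 + p1 = 1 removes the selected classes entirely, so every site evolves
  # under the same process on all branches (the Model A null itself is not
  # exchangeable: its 2a class is neutral on the foreground only)
  topo <- species_topology()
  cfg <- small_cfg(n_codons = 80, omega2 = 1, p0 = 0.75, p1 = 0.25)
  set.seed(3)
  tot <- c(fg_n = 0, fg_s = 0, bg_n = 0, bg_s = 0)
  # compare dN/dS-like count ratios; scale by branch length share
  bl <- default_branch_lengths()
  t_fg <- bl[["BP_ancestral"]]
  t_bg <- sum(bl) - t_fg
  for (i in 1:150) {
    g <- simulate_gene(topo, cfg, "lti")
    tot <- tot + c(g$truth$fg_nonsyn, g$truth$fg_syn,
                   g$truth$bg_nonsyn, g$truth$bg_syn)
  }
  ratio_fg <- tot[["fg_n"]] / tot[["fg_s"]]
  ratio_bg <- tot[["bg_n"]] / tot[["bg_s"]]
  expect_lt(abs(ratio_fg / ratio_bg - 1), 0.25)
})

test_that("site classes are drawn in the configured proportions", {
  topo <- species_topology()
  cfg <- small_cfg(n_codons = 400)
  set.seed(9)
  cls <- unlist(lapply(1:10, function(i)
    simulate_gene(topo, cfg, "background")$site_class))
  w <- grasselect:::site_class_weights(cfg$p0, cfg$p1)
  obs <- tabulate(cls + 1L, 4L)
  expect_gt(chisq.test(obs, p = w)$p.value, 0.001)
})

test_that("long branches drive tip codon frequencies to stationarity", {
  bl <- setNames(rep(8, 14), names(default_branch_lengths()))
  topo_long <- species_topology(branch_lengths = bl)
  cfg <- small_cfg(n_codons = 150)
  g <- simulate_gene(topo_long, cfg, "background", seed = 21)
  pi <- grasselect:::f3x4_from_base_freqs(cfg$base_freqs)
  codes <- grasselect:::codon_codes(g$alignment)
  obs <- tabulate(as.vector(codes) + 1L, 61L)
  expect_gt(chisq.test(obs, p = pi)$p.value, 0.01)
})

test_that("datasets are reproducible and honour dropout/contaminant settings", {
  topo <- species_topology()
  cfg <- small_cfg(n_genes = 12, n_codons = 40, seed = 7,
                   contaminant_rate = 0.3)
  d1 <- generate_dataset(topo, cfg)
  d2 <- generate_dataset(topo, cfg)
  expect_identical(d1$alignments, d2$alignments)
  expect_identical(d1$labels, d2$labels)
  expect_identical(dplyr::select(d1$truth, -"branch_counts"),
                   dplyr::select(d2$truth, -"branch_counts"))

  # no dropout / no contaminants: all 8 taxa everywhere
  cfg0 <- small_cfg(n_genes = 6, n_codons = 40, seed = 2,
                    dropout_probs = setNames(rep(0, 8),
                                             names(default_dropout_probs())),
                    contaminant_rate = 0)
  d0 <- generate_dataset(topo, cfg0)
  expect_true(all(vapply(d0$alignments, nrow, integer(1)) == 8L))
  expect_true(all(is.na(d0$truth$contaminant_taxon)))

  # contaminant count is binomial around the configured rate
  cfg_c <- small_cfg(n_genes = 60, n_codons = 30, seed = 3,
                     contaminant_rate = 0.2)
  dc <- generate_dataset(topo, cfg_c)
  n_cont <- sum(!is.na(dc$truth$contaminant_taxon))
  expect_lt(abs(n_cont - 12), 4 * sqrt(60 * 0.2 * 0.8))
})

test_that("written datasets round-trip through the plain-text formats", {
  topo <- species_topology()
  cfg <- small_cfg(n_genes = 3, n_codons = 30, seed = 11)
  dir <- tempfile("ds")
  ds <- generate_dataset(topo, cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_true(file.exists(file.path(dir, "config.txt")))
  fa <- grasselect:::read_fasta_matrix(
    file.path(dir, "fasta", "g0001.fasta"))
  expect_identical(fa, ds$alignments$g0001)
  labs <- read.table(file.path(dir, "labels.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(labs$gene_id, ds$labels$gene_id)
  unlink(dir, recursive = TRUE)
})
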