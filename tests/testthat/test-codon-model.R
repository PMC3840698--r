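test_that("codon rate matrix has the GY94 structure", {
  pi <- rep(1 / 61, 61)
  kappa <- 3
  omega <- 0.4
  Q <- codon_q(kappa, omega, pi)
  # one hand-computed cell: TTT -> TTC is a synonymous transition (Phe/Phe),
  # so its unscaled rate is kappa * pi(TTC); check against the matrix scale
  unscaled <- matrix(0, 61, 61)
  fl <- grasselect:::codon_flux(kappa, omega, pi)
  scale <- fl$s1 + omega * fl$n1
  expect_equal(Q["TTT", "TTC"], kappa * pi[1] / scale, tolerance = 1e-12)
  # nonsynonymous transversion example: TTT (Phe) -> TTA (Leu)
  expect_equal(Q["TTT", "TTA"], omega * pi[1] / scale, tolerance = 1e-12)
  # codons differing at >1 position never exchange directly
  expect_equal(Q["AAA", "CCA"], 0)
  # rows sum to zero for random valid parameters
  set.seed(8)
  for (i in 1:3) {
    p <- runif(61); p <- p / sum(p)
    Qi <- codon_q(runif(1, 0.5, 5), runif(1, 0.05, 2), p)
    expect_lt(max(abs(rowSums(Qi))), 1e-12)
    # unit flux at stationarity
    expect_equal(-sum(p * diag(Qi)), 1, tolerance = 1e-12)
    # reversibility: pi_i q_ij = pi_j q_ji
    D <- diag(p) %*% Qi
    expect_lt(max(abs(D - t(D))), 1e-12)
  }
  # kappa = omega = 1 with uniform frequencies: all permitted rates equal
  Q1 <- codon_q(1, 1, pi)
  off <- Q1[Q1 > 0]
  expect_lt(diff(range(off)), 1e-14)
  # zero frequency for an observed codon is an error
  p0 <- pi; p0[5] <- 0; p0 <- p0 / sum(p0)
  expect_error(codon_q(2, 1, p0, observed = 4L), "zero frequency")
})

test_that("F3x4 frequencies multiply position-specific counts", {
  # uniform base composition: all sense codons get 1/61
  bases <- c("A", "C", "G", "T")
  aln <- matrix(rep(bases, 3), 4, 12, byrow = FALSE)
  rownames(aln) <- paste0("t", 1:4)
  # columns cycle through positions; make all positions uniform
  aln_u <- rbind(a = rep(bases, 3), b = rep(bases, 3),
                 c = rep(rev(bases), 3), d = rep(rev(bases), 3))
  pi_u <- f3x4(aln_u)
  expect_equal(unname(pi_u), rep(1 / 61, 61), tolerance = 1e-12)
  # hand-counted toy: a single sequence ATG GCA
  single <- matrix(c("A", "T", "G", "G", "C", "A"), 1, 6,
                   dimnames = list("x", NULL))
  pi_s <- f3x4(single)
  # position frequencies: pos1 {A,G}, pos2 {T,C}, pos3 {G,A} each 1/2;
  # codon ATG has (1/2)^3 before stop-exclusion renormalisation
  manual <- numeric(61)
  names(manual) <- sense_codons()
  for (cdn in sense_codons()) {
    p <- strsplit(cdn, "")[[1]]
    manual[cdn] <- (p[1] %in% c("A", "G")) * 0.5 *
      (p[2] %in% c("T", "C")) * 0.5 * (p[3] %in% c("G", "A")) * 0.5
  }
  manual <- pmax(manual, 1e-10)
  manual <- manual / sum(manual)
  expect_equal(pi_s, manual, tolerance = 1e-9)
  expect_equal(sum(pi_s), 1, tolerance = 1e-12)
})

test_that("codon mixture pruning matches enumeration over states and classes", {
  topo <- species_topology()
  cfg <- small_cfg(n_codons = 5)
  g <- simulate_gene(topo, cfg, "background", seed = 19)
  aln <- g$alignment[c("rice", "barley", "maize"), , drop = FALSE]
  tr <- ape::read.tree(text = "(rice:0.2,barley:0.35,maize:0.5);")
  pi <- f3x4(aln)
  m <- site_class_model(weights = c(0.5, 0.2, 0.2, 0.1),
                        omega_bg = c(0.1, 1, 0.1, 1),
                        omega_fg = c(0.1, 1, 5, 5),
                        kappa = 2.2, pi = pi)
  tr_post <- ape::reorder.phylo(tr, "postorder")
  fg <- 2L  # the barley terminal edge in postorder
  expect_equal(codon_loglik(aln, tr_post, m, foreground = fg),
               enum_codon_loglik(aln, tr_post, m, foreground = fg),
               tolerance = 1e-9)
  # degenerate mixture: a single class with omega 1 equals a one-ratio model
  m1 <- site_class_model(weights = 1, omega_bg = 1, kappa = 2.2, pi = pi)
  m4 <- site_class_model(weights = c(0.25, 0.25, 0.25, 0.25),
                         omega_bg = rep(1, 4), kappa = 2.2, pi = pi)
  expect_equal(codon_loglik(aln, tr_post, m4),
               codon_loglik(aln, tr_post, m1), tolerance = 1e-10)
  # foreground designation is irrelevant when omega_fg equals omega_bg
  m_same <- site_class_model(weights = c(0.6, 0.4), omega_bg = c(0.2, 1),
                             omega_fg = c(0.2, 1), kappa = 2.2, pi = pi)
  expect_equal(codon_loglik(aln, tr_post, m_same, foreground = fg),
               codon_loglik(aln, tr_post, m_same), tolerance = 1e-12)
})
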