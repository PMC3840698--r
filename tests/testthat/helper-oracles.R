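# Independent oracles used across the suite. These re-derive likelihoods and
# p-values from first principles (matrix exponentials via R's eigen(),
# explicit enumeration of internal states, exhaustive subset enumeration),
# sharing no code with the package's pruning kernels.

# matrix exponential via eigendecomposition (general, complex-safe)
pm_eigen <- function(Q, t) {
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t), nrow(Q)) %*% solve(e$vectors))
}

# --- nucleotide GTR oracle -------------------------------------------------

# unscaled-to-scaled GTR rate matrix built independently of the package
gtr_q_oracle <- function(base_freq, exch) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  Q <- matrix(0, 4, 4)
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- exch[k] * base_freq[j]
    Q[j, i] <- exch[k] * base_freq[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(base_freq * -diag(Q))
}

# brute-force GTR(+Gamma) log-likelihood: sum over all internal-node state
# assignments; rate categories from the same discretisation rule
enum_gtr_loglik <- function(aln, tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  Q <- gtr_q_oracle(model$base_freq, model$exch)
  pi <- model$base_freq
  rates <- if (is.infinite(model$alpha)) 1 else {
    r <- qgamma((seq_len(model$ncat) - 0.5) / model$ncat,
                shape = model$alpha, rate = model$alpha)
    r / mean(r)
  }
  codes <- matrix(match(aln, c("A", "C", "G", "T")),
                  nrow(aln), ncol(aln))
  rownames(codes) <- rownames(aln)
  codes <- codes[tr$tip.label, , drop = FALSE]
  ntip <- nrow(codes)
  nn <- ntip + tr$Nnode
  ints <- (ntip + 1):nn
  grid <- as.matrix(do.call(expand.grid, rep(list(1:4), length(ints))))
  ll <- 0
  for (s in seq_len(ncol(codes))) {
    site_lik <- 0
    for (r in rates) {
      P <- lapply(seq_len(nrow(tr$edge)),
                  function(k) pm_eigen(Q, tr$edge.length[k] * r))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nn)
        st[seq_len(ntip)] <- codes[, s]
        st[ints] <- grid[g, ]
        pr <- pi[st[ntip + 1]]
        for (k in seq_len(nrow(tr$edge)))
          pr <- pr * P[[k]][st[tr$edge[k, 1]], st[tr$edge[k, 2]]]
        tot <- tot + pr
      }
      site_lik <- site_lik + tot / length(rates)
    }
    ll <- ll + log(site_lik)
  }
  ll
}

# --- codon mixture oracle --------------------------------------------------

# independent GY94 rate matrix construction from the genetic code
codon_q_oracle <- function(kappa, omega, pi, scale = NULL) {
  codons <- sense_codons()
  aa <- vapply(codons, function(x)
    seqinr::translate(strsplit(x, "")[[1]]), character(1))
  n <- length(codons)
  cm <- do.call(rbind, strsplit(codons, ""))
  ts_pair <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(cm[i, ] != cm[j, ])
    if (length(d) != 1) next
    m <- if (ts_pair(cm[i, d], cm[j, d])) kappa else 1
    if (aa[i] != aa[j]) m <- m * omega
    Q[i, j] <- m * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  sc <- if (is.null(scale)) sum(pi * -diag(Q)) else scale
  Q / sc
}

# stationary flux scale of a background mixture, derived independently
mixture_scale_oracle <- function(kappa, omegas_bg, weights, pi) {
  fluxes <- vapply(omegas_bg, function(w) {
    Q <- codon_q_oracle(kappa, w, pi, scale = 1)
    sum(pi * -diag(Q))
  }, numeric(1))
  sum(weights * fluxes)
}

# brute-force site-class codon log-likelihood on a tree small enough to
# enumerate internal states (sum over classes and internal assignments)
enum_codon_loglik <- function(aln, tree, model, foreground = integer(0)) {
  tr <- ape::reorder.phylo(tree, "postorder")
  codons <- sense_codons()
  n <- length(codons)
  scale <- mixture_scale_oracle(model$kappa, model$omega_bg,
                                model$weights, model$pi)
  nc <- ncol(aln) %/% 3
  codes <- matrix(NA_integer_, nrow(aln), nc,
                  dimnames = list(rownames(aln), NULL))
  for (i in seq_len(nrow(aln))) {
    for (s in seq_len(nc)) {
      codes[i, s] <- match(paste(aln[i, (3 * s - 2):(3 * s)],
                                 collapse = ""), codons)
    }
  }
  codes <- codes[tr$tip.label, , drop = FALSE]
  ntip <- nrow(codes)
  nn <- ntip + tr$Nnode
  ints <- (ntip + 1):nn
  stopifnot(length(ints) <= 2)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), length(ints))))
  ll <- 0
  for (s in seq_len(nc)) {
    site_lik <- 0
    for (c in seq_along(model$weights)) {
      P <- lapply(seq_len(nrow(tr$edge)), function(k) {
        w <- if (k %in% foreground) model$omega_fg[c] else model$omega_bg[c]
        pm_eigen(codon_q_oracle(model$kappa, w, model$pi, scale = scale),
                 tr$edge.length[k])
      })
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nn)
        st[seq_len(ntip)] <- codes[, s]
        st[ints] <- grid[g, ]
        pr <- model$pi[st[ntip + 1]]
        for (k in seq_len(nrow(tr$edge)))
          pr <- pr * P[[k]][st[tr$edge[k, 1]], st[tr$edge[k, 2]]]
        tot <- tot + pr
      }
      site_lik <- site_lik + model$weights[c] * tot
    }
    ll <- ll + log(site_lik)
  }
  ll
}

# --- resampling oracle -----------------------------------------------------

# exact one-sided subset-resampling p-value by exhaustive enumeration
exact_resample_p <- function(values, subset_ids, stat_fun) {
  ids <- names(values)
  k <- sum(ids %in% subset_ids)
  obs <- stat_fun(as.numeric(values[ids %in% subset_ids]))
  combos <- utils::combn(length(values), k)
  stats <- apply(combos, 2, function(ix) stat_fun(as.numeric(values[ix])))
  mean(stats >= obs)
}

# --- small simulation helpers ---------------------------------------------

# simulate a diverged codon sequence pair under a one-ratio model
sim_codon_pair <- function(n_codons, t, kappa, omega, pi = rep(1 / 61, 61),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- codon_q(kappa, omega, pi)
  P <- pm_eigen(Q, t)
  codons <- sense_codons()
  a_idx <- sample(seq_along(pi), n_codons, replace = TRUE, prob = pi)
  b_idx <- vapply(a_idx, function(i)
    sample(seq_along(pi), 1, prob = pmax(P[i, ], 0)), integer(1))
  list(a = paste(codons[a_idx], collapse = ""),
       b = paste(codons[b_idx], collapse = ""))
}

small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 5L, n_codons = 60, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
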