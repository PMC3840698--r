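#' Estimate a gene tree under GTR+Gamma
#'
#' Builds a topology by neighbour-joining on maximum-likelihood pairwise GTR
#' distances, then jointly optimises all branch lengths, the five free
#' exchangeabilities and the gamma shape by bounded maximisation of the
#' pruning log-likelihood (base frequencies are fixed at their empirical
#' values, as is standard). The returned log-likelihood is never lower than
#' that of the starting point.
#'
#' @param alignment Character matrix (taxa x sites) or named character
#'   vector; at least three taxa.
#' @param model Starting [gtr_model()]; its `ncat` is kept.
#' @param max_iter Iteration cap passed to the optimiser.
#' @return An object of class `gene_tree`: list with `tree` (unrooted
#'   `phylo`, branch lengths in substitutions/site), `loglik`, `model`
#'   (fitted), and `converged`.
#' @export
fit_gene_tree <- function(alignment, model = NULL, max_iter = 60L) {
  aln <- as_nuc_matrix(alignment)
  if (nrow(aln) < 3L) stop("need at least 3 taxa", call. = FALSE)
  base_freq <- empirical_base_freq(aln)
  if (is.null(model)) model <- gtr_model(base_freq = base_freq, alpha = Inf)
  dist_model <- gtr_model(exch = model$exch, base_freq = base_freq,
                          alpha = Inf)
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        gtr_pairwise_distance(aln[i, ], aln[j, ], dist_model)
    }
  }
  phy <- ape::nj(as.dist(D))
  phy$edge.length <- pmax(phy$edge.length, 1e-8)

  codes <- nuc_codes(aln)
  pat <- compress_patterns(codes)
  td <- tree_data(phy, pat$codes)
  ne <- nrow(td$edge)
  # parameters on the log scale: branch lengths, 5 exchangeabilities, alpha
  par0 <- c(log(td$lens), log(model$exch[1:5]), log(2))
  lower <- c(rep(log(1e-9), ne), rep(log(1e-3), 5), log(0.05))
  upper <- c(rep(log(10), ne), rep(log(1e3), 5), log(100))
  nll <- function(p) {
    lens <- exp(p[seq_len(ne)])
    exch <- c(exp(p[ne + 1:5]), 1)
    alpha <- exp(p[ne + 6])
    ll <- nuc_site_loglik_cpp(td$codes, td$edge, lens, base_freq, exch,
                              gamma_rates(alpha, model$ncat),
                              td$nnode, td$ntip)
    -sum(pat$weights * ll)
  }
  fit <- nlminb(par0, nll, lower = lower, upper = upper,
                control = list(iter.max = max_iter, eval.max = 20L * max_iter,
                               rel.tol = 1e-8))
  obj0 <- nll(par0)
  # monotone guarantee: fall back to the start if the optimiser went uphill
  p <- if (fit$objective <= obj0) fit$par else par0
  phy2 <- td$phy
  phy2$edge.length <- exp(p[seq_len(ne)])
  fitted <- gtr_model(exch = c(exp(p[ne + 1:5]), 1), base_freq = base_freq,
                      alpha = exp(p[ne + 6]), ncat = model$ncat)
  structure(list(tree = phy2, loglik = -min(fit$objective, obj0),
                 model = fitted,
                 converged = fit$convergence == 0),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree (", length(x$tree$tip.label), " tips), log-likelihood ",
      format(x$loglik, digits = 8),
      if (!x$converged) " [optimizer not converged]", "\n", sep = "")
  invisible(x)
}

empirical_base_freq <- function(aln) {
  tab <- table(factor(aln, levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) + 0.5  # tiny regularisation against absent bases
  f / sum(f)
}

#' Check a gene tree against the species topology
#'
#' Passes when the unrooted gene-tree topology equals the species topology
#' pruned to the taxa present in the gene tree. Trees with three or fewer
#' taxa have a single unrooted shape and always pass.
#'
#' @param gene_tree `phylo` or `gene_tree`.
#' @param topology A [species_topology()].
#' @return `TRUE` or `FALSE`.
#' @export
check_topology <- function(gene_tree, topology = species_topology()) {
  phy <- if (inherits(gene_tree, "gene_tree")) gene_tree$tree else gene_tree
  taxa <- phy$tip.label
  if (!all(taxa %in% topology$taxa)) return(FALSE)
  if (length(taxa) <= 3L) return(TRUE)
  ref <- ape::keep.tip(topology$tree, taxa)
  d <- ape::dist.topo(ape::unroot(phy), ape::unroot(ref))
  as.numeric(d) == 0
}

#' Long-branch quality control
#'
#' Flags trees in which the longest branch is more than `factor` times
#' longer than the second longest (strict inequality, so a ratio of exactly
#' 3 is kept). An offending external branch points at a likely
#' non-orthologous sequence, so that taxon is dropped and the gene re-enters
#' the tree-building loop; an offending internal branch discards the tree.
#'
#' @param tree `phylo` or `gene_tree` with at least four branches.
#' @param factor Ratio threshold (default 3).
#' @return One-row tibble with columns `action` (`"keep"`,
#'   `"drop_taxon"`, or `"discard_tree"`), `taxon` (the dropped tip or
#'   `NA`), and `ratio` (longest / second longest).
#' @export
long_branch_qc <- function(tree, factor = 3) {
  phy <- if (inherits(tree, "gene_tree")) tree$tree else tree
  el <- phy$edge.length
  if (length(el) < 4L) stop("need at least 4 branches", call. = FALSE)
  ord <- order(el, decreasing = TRUE)
  ratio <- el[ord[1]] / el[ord[2]]
  if (!(ratio > factor)) {
    return(tibble::tibble(action = "keep", taxon = NA_character_,
                          ratio = ratio))
  }
  child <- phy$edge[ord[1], 2]
  ntip <- length(phy$tip.label)
  if (child <= ntip) {
    tibble::tibble(action = "drop_taxon", taxon = phy$tip.label[child],
                   ratio = ratio)
  } else {
    tibble::tibble(action = "discard_tree", taxon = NA_character_,
                   ratio = ratio)
  }
}

#' Cophenetic distance from a species to the outgroup(s)
#'
#' Path-length (cophenetic) distance from the species tip to each outgroup
#' tip present in the tree; when both outgroups are present the mean of the
#' two distances is returned.
#'
#' @param tree `phylo` or `gene_tree`.
#' @param species Tip label of the focal species.
#' @param outgroups Outgroup tip labels.
#' @return Mean distance (substitutions/site), or `NA` when no outgroup is
#'   present.
#' @export
outgroup_distance <- function(tree, species,
                              outgroups = c("maize", "sorghum")) {
  phy <- if (inherits(tree, "gene_tree")) tree$tree else tree
  og <- intersect(outgroups, phy$tip.label)
  if (length(og) == 0 || !(species %in% phy$tip.label)) return(NA_real_)
  cm <- ape::cophenetic.phylo(phy)
  mean(cm[species, og])
}
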