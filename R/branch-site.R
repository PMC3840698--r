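#' Codon-scale branch lengths from a nucleotide gene tree
#'
#' Re-scales a nucleotide gene tree to codon units by fitting a one-ratio
#' codon model in which the relative branch proportions are taken from the
#' gene tree and a single scale factor, `kappa` and `omega` are optimised.
#' The resulting branch lengths (expected substitutions per codon) are then
#' held fixed during the branch-site fits, so the null and alternative
#' models share identical branch lengths and the likelihood-ratio test
#' stays properly nested.
#'
#' @param alignment In-frame codon alignment.
#' @param tree Nucleotide `gene_tree` or `phylo` (substitutions/site).
#' @param pi Codon frequencies; default F3x4 from the alignment.
#' @return List with `phy` (codon-scaled `phylo`), `kappa`, `omega`,
#'   `scale` and `loglik`.
#' @export
codon_branch_lengths <- function(alignment, tree, pi = NULL) {
  phy <- if (inherits(tree, "gene_tree")) tree$tree else tree
  aln <- as_nuc_matrix(alignment)[phy$tip.label, , drop = FALSE]
  if (is.null(pi)) pi <- f3x4(aln)
  codes <- codon_codes(aln)
  pat <- compress_patterns(codes)
  td <- tree_data(phy, pat$codes)
  el0 <- pmax(3 * td$lens, 1e-7)  # nucleotide sites -> codons
  type <- get("type", envir = .gs)
  nll <- function(p) {
    cls <- codon_class_loglik_cpp(td$codes, td$edge, exp(p[1]) * el0,
                                  unname(pi), type, exp(p[2]),
                                  exp(p[3]), exp(p[3]), integer(0),
                                  td$nnode, td$ntip)
    -sum(pat$weights * cls[, 1])
  }
  fit <- nlminb(c(0, log(2), log(0.3)), nll,
                lower = c(log(1e-3), log(0.01), log(1e-4)),
                upper = c(log(1e3), log(100), log(100)))
  phy2 <- td$phy
  phy2$edge.length <- exp(fit$par[1]) * el0
  list(phy = phy2, kappa = exp(fit$par[2]), omega = exp(fit$par[3]),
       scale = exp(fit$par[1]), loglik = -fit$objective)
}

# Profile the Model A mixture weights (p0, p1) for fixed class-conditional
# site log-likelihoods. The four class proportions factorise as
# (p0, p1, p2a, p2b) = (q r, (1-q) r, q (1-r), (1-q)(1-r)) with
# q = p0/(p0+p1), r = p0+p1, so the inner problem is a smooth 2-parameter
# optimisation that costs almost nothing per evaluation.
profile_weights <- function(cls, w_pat, start = c(1, 1)) {
  emx <- pmax(cls[, 1], cls[, 2], cls[, 3], cls[, 4])
  E <- exp(cls - emx)
  nll <- function(p) {
    q <- plogis(p[1]); r <- plogis(p[2])
    wts <- c(q * r, (1 - q) * r, q * (1 - r), (1 - q) * (1 - r))
    -sum(w_pat * (log(pmax(E %*% wts, 1e-300)) + emx))
  }
  o <- nlminb(start, nll, lower = c(-12, -12), upper = c(12, 12))
  q <- plogis(o$par[1]); r <- plogis(o$par[2])
  list(loglik = -o$objective, par = o$par,
       weights = c(q * r, (1 - q) * r, q * (1 - r), (1 - q) * (1 - r)))
}

#' Branch-site test for positive selection on one foreground branch
#'
#' Fits the branch-site model (Model A) on a designated foreground branch
#' and its null counterpart with the foreground omega fixed at 1, and
#' reports the likelihood-ratio test. Site classes: purifying (`omega0`
#' everywhere), neutral (1 everywhere), and two selected classes that use
#' `omega2` on the foreground branch only. Mixture weights follow the
#' Model A constraint; `omega0`, `kappa` and (in the alternative) `omega2`
#' are optimised with the class proportions profiled out at every step.
#' The alternative is run from four `omega2` starting values (0.5, 1, 1.5,
#' 2; values below the `omega2 >= 1` bound are projected just above 1) and
#' the best likelihood is kept, so the reported alternative likelihood
#' dominates every single start. Branch lengths are fixed at the
#' [codon_branch_lengths()] estimate for both hypotheses.
#'
#' @param alignment In-frame codon alignment.
#' @param tree Nucleotide `gene_tree`/`phylo`; rescaled internally.
#' @param foreground `"BP_ancestral"` or `"CP_stem"`.
#' @param topology A [species_topology()].
#' @param pi Codon frequencies; default F3x4 from the alignment.
#' @param prelim Optional precomputed [codon_branch_lengths()] result
#'   (reused across the two foreground tests of the same gene).
#' @param omega2_starts Starting values for the foreground omega.
#' @param gene_id Optional identifier carried into the result.
#' @return Object of class `branch_site_fit`; when the foreground branch is
#'   not identifiable in this gene tree the fit is returned with
#'   `skipped = TRUE` and a reason.
#' @export
fit_branch_site <- function(alignment, tree,
                            foreground = c("BP_ancestral", "CP_stem"),
                            topology = species_topology(), pi = NULL,
                            prelim = NULL,
                            omega2_starts = c(0.5, 1, 1.5, 2),
                            gene_id = NA_character_) {
  foreground <- match.arg(foreground)
  phy_in <- if (inherits(tree, "gene_tree")) tree$tree else tree
  aln <- as_nuc_matrix(alignment)[phy_in$tip.label, , drop = FALSE]
  if (is.null(pi)) pi <- f3x4(aln)
  if (is.null(prelim)) prelim <- codon_branch_lengths(aln, phy_in, pi = pi)
  phy <- prelim$phy
  fg <- foreground_edge(phy, foreground, topology)
  base <- structure(
    list(gene_id = gene_id, foreground = foreground, skipped = FALSE,
         skip_reason = NA_character_, tree = phy), class = "branch_site_fit")
  if (is.na(fg)) {
    base$skipped <- TRUE
    base$skip_reason <- "foreground branch not identifiable"
    return(base)
  }
  codes <- codon_codes(aln)
  pat <- compress_patterns(codes)
  td <- tree_data(phy, pat$codes)
  # foreground edge index must refer to the postorder edge table used by the
  # pruning kernel; foreground_edge() already works in postorder
  type <- get("type", envir = .gs)
  inner_start <- c(qlogis(0.7), qlogis(0.8))
  # class matrices share one scale anchored on the preliminary one-ratio fit,
  # so the fixed branch lengths keep their units across both hypotheses
  # the foreground branch length is re-optimised under each hypothesis (as a
  # multiplier on its preliminary value); all other branch lengths stay fixed.
  # Without this freedom, a substitution burst on the foreground branch gets
  # absorbed into the shared branch-length estimate and the test loses power.
  eval_model <- function(omega0, omega2, kappa, fg_mult = 1) {
    fl <- codon_flux(kappa, 1, pi)
    scale <- fl$s1 + prelim$omega * fl$n1
    lens <- td$lens
    lens[fg] <- lens[fg] * fg_mult
    cls <- modelA_site_loglik_cpp(td$codes, td$edge, lens, unname(pi),
                                  type, kappa, omega0, omega2, fg,
                                  td$nnode, td$ntip, scale)
    pw <- profile_weights(cls, pat$weights, start = inner_start)
    inner_start <<- pw$par
    list(loglik = pw$loglik, weights = pw$weights, cls = cls)
  }
  # null: omega2 fixed at 1; optimise (omega0, kappa, fg length)
  null_nll <- function(p)
    -eval_model(plogis(p[1]), 1, exp(p[2]), exp(p[3]))$loglik
  null_fit <- nlminb(c(qlogis(min(prelim$omega, 0.9)), log(prelim$kappa), 0),
                     null_nll, lower = c(-12, log(0.01), log(0.02)),
                     upper = c(12, log(100), log(50)),
                     control = list(iter.max = 100, rel.tol = 1e-8))
  null_state <- eval_model(plogis(null_fit$par[1]), 1, exp(null_fit$par[2]),
                           exp(null_fit$par[3]))
  lnl_null <- null_state$loglik

  # alternative: omega2 = 1 + exp(z) free, warm-started from the null; kappa
  # is carried over from the null maximum (it is insensitive to omega2), so
  # the four omega2 starts optimise (omega0, omega2, foreground length)
  kappa_hat <- exp(null_fit$par[2])
  alt_nll <- function(p)
    -eval_model(plogis(p[1]), 1 + exp(p[2]), kappa_hat, exp(p[3]))$loglik
  best <- NULL
  z_starts <- unique(vapply(omega2_starts,
                            function(w2) log(max(w2, 1 + 1e-6) - 1),
                            numeric(1)))
  for (z0 in z_starts) {
    fit <- nlminb(c(null_fit$par[1], z0, null_fit$par[3]), alt_nll,
                  lower = c(-12, -18, log(0.02)),
                  upper = c(12, log(99), log(50)),
                  control = list(iter.max = 100, rel.tol = 1e-8))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  alt_state <- eval_model(plogis(best$par[1]), 1 + exp(best$par[2]),
                          kappa_hat, exp(best$par[3]))

  # guard against a spurious ratio caused by the null stopping short of its
  # optimum: re-polish the null from the alternative's parameters
  if (alt_state$loglik - lnl_null > 0.75) {
    refit <- nlminb(c(best$par[1], null_fit$par[2], best$par[3]), null_nll,
                    lower = c(-12, log(0.01), log(0.02)),
                    upper = c(12, log(100), log(50)),
                    control = list(iter.max = 100, rel.tol = 1e-8))
    if (refit$objective < null_fit$objective) {
      null_fit <- refit
      null_state <- eval_model(plogis(null_fit$par[1]), 1,
                               exp(null_fit$par[2]), exp(null_fit$par[3]))
      lnl_null <- null_state$loglik
    }
  }
  lnl_alt <- max(alt_state$loglik, lnl_null)  # nesting guarantee

  lr <- max(0, 2 * (alt_state$loglik - lnl_null))
  # per-site posterior over the four classes at the alternative MLE
  emx <- pmax(alt_state$cls[, 1], alt_state$cls[, 2],
              alt_state$cls[, 3], alt_state$cls[, 4])
  E <- exp(alt_state$cls - emx)
  wts <- alt_state$weights
  lik <- pmax(as.vector(E %*% wts), 1e-300)
  post <- sweep(E, 2, wts, `*`) / lik
  p_sel <- (post[, 3] + post[, 4])[pat$map]
  base$lnl_null <- lnl_null
  base$lnl_alt <- lnl_alt
  base$lr <- lr
  base$p_value <- lrt_pvalue(lnl_null, lnl_alt)
  base$omega0 <- plogis(best$par[1])
  base$omega2 <- 1 + exp(best$par[2])
  base$kappa <- kappa_hat
  base$fg_length <- td$lens[fg] * exp(best$par[3])
  base$weights <- wts
  base$p0 <- wts[1]
  base$p1 <- wts[2]
  base$posterior <- tibble::tibble(site = seq_along(p_sel),
                                   p_selected = p_sel)
  base$fg_edge <- fg
  base
}

#' @export
print.branch_site_fit <- function(x, ...) {
  if (x$skipped) {
    cat("Branch-site fit (", x$foreground, "): skipped - ",
        x$skip_reason, "\n", sep = "")
    return(invisible(x))
  }
  cat("Branch-site LRT on ", x$foreground, "\n",
      "  lnL(null) = ", format(x$lnl_null, digits = 9),
      ",  lnL(alt) = ", format(x$lnl_alt, digits = 9), "\n",
      "  LR = ", format(x$lr, digits = 5),
      ",  P = ", format(x$p_value, digits = 4),
      ",  omega2 = ", format(x$omega2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Chi-square likelihood-ratio p-value (1 df)
#'
#' Upper tail of the chi-square distribution with one degree of freedom at
#' `LR = 2 (lnL1 - lnL0)`, clamped at zero against numerical noise.
#'
#' @param lnl0,lnl1 Null and alternative log-likelihoods.
#' @return P-value in `[0, 1]`.
#' @examples
#' lrt_pvalue(-100, -100)  # 1
#' @export
lrt_pvalue <- function(lnl0, lnl1) {
  lr <- pmax(0, 2 * (lnl1 - lnl0))
  pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Codon sites under positive selection (naive empirical Bayes)
#'
#' Sites whose posterior probability of belonging to a positively selected
#' class (2a or 2b), evaluated at the alternative-model MLE, reaches the
#' cutoff. This is naive empirical Bayes: parameter uncertainty is not
#' integrated over, only the point estimates are used.
#'
#' @param fit A non-skipped `branch_site_fit`.
#' @param cutoff Posterior threshold (default 0.9).
#' @return Integer vector of 1-based codon positions.
#' @export
neb_sites <- function(fit, cutoff = 0.9) {
  stopifnot(inherits(fit, "branch_site_fit"), !fit$skipped)
  fit$posterior$site[fit$posterior$p_selected >= cutoff]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.branch_site_fit <- function(x, ...) {
  if (x$skipped) return(tibble::tibble())
  tibble::tibble(
    term = c("omega0", "omega2", "kappa", "p0", "p1", "p2a", "p2b"),
    estimate = c(x$omega0, x$omega2, x$kappa, x$weights))
}

#' @export
glance.branch_site_fit <- function(x, ...) {
  if (x$skipped) {
    return(tibble::tibble(
      gene_id = x$gene_id, foreground = x$foreground,
      lnl_null = NA_real_, lnl_alt = NA_real_, lr = NA_real_,
      p_value = NA_real_, omega2 = NA_real_, n_sites = NA_integer_,
      skipped = TRUE))
  }
  tibble::tibble(
    gene_id = x$gene_id, foreground = x$foreground,
    lnl_null = x$lnl_null, lnl_alt = x$lnl_alt, lr = x$lr,
    p_value = x$p_value, omega2 = x$omega2,
    n_sites = length(neb_sites(x)), skipped = FALSE)
}

#' @export
augment.branch_site_fit <- function(x, ...) {
  stopifnot(!x$skipped)
  x$posterior
}

#' Branch-site tests across a gene set
#'
#' Runs [fit_branch_site()] for every gene and every requested foreground
#' branch, then adjusts p-values per foreground branch with
#' Benjamini-Hochberg false discovery rate ([fdr_adjust()]).
#'
#' @param alignments Named list of codon alignments.
#' @param trees Named list of matching gene trees.
#' @param foregrounds Foreground branches to test.
#' @param topology A [species_topology()].
#' @param neb_cutoff Posterior cutoff for reported sites.
#' @return Tibble with one row per (gene, foreground): likelihoods, `lr`,
#'   `p_value`, `q_value`, `omega2`, and the NEB `sites` string.
#' @export
test_selection <- function(alignments, trees,
                           foregrounds = c("BP_ancestral", "CP_stem"),
                           topology = species_topology(),
                           neb_cutoff = 0.9) {
  rows <- purrr::imap(alignments, function(aln, id) {
    tr <- trees[[id]]
    if (is.null(tr)) return(NULL)
    prelim <- codon_branch_lengths(aln, tr)
    purrr::map_dfr(foregrounds, function(fgb) {
      fit <- fit_branch_site(aln, tr, foreground = fgb,
                             topology = topology, prelim = prelim,
                             gene_id = id)
      g <- glance(fit)
      g$sites <- if (fit$skipped) NA_character_ else
        paste(neb_sites(fit, neb_cutoff), collapse = ";")
      g
    })
  })
  res <- dplyr::bind_rows(rows)
  res$q_value <- NA_real_
  for (fgb in unique(res$foreground)) {
    sel <- res$foreground == fgb & !res$skipped
    res$q_value[sel] <- fdr_adjust(res$p_value[sel])
  }
  dplyr::relocate(res, "q_value", .after = "p_value")
}
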