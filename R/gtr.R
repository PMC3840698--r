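#' General time-reversible nucleotide model with discrete-gamma rates
#'
#' @param exch Six exchangeabilities in the order AC, AG, AT, CG, CT, GT;
#'   GT is conventionally fixed at 1 for identifiability.
#' @param base_freq Stationary base frequencies (A, C, G, T), summing to 1.
#' @param alpha Gamma shape for among-site rate variation; `Inf` disables
#'   rate variation.
#' @param ncat Number of discrete (equal-weight, mean-one) rate categories.
#' @return A validated list of class `gtr_model`.
#' @examples
#' jc <- gtr_model()  # equal rates and frequencies: Jukes-Cantor limit
#' @export
gtr_model <- function(exch = rep(1, 6), base_freq = rep(0.25, 4),
                      alpha = Inf, ncat = 4L) {
  stopifnot(length(exch) == 6, all(exch > 0),
            length(base_freq) == 4, all(base_freq > 0),
            abs(sum(base_freq) - 1) < 1e-12, alpha > 0, ncat >= 1)
  structure(list(exch = as.numeric(exch),
                 base_freq = as.numeric(base_freq),
                 alpha = alpha, ncat = as.integer(ncat)),
            class = "gtr_model")
}

# Discrete-gamma category rates (median discretisation, normalised to mean 1).
gamma_rates <- function(alpha, ncat) {
  if (is.infinite(alpha) || ncat == 1L) return(1)
  r <- qgamma((seq_len(ncat) - 0.5) / ncat, shape = alpha, rate = alpha)
  r / mean(r)
}

#' GTR rate matrix of a model
#'
#' The instantaneous rate matrix, scaled to one expected substitution per
#' site at stationarity (rows sum to zero).
#'
#' @param model A [gtr_model()].
#' @return 4 x 4 numeric matrix with A, C, G, T dimnames.
#' @export
gtr_rate_matrix <- function(model) {
  Q <- gtr_q_cpp(model$base_freq, model$exch)
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  Q
}

#' Phylogenetic log-likelihood under GTR+Gamma
#'
#' Felsenstein-pruning log-likelihood of a nucleotide alignment on a tree,
#' summed over sites and averaged over the equal-weight discrete gamma
#' categories. Gaps and ambiguous symbols are treated as missing data.
#'
#' @param alignment Character matrix (taxa x sites) or named character
#'   vector of equal-length sequences.
#' @param tree `phylo` with branch lengths in expected substitutions/site.
#' @param model A [gtr_model()].
#' @return Log-likelihood (scalar).
#' @export
gtr_loglik <- function(alignment, tree, model = gtr_model()) {
  codes <- nuc_codes(alignment)
  if (ncol(codes) == 0) stop("empty alignment", call. = FALSE)
  pat <- compress_patterns(codes)
  td <- tree_data(tree, pat$codes)
  ll <- nuc_site_loglik_cpp(td$codes, td$edge, td$lens, model$base_freq,
                            model$exch, gamma_rates(model$alpha, model$ncat),
                            td$nnode, td$ntip)
  sum(pat$weights * ll)
}

#' Maximum-likelihood pairwise distance under GTR
#'
#' Optimises the evolutionary distance between two sequences under a fixed
#' GTR(+Gamma) model by maximising the two-sequence likelihood; sites with
#' a gap or ambiguity in either sequence are excluded. In the equal-rate,
#' equal-frequency limit this reproduces the Jukes-Cantor closed form.
#'
#' @param a,b Nucleotide sequences (strings or character vectors).
#' @param model A [gtr_model()].
#' @param upper Upper search bound for the distance.
#' @return ML distance in expected substitutions per site.
#' @export
gtr_pairwise_distance <- function(a, b, model = gtr_model(), upper = 10) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  idx <- get("nuc_index", envir = .gs)
  ia <- idx[a]; ib <- idx[b]
  ok <- !is.na(ia) & !is.na(ib)
  counts <- table(factor(ia[ok], levels = 0:3), factor(ib[ok], levels = 0:3))
  counts <- as.matrix(counts)
  Q <- gtr_q_cpp(model$base_freq, model$exch)
  rates <- gamma_rates(model$alpha, model$ncat)
  pi <- model$base_freq
  nll <- function(t) {
    P <- 0
    for (r in rates) P <- P + rev_pmat_cpp(Q, pi, t * r) / length(rates)
    lp <- log(pmax(pi * P, 1e-300))
    -sum(counts * lp)
  }
  optimize(nll, c(1e-9, upper), tol = 1e-10)$minimum
}
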