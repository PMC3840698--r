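#' Goldman-Yang style codon rate matrix
#'
#' Builds the 61-state codon rate matrix: a substitution between codons
#' differing at exactly one position has rate proportional to the target
#' codon frequency times 1, `kappa`, `omega`, or `kappa * omega` for a
#' synonymous transversion, synonymous transition, nonsynonymous
#' transversion, or nonsynonymous transition respectively; all other rates
#' (including anything into a stop codon) are zero. The matrix is scaled to
#' one expected substitution per codon per unit branch length at
#' stationarity.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (> 0).
#' @param pi Codon frequencies over [sense_codons()], summing to 1.
#' @param observed Optional integer codon codes; an error is raised when any
#'   observed codon has zero frequency.
#' @return 61 x 61 rate matrix with codon dimnames.
#' @examples
#' Q <- codon_q(2, 0.5, rep(1 / 61, 61))
#' range(rowSums(Q))  # rows sum to zero
#' @export
codon_q <- function(kappa, omega, pi, observed = NULL) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  pi <- as.numeric(pi)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1", call. = FALSE)
  if (!is.null(observed)) {
    obs <- unique(observed[observed >= 0]) + 1L
    if (any(pi[obs] <= 0))
      stop("zero frequency for an observed codon", call. = FALSE)
  }
  Q <- codon_q_cpp(kappa, omega, pi, get("type", envir = .gs))
  dimnames(Q) <- list(sense_codons(), sense_codons())
  Q
}

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies (codon positions 1, 2, 3) are
#' multiplied per codon, stop codons are excluded, and the result is
#' renormalised over the 61 sense codons. Gaps and ambiguous symbols are
#' ignored in the counts. Frequencies of codons never observable from the
#' data (a base absent at one position) are floored at a tiny positive
#' value before renormalisation so downstream matrices stay well defined.
#'
#' @param alignment Character matrix or named character vector (in-frame).
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4 <- function(alignment) {
  aln <- as_nuc_matrix(alignment)
  nc <- ncol(aln)
  if (nc == 0) stop("empty alignment", call. = FALSE)
  if (nc %% 3L != 0L)
    stop("alignment length is not a multiple of 3", call. = FALSE)
  pos <- rep(1:3, length.out = nc)
  freqs <- sapply(1:3, function(p) {
    tab <- table(factor(aln[, pos == p], levels = c("A", "C", "G", "T")))
    f <- as.numeric(tab)
    if (sum(f) == 0) stop("empty alignment", call. = FALSE)
    f / sum(f)
  })
  bf <- t(freqs)
  colnames(bf) <- c("A", "C", "G", "T")
  codons <- sense_codons()
  cmat <- do.call(rbind, strsplit(codons, ""))
  pi <- bf[1, cmat[, 1]] * bf[2, cmat[, 2]] * bf[3, cmat[, 3]]
  pi <- pmax(pi, 1e-10)
  pi <- pi / sum(pi)
  names(pi) <- codons
  pi
}

#' Site-class mixture model for codon likelihoods
#'
#' Describes a mixture of site classes, each with a weight, a background
#' omega (used on every branch) and a foreground omega (used only on the
#' designated foreground branches). A single class with equal background
#' and foreground omega is an ordinary one-ratio codon model; the
#' branch-site Model A layout is the four-class special case.
#'
#' @param weights Class weights (must sum to 1).
#' @param omega_bg Background omega per class.
#' @param omega_fg Foreground omega per class (defaults to `omega_bg`).
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (61).
#' @return A list of class `site_class_model`.
#' @export
site_class_model <- function(weights, omega_bg, omega_fg = omega_bg,
                             kappa = 2, pi = rep(1 / 61, 61)) {
  stopifnot(length(weights) == length(omega_bg),
            length(omega_fg) == length(omega_bg),
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0),
            all(omega_bg >= 0), all(omega_fg >= 0), kappa > 0,
            length(pi) == 61)
  structure(list(weights = as.numeric(weights),
                 omega_bg = as.numeric(omega_bg),
                 omega_fg = as.numeric(omega_fg),
                 kappa = kappa, pi = as.numeric(pi) / sum(pi)),
            class = "site_class_model")
}

#' Codon mixture log-likelihood on a tree
#'
#' Pruning log-likelihood over the 61 sense codons: each site's likelihood
#' is the weighted sum over site classes of the pruning likelihood in which
#' foreground branches use the class's foreground omega and all other
#' branches its background omega; the total is the sum of site logs.
#'
#' @param alignment In-frame codon alignment (character matrix or named
#'   vector); codons containing gaps/ambiguities are missing data.
#' @param tree `phylo` with branch lengths in expected substitutions per
#'   codon.
#' @param model A [site_class_model()].
#' @param foreground Integer vector of postorder edge indices treated as
#'   foreground (empty/NULL for none).
#' @return Log-likelihood (scalar).
#' @export
codon_loglik <- function(alignment, tree, model, foreground = NULL) {
  codes <- codon_codes(alignment)
  pat <- compress_patterns(codes)
  td <- tree_data(tree, pat$codes)
  scale <- mixture_scale(model$kappa, model$omega_bg, model$weights,
                         model$pi)
  cls <- codon_class_loglik_cpp(
    td$codes, td$edge, td$lens, model$pi, get("type", envir = .gs),
    model$kappa, model$omega_bg, model$omega_fg,
    as.integer(foreground %||% integer(0)), td$nnode, td$ntip, scale)
  sum(pat$weights * logsumexp_rows(cls, model$weights))
}

# Synonymous/nonsynonymous flux fractions of an (unscaled) GY94 process.
# Returns the synonymous fraction of total substitution flux at the given
# omega, the synonymous "site" fraction (flux fraction at omega = 1), and
# the raw synonymous/nonsynonymous flux parts.
codon_flux <- function(kappa, omega, pi) {
  type <- get("type", envir = .gs)
  pp <- outer(pi, pi)
  s1 <- sum(pp[type == 1L]) + kappa * sum(pp[type == 2L])
  n1 <- sum(pp[type == 3L]) + kappa * sum(pp[type == 4L])
  list(rho_s = s1 / (s1 + omega * n1), f_s = s1 / (s1 + n1),
       s1 = s1, n1 = n1)
}

# Common scale for a set of site classes: the stationary substitution flux of
# the mixture's background process. Dividing every class matrix by this one
# constant preserves the relative rates between classes (a positively
# selected class genuinely substitutes faster), while a branch length of t
# still means t expected substitutions per codon under the background
# mixture. This mirrors the convention of the standard codon-model tools.
mixture_scale <- function(kappa, omegas, weights, pi) {
  fl <- codon_flux(kappa, 1, pi)
  sum(weights * (fl$s1 + omegas * fl$n1))
}
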