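#' Simulation configuration for synthetic ortholog datasets
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study conditions this package targets: a gene set in
#' which roughly 9% of genes are labelled low-temperature-induced (LTI),
#' alignments of about 400 codons (~1200 bp), per-species missingness
#' mirroring the relative coverage of the eight grass species, and a small
#' rate of planted non-orthologous contaminants to exercise the long-branch
#' quality control.
#'
#' Site classes follow the branch-site (Model A) layout: a purifying class
#' (`omega0` on all branches), a neutral class, and two positively selected
#' classes whose foreground ratio `omega2` applies only on the designated
#' foreground branches of LTI genes. Background genes evolve with
#' `omega2 = 1` (no positive selection anywhere).
#'
#' @param n_genes Number of genes to simulate.
#' @param lti_fraction Probability a gene is labelled LTI.
#' @param n_codons Codons per gene; a scalar or a length-2 range sampled
#'   uniformly per gene.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega0 Purifying-class dN/dS, in (0, 1).
#' @param omega2 Foreground dN/dS for positively selected classes of LTI
#'   genes (>= 1).
#' @param p0,p1 Proportions of the purifying and neutral site classes; the
#'   remaining `1 - p0 - p1` is split between the two selected classes in
#'   proportion `p0 : p1`.
#' @param foreground Foreground branch name(s) on which LTI genes experience
#'   positive selection.
#' @param base_freqs 3 x 4 matrix of position-specific nucleotide
#'   frequencies (rows = codon positions, columns = A, C, G, T) from which
#'   stationary codon frequencies are built (F3x4 style).
#' @param dropout_probs Named per-species probability that the gene lacks
#'   that species.
#' @param contaminant_rate Probability a gene receives one long-branch
#'   non-ortholog (an independently re-evolved sequence on a 3.5x-scaled
#'   terminal branch).
#' @param contaminant_scale Terminal-branch scaling factor for contaminants.
#' @param seed Base RNG seed used by [generate_dataset()].
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' @export
sim_config <- function(n_genes = 100,
                       lti_fraction = 0.09,
                       n_codons = 400,
                       kappa = 2.5,
                       omega0 = 0.1,
                       omega2 = 8,
                       p0 = 0.6,
                       p1 = 0.25,
                       foreground = "BP_ancestral",
                       base_freqs = default_base_freqs(),
                       dropout_probs = default_dropout_probs(),
                       contaminant_rate = 0.02,
                       contaminant_scale = 3.5,
                       seed = 1L) {
  stopifnot(n_genes >= 1, lti_fraction >= 0, lti_fraction <= 1,
            all(n_codons >= 1), length(n_codons) %in% c(1L, 2L),
            kappa > 0, omega0 > 0, omega0 <= 1, omega2 >= 1,
            p0 >= 0, p1 >= 0, p0 + p1 <= 1,
            all(dropout_probs >= 0), all(dropout_probs <= 1),
            contaminant_rate >= 0, contaminant_rate <= 1,
            contaminant_scale > 0)
  stopifnot(is.matrix(base_freqs), nrow(base_freqs) == 3,
            ncol(base_freqs) == 4, all(base_freqs > 0))
  base_freqs <- base_freqs / rowSums(base_freqs)
  structure(list(
    n_genes = as.integer(n_genes), lti_fraction = lti_fraction,
    n_codons = as.integer(n_codons), kappa = kappa, omega0 = omega0,
    omega2 = omega2, p0 = p0, p1 = p1, foreground = foreground,
    base_freqs = base_freqs, dropout_probs = dropout_probs,
    contaminant_rate = contaminant_rate,
    contaminant_scale = contaminant_scale,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default position-specific base frequencies
#'
#' Mildly GC-rich composition with an elevated GC content at the third codon
#' position, as is typical of grass coding sequences.
#'
#' @return 3 x 4 matrix (rows = codon positions; columns = A, C, G, T).
#' @export
default_base_freqs <- function() {
  m <- rbind(c(0.27, 0.23, 0.31, 0.19),
             c(0.29, 0.23, 0.21, 0.27),
             c(0.19, 0.30, 0.31, 0.20))
  dimnames(m) <- list(paste0("pos", 1:3), c("A", "C", "G", "T"))
  m
}

#' Default per-species dropout probabilities
#'
#' Set from the relative per-species coverage of a published 4330-tree grass
#' ortholog collection (fraction of trees lacking each species); the anchor
#' species (*B. distachyon*) and rice are never dropped.
#'
#' @return Named numeric vector over the eight species.
#' @export
default_dropout_probs <- function() {
  c(maize = 0.056, sorghum = 0.030, rice = 0, brachypodium = 0,
    wheat = 0.257, barley = 0.129, lolium = 0.066, festuca = 0.589)
}

# Class proportions (p0, p1, p2a, p2b) from the Model A parameterisation.
site_class_weights <- function(p0, p1) {
  s <- p0 + p1
  p2 <- 1 - s
  c(p0 = p0, p1 = p1, p2a = p2 * p0 / s, p2b = p2 * p1 / s)
}

# F3x4 codon frequencies from a 3 x 4 base-frequency matrix.
f3x4_from_base_freqs <- function(base_freqs) {
  codons <- sense_codons()
  cmat <- do.call(rbind, strsplit(codons, ""))
  idx <- get("nuc_index", envir = .gs) + 1L
  pi <- base_freqs[1, idx[cmat[, 1]]] *
    base_freqs[2, idx[cmat[, 2]]] *
    base_freqs[3, idx[cmat[, 3]]]
  pi <- pi / sum(pi)
  names(pi) <- codons
  pi
}
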