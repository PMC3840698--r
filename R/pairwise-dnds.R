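#' Pairwise dN and dS by maximum likelihood
#'
#' Fits the two-sequence codon model by maximising the likelihood over the
#' divergence `t` (expected substitutions per codon), `kappa` and `omega`,
#' then decomposes the distance into synonymous and nonsynonymous
#' substitutions per synonymous / nonsynonymous site: with `rho_s` the
#' synonymous fraction of substitution flux under the fitted process and
#' `f_s` the synonymous site fraction (the flux fraction of the same
#' process at omega = 1),
#' `dS = t * rho_s / (3 * f_s)` and `dN = t * (1 - rho_s) / (3 * (1 - f_s))`,
#' so that `dN/dS` equals the fitted `omega` exactly.
#'
#' @param a,b Equal-length in-frame nucleotide sequences (strings, character
#'   vectors, or two rows of an alignment); at least 30 codons. Codons with
#'   a gap or ambiguity in either sequence are excluded.
#' @param pi Codon frequencies; defaults to F3x4 computed from the pair.
#' @param t_max Upper bound for `t`; a fit hitting it is flagged saturated.
#' @return One-row tibble: `t`, `kappa`, `omega`, `dN`, `dS`, `saturated`.
#' @examples
#' s <- strrep("ATGGCTAAGCTTGGG", 8)  # 40 codons
#' estimate_pairwise_dnds(s, s)$dS  # identical sequences: 0
#' @export
estimate_pairwise_dnds <- function(a, b, pi = NULL, t_max = 20) {
  aln <- rbind(a = seq_chars(a), b = seq_chars(b))
  if (ncol(aln) %% 3L != 0L)
    stop("sequences are not in frame", call. = FALSE)
  if (ncol(aln) < 90L)
    stop("need at least 30 codons", call. = FALSE)
  codes <- codon_codes(aln)
  ok <- codes[1, ] >= 0L & codes[2, ] >= 0L
  if (!any(ok)) stop("no comparable codons", call. = FALSE)
  if (is.null(pi)) pi <- f3x4(aln)
  key <- paste(codes[1, ok], codes[2, ok])
  tab <- table(key)
  pair <- do.call(rbind, strsplit(names(tab), " "))
  ia <- as.integer(pair[, 1]); ib <- as.integer(pair[, 2])
  cnt <- as.numeric(tab)
  type <- get("type", envir = .gs)
  pdiff <- mean(codes[1, ok] != codes[2, ok])
  nll <- function(p) {
    -codon_pair_loglik_cpp(ia, ib, cnt, unname(pi), type,
                           exp(p[2]), exp(p[3]), exp(p[1]))
  }
  start <- c(log(max(0.5 * pdiff + 1e-4, 1e-3)), log(2), log(0.3))
  fit <- nlminb(start, nll,
                lower = c(log(1e-8), log(0.01), log(1e-4)),
                upper = c(log(t_max), log(100), log(100)))
  t_hat <- exp(fit$par[1]); kappa <- exp(fit$par[2]); omega <- exp(fit$par[3])
  fl <- codon_flux(kappa, omega, pi)
  dS <- t_hat * fl$rho_s / (3 * fl$f_s)
  dN <- t_hat * (1 - fl$rho_s) / (3 * (1 - fl$f_s))
  tibble::tibble(t = t_hat, kappa = kappa, omega = omega, dN = dN, dS = dS,
                 saturated = t_hat > 0.995 * t_max)
}

seq_chars <- function(x) {
  if (is.character(x) && length(x) == 1L) strsplit(toupper(x), "")[[1]]
  else toupper(as.character(x))
}

#' Per-species lineage rates relative to the outgroups
#'
#' For every gene and every non-outgroup species present in its tree,
#' extracts the GTR cophenetic distance to the outgroup(s) from the gene
#' tree and estimates pairwise dN and dS between the species and each
#' outgroup present; when both outgroups are present the mean over the two
#' is reported, mirroring the treatment of the tree distances.
#'
#' @param alignments Named list of in-frame codon alignments.
#' @param trees Named list of `gene_tree`/`phylo` objects (same names).
#' @param labels Optional tibble `gene_id`, `is_lti` used to flag rows.
#' @param topology A [species_topology()].
#' @return Tibble with one row per (gene, species): `gene_id`, `species`,
#'   `gtr_distance`, `dS`, `dN`, `saturated`, `is_lti`.
#' @export
lineage_rates <- function(alignments, trees, labels = NULL,
                          topology = species_topology()) {
  og <- outgroup_species(topology)
  rows <- purrr::imap(alignments, function(aln, id) {
    phy <- trees[[id]]
    if (is.null(phy)) return(NULL)
    if (inherits(phy, "gene_tree")) phy <- phy$tree
    present <- intersect(rownames(aln), phy$tip.label)
    og_here <- intersect(og, present)
    if (length(og_here) == 0) return(NULL)
    pi <- f3x4(aln[present, , drop = FALSE])
    purrr::map_dfr(setdiff(present, og), function(sp) {
      fits <- purrr::map_dfr(og_here, function(o)
        estimate_pairwise_dnds(aln[sp, ], aln[o, ], pi = pi))
      tibble::tibble(
        gene_id = id, species = sp,
        gtr_distance = outgroup_distance(phy, sp, og),
        dS = mean(fits$dS), dN = mean(fits$dN),
        saturated = any(fits$saturated))
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene_id = character(0), species = character(0),
                          gtr_distance = numeric(0), dS = numeric(0),
                          dN = numeric(0), saturated = logical(0),
                          is_lti = logical(0)))
  }
  if (!is.null(labels)) {
    out <- dplyr::left_join(out, labels, by = "gene_id")
  } else {
    out$is_lti <- NA
  }
  out
}
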