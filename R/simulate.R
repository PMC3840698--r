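#' Simulate one codon alignment along the species tree
#'
#' Evolves a gene of `n_codons` codons along the species topology under a
#' branch-site codon process: each codon site is assigned independently to
#' one of four site classes (purifying, neutral, and two positively selected
#' classes), a root sequence is drawn from the stationary codon frequencies,
#' and substitutions are realized branch-by-branch by a continuous-time
#' Markov jump chain over the 61 sense codons (rates into stop codons are
#' zero). For an LTI gene the selected classes use `omega2` on the
#' configured foreground branch(es); for a background gene `omega2` is
#' forced to 1, so foreground and background branches are exchangeable.
#'
#' @param topology A [species_topology()].
#' @param cfg A [sim_config()].
#' @param gene_class `"background"` or `"lti"`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param n_codons Optional override of the configured length.
#'
#' @return A list with elements `alignment` (character matrix of nucleotides,
#'   rows named by taxa — before any dropout), `truth` (one-row tibble with
#'   the realized per-branch substitution counts nested in `branch_counts`),
#'   and `site_class` (0-based class per codon).
#' @export
simulate_gene <- function(topology, cfg, gene_class = c("background", "lti"),
                          seed = NULL, n_codons = NULL) {
  gene_class <- match.arg(gene_class)
  if (!is.null(seed)) set.seed(seed)
  ncod <- n_codons %||% (if (length(cfg$n_codons) == 2L)
    sample(cfg$n_codons[1]:cfg$n_codons[2], 1L) else cfg$n_codons)
  if (ncod < 1) stop("zero-length alignment requested", call. = FALSE)
  if (cfg$omega0 > 1) stop("omega0 must not exceed 1", call. = FALSE)

  phy <- ape::reorder.phylo(topology$tree, "cladewise")
  if (any(!is.finite(phy$edge.length)))
    stop("branch lengths must be finite", call. = FALSE)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  pi <- f3x4_from_base_freqs(cfg$base_freqs)
  type <- get("type", envir = .gs)

  w <- site_class_weights(cfg$p0, cfg$p1)
  site_class <- sample(0:3, ncod, replace = TRUE, prob = w)
  omega2 <- if (gene_class == "lti") cfg$omega2 else 1
  omegas <- c(cfg$omega0, 1, omega2)
  # class (rows 0,1,2a,2b) x edge assignment of omega indices (0-based)
  fg_rows <- foreground_edge_rows(phy, topology, cfg$foreground)
  nedge <- nrow(phy$edge)
  omega_assign <- matrix(rep(c(0L, 1L, 0L, 1L), nedge), 4L, nedge)
  if (length(fg_rows) > 0) omega_assign[3:4, fg_rows] <- 2L

  root_state <- sample(seq_along(pi), ncod, replace = TRUE, prob = pi) - 1L
  # all class matrices share the background-mixture flux scale, so branch
  # lengths mean expected substitutions per codon on background branches and
  # positively selected sites genuinely evolve faster on foreground branches
  scale <- mixture_scale(cfg$kappa, c(cfg$omega0, 1, cfg$omega0, 1), w,
                         unname(pi))
  sim <- sim_codon_cpp(phy$edge, phy$edge.length, root_state, site_class,
                       omega_assign, omegas, cfg$kappa, unname(pi), type,
                       ntip + phy$Nnode, root, scale)
  codons <- sense_codons()
  aln <- t(vapply(seq_len(ntip), function(i) {
    unlist(strsplit(codons[sim$states[i, ] + 1L], ""))
  }, character(3L * ncod)))
  rownames(aln) <- phy$tip.label

  labels <- edge_labels(phy)
  counts <- tibble::tibble(
    branch = labels,
    foreground = seq_len(nedge) %in% fg_rows,
    syn = sim$counts[, 1], nonsyn = sim$counts[, 2])
  truth <- tibble::tibble(
    is_lti = gene_class == "lti",
    n_codons = ncod,
    omega2_used = omega2,
    fg_syn = sum(counts$syn[counts$foreground]),
    fg_nonsyn = sum(counts$nonsyn[counts$foreground]),
    bg_syn = sum(counts$syn[!counts$foreground]),
    bg_nonsyn = sum(counts$nonsyn[!counts$foreground]),
    branch_counts = list(counts),
    selected_sites = list(which(site_class >= 2L)))
  list(alignment = aln, truth = truth, site_class = site_class,
       node_states = sim$states)
}

# Rows (cladewise edge indices) of the foreground branches in the species tree.
foreground_edge_rows <- function(phy_cladewise, topology, foreground) {
  out <- integer(0)
  sets <- edge_tip_sets(phy_cladewise)  # postorder sets
  post <- ape::reorder.phylo(phy_cladewise, "postorder")
  for (fg in foreground) {
    taxa <- sort(topology$foreground[[fg]])
    k <- which(vapply(sets, identical, logical(1), y = taxa))
    if (length(k) == 1L) {
      pair <- post$edge[k, ]
      row <- which(phy_cladewise$edge[, 1] == pair[1] &
                     phy_cladewise$edge[, 2] == pair[2])
      out <- c(out, row)
    }
  }
  out
}

# Human-readable edge labels: tip name, or "+"-joined descendant tips.
edge_labels <- function(phy) {
  sets <- edge_tip_sets(phy)
  post <- ape::reorder.phylo(phy, "postorder")
  lab_post <- vapply(sets, paste, character(1), collapse = "+")
  # map postorder labels back onto the order of phy$edge
  key_post <- paste(post$edge[, 1], post$edge[, 2])
  key <- paste(phy$edge[, 1], phy$edge[, 2])
  lab_post[match(key, key_post)]
}

#' Generate a synthetic ortholog dataset with ground truth
#'
#' Draws `cfg$n_genes` genes: each is labelled LTI with probability
#' `cfg$lti_fraction` and simulated with [simulate_gene()]; per-species
#' dropout is then applied (genes violating the downstream minimum-taxon
#' composition are still emitted — the composition filter must catch them),
#' and with probability `cfg$contaminant_rate` one non-anchor taxon is
#' replaced by a non-ortholog: a sequence independently re-evolved from the
#' same ancestral node along a `cfg$contaminant_scale`-times longer terminal
#' branch, which the long-branch quality control is designed to catch.
#'
#' The whole dataset is reproducible from `cfg$seed`.
#'
#' @param topology A [species_topology()].
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory: when given, one FASTA per gene plus
#'   `labels.tsv`, `truth.tsv`, `branch_counts.tsv` and `config.txt` are
#'   written there.
#'
#' @return A list with `alignments` (named list of character matrices, after
#'   dropout/contamination), `labels` (tibble gene_id, is_lti), `truth`
#'   (tibble with one row per gene) and `cfg`.
#' @examples
#' ds <- generate_dataset(species_topology(), sim_config(n_genes = 5, seed = 1))
#' ds$labels
#' @export
generate_dataset <- function(topology, cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  is_lti <- runif(n) < cfg$lti_fraction
  phy <- ape::reorder.phylo(topology$tree, "cladewise")
  ntip <- length(phy$tip.label)
  dropout <- cfg$dropout_probs[phy$tip.label]
  dropout[is.na(dropout)] <- 0

  alignments <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- simulate_gene(topology, cfg,
                       if (is_lti[i]) "lti" else "background")
    aln <- g$alignment
    # dropout (anchor and any zero-probability species always kept)
    drop <- phy$tip.label[runif(ntip) < dropout]
    contaminant <- NA_character_
    if (runif(1) < cfg$contaminant_rate) {
      candidates <- setdiff(rownames(aln), c("brachypodium", drop))
      if (length(candidates) > 0) {
        contaminant <- sample(candidates, 1L)
        aln[contaminant, ] <- reevolve_tip(phy, contaminant, g, cfg)
      }
    }
    if (length(drop) > 0) aln <- aln[setdiff(rownames(aln), drop), , drop = FALSE]
    alignments[[i]] <- aln
    truths[[i]] <- dplyr::mutate(g$truth, gene_id = ids[i],
                                 dropped_taxa = list(drop),
                                 contaminant_taxon = contaminant,
                                 .before = 1)
  }
  truth <- dplyr::bind_rows(truths)
  names(alignments) <- ids
  labels <- tibble::tibble(gene_id = ids, is_lti = is_lti)
  out <- list(alignments = alignments, labels = labels, truth = truth,
              cfg = cfg)
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

# Independently re-evolved replacement sequence for a contaminant taxon.
reevolve_tip <- function(phy, taxon, g, cfg) {
  tip <- match(taxon, phy$tip.label)
  row <- which(phy$edge[, 2] == tip)
  parent <- phy$edge[row, 1]
  ncod <- ncol(g$alignment) %/% 3L
  pi <- f3x4_from_base_freqs(cfg$base_freqs)
  type <- get("type", envir = .gs)
  # internal node states were recorded during the original simulation
  parent_state <- as.integer(g$node_states[parent, ])
  omegas <- c(cfg$omega0, 1)
  omega_assign <- matrix(c(0L, 1L, 0L, 1L), 4L, 1L)
  w <- site_class_weights(cfg$p0, cfg$p1)
  scale <- mixture_scale(cfg$kappa, c(cfg$omega0, 1, cfg$omega0, 1), w,
                         unname(pi))
  # evolve on a branch contaminant_scale times the tree's longest branch, so
  # the resulting terminal branch is guaranteed to trip the long-branch rule
  clen <- cfg$contaminant_scale * max(phy$edge.length)
  sim <- sim_codon_cpp(matrix(c(2L, 1L), 1L, 2L), clen,
                       parent_state, g$site_class, omega_assign, omegas,
                       cfg$kappa, unname(pi), type, 2L, 2L, scale)
  unlist(strsplit(sense_codons()[sim$states[1, ] + 1L], ""))
}

# Write a generated dataset as plain-text files: one FASTA per gene, the LTI
# label table, the ground-truth table (with per-branch counts in long
# format), and the configuration echoed as key=value lines.
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fasta_dir <- file.path(out_dir, "fasta")
  dir.create(fasta_dir, showWarnings = FALSE)
  for (id in names(ds$alignments)) {
    write_fasta(ds$alignments[[id]], file.path(fasta_dir, paste0(id, ".fasta")))
  }
  readr_write <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  readr_write(ds$labels, file.path(out_dir, "labels.tsv"))
  flat <- dplyr::mutate(ds$truth,
    dropped_taxa = vapply(.data$dropped_taxa, paste, character(1),
                          collapse = ","),
    branch_counts = NULL, selected_sites = NULL)
  readr_write(flat, file.path(out_dir, "truth.tsv"))
  bc <- dplyr::bind_rows(lapply(seq_len(nrow(ds$truth)), function(i) {
    dplyr::mutate(ds$truth$branch_counts[[i]],
                  gene_id = ds$truth$gene_id[i], .before = 1)
  }))
  readr_write(bc, file.path(out_dir, "branch_counts.tsv"))
  cfg <- ds$cfg
  kv <- c(
    sprintf("n_genes=%d", cfg$n_genes),
    sprintf("lti_fraction=%g", cfg$lti_fraction),
    sprintf("n_codons=%s", paste(cfg$n_codons, collapse = ":")),
    sprintf("kappa=%g", cfg$kappa), sprintf("omega0=%g", cfg$omega0),
    sprintf("omega2=%g", cfg$omega2),
    sprintf("p0=%g", cfg$p0), sprintf("p1=%g", cfg$p1),
    sprintf("foreground=%s", paste(cfg$foreground, collapse = ",")),
    sprintf("dropout_probs=%s",
            paste(names(cfg$dropout_probs), cfg$dropout_probs,
                  sep = ":", collapse = ",")),
    sprintf("contaminant_rate=%g", cfg$contaminant_rate),
    sprintf("contaminant_scale=%g", cfg$contaminant_scale),
    sprintf("seed=%d", cfg$seed))
  writeLines(kv, file.path(out_dir, "config.txt"))
  invisible(out_dir)
}

# Minimal FASTA writer for aligned character matrices.
write_fasta <- function(aln, path) {
  seqs <- apply(aln, 1L, paste, collapse = "")
  lines <- as.vector(rbind(paste0(">", names(seqs)), seqs))
  writeLines(lines, path)
}

# Minimal FASTA reader returning a character matrix (taxa x positions).
read_fasta_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- ids
  as_nuc_matrix(seqs)
}
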