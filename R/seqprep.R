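#' Filter coding sequences on basic hygiene rules
#'
#' Keeps a CDS record only when its translation starts with a start codon
#' (M), is at least 30 amino acids long, and the nucleotide sequence
#' contains only unambiguous A/C/G/T codons. A terminal stop codon is
#' tolerated (and excluded from the length count); sequences whose length is
#' not a multiple of 3, or whose translation contains an internal stop, are
#' rejected with a reason code.
#'
#' @param records Tibble with columns `id`, `species`, `sequence`
#'   (in-frame nucleotide string).
#' @param min_aa Minimum protein length in amino acids.
#' @return The kept records, with a `protein` column added; the rejected
#'   rows (with a `reason` column) are attached as attribute `"rejected"`.
#' @examples
#' recs <- tibble::tibble(id = "x", species = "barley",
#'                        sequence = paste(rep("ATG", 30), collapse = ""))
#' filter_cds(recs)
#' @export
filter_cds <- function(records, min_aa = 30L) {
  stopifnot(all(c("id", "species", "sequence") %in% names(records)))
  res <- purrr::map(records$sequence, classify_cds, min_aa = min_aa)
  records$protein <- vapply(res, `[[`, character(1), "protein")
  records$reason <- vapply(res, `[[`, character(1), "reason")
  kept <- dplyr::filter(records, .data$reason == "ok")
  kept$reason <- NULL
  rejected <- dplyr::filter(records, .data$reason != "ok")
  attr(kept, "rejected") <- rejected
  kept
}

classify_cds <- function(seq, min_aa) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- function(reason, protein = NA_character_)
    list(reason = reason, protein = protein)
  if (n %% 3L != 0L) return(out("length_not_multiple_of_3"))
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) return(out("ambiguous_codon"))
  prot <- paste(seqinr::translate(chars), collapse = "")
  # tolerate one terminal stop
  prot <- sub("\\*$", "", prot)
  if (grepl("\\*", prot)) return(out("internal_stop", prot))
  if (!startsWith(prot, "M")) return(out("no_start_codon", prot))
  if (nchar(prot) < min_aa) return(out("too_short", prot))
  out("ok", prot)
}

#' Pairwise protein similarity scores for orthology searching
#'
#' Scores every query sequence against every target sequence using protein
#' identity: the number of identical aligned positions, computed by direct
#' comparison when the translations have equal length and by a global
#' Needleman-Wunsch alignment score otherwise. This internal scorer stands
#' in for an external BLASTP step; no score threshold is ever applied
#' downstream, so only the ranking matters.
#'
#' @param query,target Tibbles with columns `id`, `species`, `protein`.
#' @param gap Linear gap penalty for the unequal-length case.
#' @return Tibble with columns `query_species`, `query_id`, `target_species`,
#'   `target_id`, `score`.
#' @export
similarity_scores <- function(query, target, gap = 1) {
  qs <- lapply(query$protein, function(p) utf8ToInt(p))
  ts <- lapply(target$protein, function(p) utf8ToInt(p))
  n <- length(qs); m <- length(ts)
  score <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      a <- qs[[i]]; b <- ts[[j]]
      score[i, j] <- if (length(a) == length(b)) sum(a == b) else
        nw_score_cpp(a, b, gap)
    }
  }
  tibble::tibble(
    query_species = rep(query$species, m),
    query_id = rep(query$id, m),
    target_species = rep(target$species, each = n),
    target_id = rep(target$id, each = n),
    score = as.vector(score))
}

#' Reciprocal-best-hit ortholog assignment
#'
#' Anchored on one species (by default *B. distachyon*): a gene `g` of
#' species `S` is assigned to the ortholog set of anchor gene `a` if and
#' only if `g` is `a`'s best-scoring hit among the `S` sequences **and**
#' `a` is `g`'s best-scoring hit among the anchor sequences. No score
#' threshold is applied. Tied top scores are broken deterministically by
#' lexicographic gene id; a species with a missing score direction is
#' simply absent from the set.
#'
#' @param scores Score table as produced by [similarity_scores()], covering
#'   both directions (anchor to species and species to anchor).
#' @param anchor_species Name of the anchor species.
#' @return Tibble with columns `anchor_id`, `species`, `gene_id` (one row
#'   per assigned member; the anchor's own row is included).
#' @export
reciprocal_best_hit <- function(scores, anchor_species = "brachypodium") {
  fwd <- dplyr::filter(scores, .data$query_species == anchor_species,
                       .data$target_species != anchor_species)
  rev <- dplyr::filter(scores, .data$target_species == anchor_species,
                       .data$query_species != anchor_species)
  best_fwd <- fwd |>
    dplyr::group_by(.data$query_id, .data$target_species) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$target_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  best_rev <- rev |>
    dplyr::group_by(.data$query_species, .data$query_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$target_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  hits <- dplyr::inner_join(
    dplyr::select(best_fwd, anchor_id = "query_id",
                  species = "target_species", gene_id = "target_id"),
    dplyr::select(best_rev, gene_id = "query_id",
                  species = "query_species", anchor_id = "target_id"),
    by = c("anchor_id", "species", "gene_id"))
  anchors <- tibble::tibble(anchor_id = sort(unique(scores$query_id[
    scores$query_species == anchor_species])))
  out <- dplyr::bind_rows(
    dplyr::mutate(anchors, species = anchor_species,
                  gene_id = .data$anchor_id),
    hits)
  dplyr::arrange(out, .data$anchor_id, .data$species)
}

#' Minimum taxon-composition rule for an ortholog set
#'
#' An ortholog set is analysable only when it contains at least one species
#' from each core Pooideae clade (wheat/barley for Hordeeae, *Lolium* /
#' *Festuca* for Poeae), plus *B. distachyon*, rice, and at least one of
#' the two PACMAD outgroups — a minimum of five taxa.
#'
#' @param species_present Character vector of species in the set.
#' @return `TRUE` when the rule passes.
#' @examples
#' composition_filter(c("barley", "lolium", "brachypodium", "rice", "maize"))
#' @export
composition_filter <- function(species_present) {
  s <- species_present
  any(c("wheat", "barley") %in% s) &&
    any(c("lolium", "festuca") %in% s) &&
    "brachypodium" %in% s &&
    "rice" %in% s &&
    any(c("maize", "sorghum") %in% s)
}

#' Label ortholog sets as low-temperature-induced
#'
#' An ortholog set counts as LTI when its barley member or its *L. perenne*
#' member appears in the LTI gene table; evidence from any other species
#' (for example wheat) does not count.
#'
#' @param sets Tibble of ortholog memberships with columns `anchor_id`,
#'   `species`, `gene_id` (as from [reciprocal_best_hit()]).
#' @param lti_table Tibble with columns `species`, `gene_id` listing known
#'   LTI genes.
#' @return Tibble with columns `anchor_id`, `is_lti`.
#' @export
label_lti <- function(sets, lti_table) {
  evidence <- dplyr::filter(sets, .data$species %in% c("barley", "lolium"))
  if (nrow(lti_table) == 0) {
    hit <- evidence[0, ]
  } else {
    hit <- dplyr::inner_join(evidence, lti_table,
                             by = c("species", "gene_id"))
  }
  sets |>
    dplyr::distinct(.data$anchor_id) |>
    dplyr::mutate(is_lti = .data$anchor_id %in% hit$anchor_id)
}

# Translate the codon rows of an alignment matrix to protein strings
# (gap/ambiguous codons become X).
translate_rows <- function(aln) {
  codes <- codon_codes(aln)
  aa <- get("codon_aa", envir = .gs)
  apply(codes, 1L, function(row) {
    p <- ifelse(row < 0, "X", aa[row + 1L])
    paste(p, collapse = "")
  })
}

#' Re-derive ortholog sets from a dataset by reciprocal best hit
#'
#' Flattens a per-gene dataset into per-species sequence pools, scores
#' every anchor-species protein against every pool ([similarity_scores()]),
#' assigns members by [reciprocal_best_hit()], rebuilds one codon alignment
#' per anchor gene, and labels sets as LTI from barley / *L. perenne*
#' evidence only ([label_lti()]). A member whose sequence length differs
#' from the anchor's cannot be aligned and is left out of the rebuilt set.
#'
#' @param dataset A dataset as returned by [generate_dataset()].
#' @param anchor Anchor species.
#' @return List with `alignments` (regrouped, named by anchor gene),
#'   `labels` (tibble `gene_id`, `is_lti` as decided by the labelling
#'   rule), and `sets` (the raw membership table).
#' @export
prep_orthologs <- function(dataset, anchor = "brachypodium") {
  recs <- purrr::imap_dfr(dataset$alignments, function(aln, gid) {
    tibble::tibble(id = paste(rownames(aln), gid, sep = "."),
                   species = rownames(aln), gene = gid,
                   protein = translate_rows(aln))
  })
  anchor_recs <- dplyr::filter(recs, .data$species == anchor)
  others <- setdiff(unique(recs$species), anchor)
  scores <- purrr::map_dfr(others, function(sp) {
    pool <- dplyr::filter(recs, .data$species == sp)
    dplyr::bind_rows(similarity_scores(anchor_recs, pool),
                     similarity_scores(pool, anchor_recs))
  })
  sets <- reciprocal_best_hit(scores, anchor_species = anchor)
  # species-level LTI evidence from the dataset's gene-level labels
  lti_genes <- dataset$labels$gene_id[dataset$labels$is_lti]
  lti_table <- dplyr::filter(recs, .data$gene %in% lti_genes,
                             .data$species %in% c("barley", "lolium")) |>
    dplyr::select("species", gene_id = "id")
  labels <- label_lti(sets, lti_table)
  rec_gene <- setNames(recs$gene, recs$id)
  alignments <- list()
  for (aid in unique(sets$anchor_id)) {
    g_anchor <- rec_gene[[aid]]
    members <- dplyr::filter(sets, .data$anchor_id == aid)
    ref_len <- ncol(dataset$alignments[[g_anchor]])
    rows <- list()
    for (j in seq_len(nrow(members))) {
      g <- rec_gene[[members$gene_id[j]]]
      sp <- members$species[j]
      src <- dataset$alignments[[g]]
      if (ncol(src) == ref_len && sp %in% rownames(src))
        rows[[sp]] <- src[sp, ]
    }
    alignments[[g_anchor]] <- do.call(rbind, rows)
  }
  labels$gene_id <- unname(rec_gene[labels$anchor_id])
  list(alignments = alignments,
       labels = dplyr::select(labels, "gene_id", "is_lti"),
       sets = sets)
}
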