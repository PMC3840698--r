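make_cds <- function(aa_len, start = TRUE, ambiguous = FALSE,
                     internal_stop = FALSE) {
  body <- paste(rep("GCT", aa_len - 1), collapse = "")  # alanines
  s <- paste0(if (start) "ATG" else "CTG", body)
  if (internal_stop) substr(s, 16, 18) <- "TAA"
  if (ambiguous) substr(s, 7, 7) <- "N"
  s
}

test_that("CDS filter enforces start, length and ambiguity rules exactly", {
  recs <- tibble::tibble(
    id = paste0("r", 1:6), species = "barley",
    sequence = c(make_cds(30),               # boundary: exactly 30 aa
                 make_cds(29),               # one below threshold
                 make_cds(40, start = FALSE),
                 make_cds(40, ambiguous = TRUE),
                 make_cds(40, internal_stop = TRUE),
                 paste0(make_cds(40), "GC")))  # length not divisible by 3
  kept <- filter_cds(recs)
  expect_equal(kept$id, "r1")
  expect_true(startsWith(kept$protein, "M"))
  rej <- attr(kept, "rejected")
  expect_equal(setNames(rej$reason, rej$id),
               c(r2 = "too_short", r3 = "no_start_codon",
                 r4 = "ambiguous_codon", r5 = "internal_stop",
                 r6 = "length_not_multiple_of_3"))
  # terminal stop is tolerated and not counted towards the length
  with_stop <- tibble::tibble(id = "s", species = "rice",
                              sequence = paste0(make_cds(30), "TGA"))
  expect_equal(nrow(filter_cds(with_stop)), 1L)
})

test_that("reciprocal best hit requires agreement in both directions", {
  scores <- tibble::tibble(
    query_species = c("brachypodium", "brachypodium", "barley", "barley"),
    query_id = c("bd1", "bd1", "hv1", "hv2"),
    target_species = c("barley", "barley", "brachypodium", "brachypodium"),
    target_id = c("hv1", "hv2", "bd1", "bd1"),
    score = c(10, 8, 9, 11))
  # bd1's best is hv1; hv1's best is bd1 -> reciprocal
  sets <- reciprocal_best_hit(scores)
  expect_true(any(sets$anchor_id == "bd1" & sets$gene_id == "hv1"))
  # break reciprocity: bd1 prefers hv2, but hv2 maps back to bd1 while
  # bd1's top target changes
  scores2 <- scores
  scores2$score[2] <- 20  # bd1 -> hv2 now best
  sets2 <- reciprocal_best_hit(scores2)
  expect_true(any(sets2$anchor_id == "bd1" & sets2$gene_id == "hv2"))
  expect_false(any(sets2$gene_id == "hv1"))
  # missing direction: species without reverse scores contributes nothing
  only_fwd <- scores[1:2, ]
  sets3 <- reciprocal_best_hit(only_fwd)
  expect_false(any(sets3$species == "barley"))
})

test_that("RBH output is invariant to score-table row order and breaks ties
           lexicographically", {
  set.seed(4)
  scores <- tibble::tibble(
    query_species = rep(c("brachypodium", "rice"), each = 9),
    query_id = c(rep(paste0("bd", 1:3), each = 3), rep(paste0("os", 1:3), 3)),
    target_species = rep(c("rice", "brachypodium"), each = 9),
    target_id = c(rep(paste0("os", 1:3), 3), rep(paste0("bd", 1:3), each = 3)),
    score = c(9, 1, 1, 1, 9, 1, 1, 1, 9, 9, 1, 1, 1, 9, 1, 1, 1, 9))
  base <- reciprocal_best_hit(scores)
  for (i in 1:5) {
    shuffled <- scores[sample.int(nrow(scores)), ]
    expect_identical(reciprocal_best_hit(shuffled), base)
  }
  # all-tied toy table: the lexicographically smallest ids win consistently
  tied <- tibble::tibble(
    query_species = c(rep("brachypodium", 2), rep("rice", 2)),
    query_id = c("bd1", "bd1", "os2", "os1"),
    target_species = c(rep("rice", 2), rep("brachypodium", 2)),
    target_id = c("os2", "os1", "bd1", "bd1"),
    score = 5)
  res <- reciprocal_best_hit(tied)
  expect_true(any(res$anchor_id == "bd1" & res$gene_id == "os1"))
  expect_false(any(res$gene_id == "os2"))
})

test_that("composition rule needs both CP clades, anchors and an outgroup", {
  all8 <- c("maize", "sorghum", "rice", "brachypodium", "wheat", "barley",
            "lolium", "festuca")
  expect_true(composition_filter(all8))
  # minimum passing set has exactly five taxa
  min5 <- c("barley", "lolium", "brachypodium", "rice", "maize")
  expect_true(composition_filter(min5))
  expect_length(min5, 5L)
  expect_false(composition_filter(setdiff(all8, "rice")))
  expect_false(composition_filter(setdiff(all8, "brachypodium")))
  expect_false(composition_filter(setdiff(all8, c("wheat", "barley"))))
  expect_false(composition_filter(setdiff(all8, c("lolium", "festuca"))))
  expect_false(composition_filter(setdiff(all8, c("maize", "sorghum"))))
})

test_that("LTI labels come from barley or Lolium evidence only", {
  sets <- tibble::tibble(
    anchor_id = c("a1", "a1", "a1", "a2", "a2", "a3"),
    species = c("brachypodium", "barley", "wheat",
                "brachypodium", "wheat", "brachypodium"),
    gene_id = c("a1", "hv9", "ta1", "a2", "ta7", "a3"))
  lti <- tibble::tibble(species = c("barley", "wheat"),
                        gene_id = c("hv9", "ta7"))
  flags <- label_lti(sets, lti)
  expect_equal(flags$is_lti[flags$anchor_id == "a1"], TRUE)
  # wheat-only evidence does not count
  expect_equal(flags$is_lti[flags$anchor_id == "a2"], FALSE)
  expect_equal(flags$is_lti[flags$anchor_id == "a3"], FALSE)
  # empty label table: everything FALSE
  none <- label_lti(sets, lti[0, ])
  expect_false(any(none$is_lti))
})

test_that("RBH on clean synthetic data recovers the true ortholog sets", {
  topo <- species_topology()
  cfg <- small_cfg(n_genes = 12, n_codons = 60, seed = 8,
                   contaminant_rate = 0)
  ds <- generate_dataset(topo, cfg)
  prep <- prep_orthologs(ds)
  # membership is correct when every member comes from the anchor's gene
  total <- correct <- 0
  rec_gene <- function(x) sub("^[a-z]+\\.", "", x)
  for (i in seq_len(nrow(prep$sets))) {
    total <- total + 1
    correct <- correct +
      (rec_gene(prep$sets$gene_id[i]) == rec_gene(prep$sets$anchor_id[i]))
  }
  expect_gte(correct / total, 0.99)
  # LTI labels survive the regrouping (barley/lolium dropout permitting)
  merged <- dplyr::inner_join(prep$labels, ds$labels, by = "gene_id",
                              suffix = c("_rbh", "_truth"))
  bad <- sum(merged$is_lti_rbh & !merged$is_lti_truth)
  expect_equal(bad, 0L)
})
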