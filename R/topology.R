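#' Grass species topology with clade annotations
#'
#' Builds the fixed eight-taxon species tree used throughout the package:
#' two PACMAD outgroups (maize, sorghum), rice, *Brachypodium distachyon*,
#' and four core Pooideae species (wheat and barley in Hordeeae, *Lolium
#' perenne* and *Festuca pratensis* in Poeae). Two internal branches carry
#' names because they are the candidate foreground branches for the
#' branch-site selection tests:
#'
#' * `BP_ancestral` — the branch subtending *Brachypodium* plus the core
#'   Pooideae, i.e. the Pooideae stem after the split from rice;
#' * `CP_stem` — the branch subtending the four core Pooideae species,
#'   after the *Brachypodium* divergence.
#'
#' @param branch_lengths Optional named numeric vector of branch lengths in
#'   expected substitutions per codon, named by the child clade/tip of each
#'   branch (see `default_branch_lengths()`); defaults to values loosely
#'   consistent with published median grass divergences.
#'
#' @return An object of class `species_topology`: a list with elements
#'   `tree` (rooted `phylo`), `taxa`, `clade_map` (tibble of species and
#'   clade), and `foreground` (named list of taxon sets defining the two
#'   foreground branches).
#' @examples
#' topo <- species_topology()
#' topo$clade_map
#' @export
species_topology <- function(branch_lengths = default_branch_lengths()) {
  bl <- branch_lengths
  newick <- sprintf(
    paste0("((sorghum:%g,maize:%g):%g,(rice:%g,(brachypodium:%g,",
           "((wheat:%g,barley:%g):%g,(lolium:%g,festuca:%g):%g):%g):%g):%g);"),
    bl[["sorghum"]], bl[["maize"]], bl[["outgroup_clade"]],
    bl[["rice"]], bl[["brachypodium"]],
    bl[["wheat"]], bl[["barley"]], bl[["hordeeae"]],
    bl[["lolium"]], bl[["festuca"]], bl[["poeae"]],
    bl[["CP_stem"]], bl[["BP_ancestral"]], bl[["bep_clade"]])
  tree <- ape::read.tree(text = newick)
  clade_map <- tibble::tibble(
    species = c("maize", "sorghum", "rice", "brachypodium",
                "wheat", "barley", "lolium", "festuca"),
    clade = c("outgroup", "outgroup", "rice", "Bd",
              "Hordeeae", "Hordeeae", "Poeae", "Poeae"))
  structure(
    list(tree = tree,
         taxa = clade_map$species,
         clade_map = clade_map,
         foreground = list(
           BP_ancestral = c("brachypodium", "wheat", "barley",
                            "lolium", "festuca"),
           CP_stem = c("wheat", "barley", "lolium", "festuca"))),
    class = "species_topology")
}

#' Default branch lengths for the grass species tree
#'
#' Branch lengths in expected substitutions per codon, chosen so that
#' tip-to-outgroup path lengths fall in the range of published median grass
#' divergences (roughly 0.2--0.26 nucleotide substitutions per site). These
#' are simulation defaults of this package, not estimates from any
#' particular data set.
#'
#' @return Named numeric vector.
#' @export
default_branch_lengths <- function() {
  c(sorghum = 0.12, maize = 0.12, outgroup_clade = 0.10,
    rice = 0.30, brachypodium = 0.20,
    wheat = 0.12, barley = 0.12, hordeeae = 0.04,
    lolium = 0.12, festuca = 0.12, poeae = 0.04,
    CP_stem = 0.06, BP_ancestral = 0.10, bep_clade = 0.10)
}

#' @export
print.species_topology <- function(x, ...) {
  cat("Grass species topology (", length(x$taxa), " taxa)\n", sep = "")
  cat("Foreground branches: BP_ancestral, CP_stem\n")
  print(x$tree)
  invisible(x)
}

#' Outgroup species of a topology
#'
#' @param topology A `species_topology`.
#' @return Character vector of outgroup species names.
#' @export
outgroup_species <- function(topology = species_topology()) {
  topology$clade_map$species[topology$clade_map$clade == "outgroup"]
}

#' Locate a foreground branch in a gene tree
#'
#' Finds the edge of `tree` whose bipartition separates the taxa of the
#' named foreground clade (restricted to the taxa present) from the rest.
#' The branch is considered identifiable only when the surviving clade
#' members form a proper internal bipartition and, for `BP_ancestral`
#' (`CP_stem`), *Brachypodium* (at least two core Pooideae species plus
#' *Brachypodium*) survive so the branch is distinguishable from its
#' neighbours.
#'
#' @param tree A `phylo` or `gene_tree`.
#' @param foreground `"BP_ancestral"` or `"CP_stem"`.
#' @param topology A `species_topology`.
#' @return Postorder edge index, or `NA_integer_` when the branch is not
#'   identifiable in this gene tree.
#' @export
foreground_edge <- function(tree, foreground = c("BP_ancestral", "CP_stem"),
                            topology = species_topology()) {
  foreground <- match.arg(foreground)
  phy <- if (inherits(tree, "gene_tree")) tree$tree else tree
  present <- phy$tip.label
  clade <- intersect(topology$foreground[[foreground]], present)
  cp <- intersect(topology$foreground$CP_stem, present)
  has_bd <- "brachypodium" %in% present
  identifiable <- switch(foreground,
    BP_ancestral = has_bd && length(cp) >= 1L,
    CP_stem = has_bd && length(cp) >= 2L)
  if (!identifiable || length(clade) < 2L ||
      length(clade) >= length(present) - 1L)
    return(NA_integer_)
  find_clade_edge(phy, clade)
}
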