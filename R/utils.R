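# Shared low-level helpers: alignment coding, site-pattern compression and
# tree bookkeeping for the C++ pruning routines.

# Coerce an alignment to a character matrix of single nucleotides with taxon
# rownames. Accepts a character matrix (1 column per base) or a named
# character vector of sequences.
as_nuc_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)))
    return(toupper(x))
  }
  stopifnot(is.character(x), !is.null(names(x)))
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

# Integer nucleotide codes (A=0,C=1,G=2,T=3; anything else -1 = missing).
nuc_codes <- function(aln) {
  aln <- as_nuc_matrix(aln)
  idx <- get("nuc_index", envir = .gs)
  m <- matrix(idx[aln], nrow(aln), ncol(aln))
  m[is.na(m)] <- -1L
  storage.mode(m) <- "integer"
  rownames(m) <- rownames(aln)
  m
}

# Integer codon codes (0-based index into sense_codons(); -1 when a codon
# contains any non-ACGT symbol or is a stop codon).
codon_codes <- function(aln) {
  aln <- as_nuc_matrix(aln)
  nc <- ncol(aln)
  if (nc %% 3L != 0L)
    stop("alignment length is not a multiple of 3", call. = FALSE)
  ncod <- nc %/% 3L
  idx <- get("codon_index", envir = .gs)
  p1 <- aln[, seq(1L, nc, by = 3L), drop = FALSE]
  p2 <- aln[, seq(2L, nc, by = 3L), drop = FALSE]
  p3 <- aln[, seq(3L, nc, by = 3L), drop = FALSE]
  cod <- matrix(paste0(p1, p2, p3), nrow(aln), ncod)
  m <- matrix(idx[cod], nrow(aln), ncod)
  m[is.na(m)] <- -1L
  storage.mode(m) <- "integer"
  rownames(m) <- rownames(aln)
  m
}

# Collapse duplicate site columns; returns unique patterns with multiplicities.
compress_patterns <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  map <- match(key, key[u])
  list(codes = codes[, u, drop = FALSE],
       weights = as.numeric(tabulate(map, sum(u))),
       map = map)
}

# Postorder edge data for a phylo object, with the code matrix rows ordered to
# match tip numbering.
tree_data <- function(phy, codes) {
  phy <- ape::reorder.phylo(phy, "postorder")
  tips <- phy$tip.label
  miss <- setdiff(tips, rownames(codes))
  if (length(miss) > 0)
    stop("alignment lacks taxa present in tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  list(edge = phy$edge,
       lens = phy$edge.length,
       nnode = length(tips) + phy$Nnode,
       ntip = length(tips),
       codes = codes[tips, , drop = FALSE],
       phy = phy)
}

# Tip labels descending from the child node of each edge (postorder phylo).
edge_tip_sets <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; ch <- phy$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(seq_len(nrow(phy$edge)), function(k) sort(sets[[phy$edge[k, 2]]]))
}

# Locate the internal or terminal edge whose bipartition isolates `taxa`
# (either side of the edge). Returns the postorder edge index, or NA.
find_clade_edge <- function(phy, taxa) {
  phy <- ape::reorder.phylo(phy, "postorder")
  all_tips <- sort(phy$tip.label)
  taxa <- sort(intersect(taxa, all_tips))
  if (length(taxa) == 0) return(NA_integer_)
  sets <- edge_tip_sets(phy)
  comp <- sort(setdiff(all_tips, taxa))
  for (k in seq_along(sets)) {
    if (identical(sets[[k]], taxa) || identical(sets[[k]], comp))
      return(k)
  }
  NA_integer_
}

logsumexp_rows <- function(m, w) {
  # log(sum_c w_c exp(m[, c])) per row
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(as.vector(exp(m - mx) %*% w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
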