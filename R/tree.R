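# Neighbor-joining consensus trees with midpoint rooting, CpG-excluded K2P
# consensus distance matrices, and a star-likeness score for intra-species
# copy phylogenies.

#' CpG-excluded K2P distance matrix between consensus sequences
#'
#' Pairwise ends-free global alignments; CpG positions of either sequence
#' are excluded so the matrix is symmetric.
#'
#' @param consensuses [seq_tbl()].
#' @param exclude_cpg exclude CpG dinucleotide positions.
#' @param scheme nucleotide scoring scheme.
#' @param band DP band half-width (0 = full matrix).
#' @return symmetric numeric matrix (substitutions/site, 0 diagonal);
#'   saturated pairs become `NA`.
#' @export
consensus_distances <- function(consensuses, exclude_cpg = TRUE,
                                scheme = dna_scheme(), band = 200L) {
  n <- nrow(consensuses)
  m <- matrix(0, n, n, dimnames = list(consensuses$id, consensuses$id))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- needleman_wunsch(consensuses$seq[i], consensuses$seq[j],
                              scheme, free_ends = TRUE, band = band)
      cc <- count_changes(aln$a_aln, aln$b_aln, exclude_cpg,
                          cpg_on = "both")
      m[i, j] <- m[j, i] <- as.numeric(k2p(cc$p, cc$q))
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}); negative
#' branch lengths are clamped to zero and flagged in
#' `attr(, "clamped_branches")`.
#'
#' @param distances symmetric distance matrix (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(distances) {
  if (!isSymmetric(unname(as.matrix(distances)), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (nrow(as.matrix(distances)) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.matrix(distances))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_branches") <- clamped
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (via \pkg{phangorn}).
#'
#' @param tree a `phylo` tree.
#' @return rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Star-likeness score of a tree
#'
#' Sum of internal branch lengths over the sum of all branch lengths: 0 for
#' a perfect star (all internal branches zero), approaching 1 when internal
#' structure dominates. Copies inserted in one burst and evolving neutrally
#' afterwards give near-star trees (low scores); staged bursts leave
#' internal structure (higher scores).
#'
#' @param tree a `phylo` tree with >= 4 leaves.
#' @return numeric in `[0, 1]`.
#' @export
star_score <- function(tree) {
  if (length(tree$tip.label) < 4) stop("need at least 4 leaves")
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2] > ntip
  total <- sum(tree$edge.length)
  if (total == 0) return(0)
  sum(tree$edge.length[internal]) / total
}

#' Sibling leaves of a tip in an unrooted tree
#'
#' Utility for topology checks: the other tips attached to the same
#' internal node as `tip` (its cherry partners, if any).
#'
#' @param tree a `phylo` tree.
#' @param tip tip label.
#' @return character vector of tip labels (possibly empty).
#' @export
tip_siblings <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("tip not in tree: ", tip)
  parent <- tree$edge[tree$edge[, 2] == i, 1]
  kids <- tree$edge[tree$edge[, 1] == parent, 2]
  kids <- setdiff(kids, i)
  tree$tip.label[kids[kids <= length(tree$tip.label)]]
}
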