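# Clock-gene ranking: root-to-tip variance (clock-likeness), bipartition
# concordance with the species tree, and total tree length -- the three
# statistics used to pick fixed-size clock-gene sets from a gene-tree
# directory.

#' Population variance of root-to-tip path lengths
#'
#' Zero for a perfectly clock-like (ultrametric-in-substitutions) tree.
#' Unrooted input is midpoint-rooted when \code{midpoint_root = TRUE},
#' otherwise rejected.
#'
#' @param tree \code{phylo} with branch lengths (substitutions/site).
#' @param midpoint_root Midpoint-root unrooted input?
#' @return Population variance (divisor n) of the tip path lengths.
#' @export
root_to_tip_variance <- function(tree, midpoint_root = TRUE) {
  if (!ape::is.rooted(tree)) {
    if (!midpoint_root) stop("unrooted tree; supply a rooted tree")
    tree <- phangorn::midpoint(tree)
  }
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  mean((d - mean(d))^2)
}

# Non-trivial bipartitions as canonical keys: each split is represented by
# the sorted tip-label set on the side not containing the reference tip.
.split_keys <- function(tree, ref_tip) {
  ntip <- ape::Ntip(tree)
  if (ntip < 4L) return(character(0))
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(side) {
    s <- labs[side]
    if (ref_tip %in% s) s <- setdiff(labs, s)
    if (length(s) < 2L || length(s) > ntip - 2L) return(NA_character_)
    paste(sort(s), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Bipartition concordance of a gene tree with a species tree
#'
#' Fraction of the species tree's non-trivial bipartitions (restricted to
#' the shared tip set) recovered in the gene tree. With
#' \code{denominator = "gene"} the gene tree's splits form the denominator
#' instead.
#'
#' @param gene_tree,species_tree \code{phylo}; gene-tree tips must be a
#'   subset of species-tree tips. Polytomies allowed in the gene tree.
#' @param denominator \code{"species"} (default) or \code{"gene"}.
#' @return Fraction in [0, 1].
#' @export
bipartition_concordance <- function(gene_tree, species_tree,
                                    denominator = c("species", "gene")) {
  denominator <- match.arg(denominator)
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4L) stop("fewer than 4 shared tips")
  gt <- ape::keep.tip(gene_tree, shared)
  st <- ape::keep.tip(species_tree, shared)
  ref <- sort(shared)[1L]
  gk <- .split_keys(ape::unroot(gt), ref)
  sk <- .split_keys(ape::unroot(st), ref)
  denom <- if (denominator == "species") sk else gk
  if (!length(denom)) return(0)
  length(intersect(gk, sk)) / length(denom)
}

#' Total tree length
#' @param tree \code{phylo}.
#' @return Sum of branch lengths; missing lengths count 0 with a warning.
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; length 0")
    return(0)
  }
  el <- tree$edge.length
  if (anyNA(el)) {
    warning("missing branch lengths treated as 0")
    el[is.na(el)] <- 0
  }
  sum(el)
}

#' Per-gene clock statistics against a species tree
#'
#' @param gene_trees Named list of \code{phylo} gene trees, or a directory
#'   of Newick files (one tree per file; file names become gene names).
#' @param species_tree Rooted species tree.
#' @param outgroup Optional tip label(s) used to root gene trees; midpoint
#'   rooting is used when absent.
#' @return data.frame: gene, concordance, rtt_variance, tree_length.
#' @export
gene_tree_stats <- function(gene_trees, species_tree, outgroup = NULL) {
  if (is.character(gene_trees) && length(gene_trees) == 1L) {
    files <- list.files(gene_trees, pattern = "\\.(nwk|tre|tree|newick)$",
                        full.names = TRUE)
    nm <- sub("\\.[^.]*$", "", basename(files))
    gene_trees <- stats::setNames(
      lapply(files, function(f) read_newick(f, allow_polytomy = TRUE)), nm)
  }
  rows <- lapply(names(gene_trees), function(g) {
    tr <- gene_trees[[g]]
    rooted <- if (!is.null(outgroup) && all(outgroup %in% tr$tip.label))
      ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    else if (ape::is.rooted(tr)) tr else phangorn::midpoint(tr)
    data.frame(gene = g,
               concordance = bipartition_concordance(tr, species_tree),
               rtt_variance = root_to_tip_variance(rooted),
               tree_length = tree_length(tr))
  })
  do.call(rbind, rows)
}

#' Rank genes and select a fixed-size clock set
#'
#' Deterministic, stable lexicographic sort: concordance descending (the
#' emphasized statistic), then root-to-tip variance ascending, then tree
#' length descending.
#'
#' @param stats data.frame from \code{gene_tree_stats}.
#' @param k Subset size (e.g. 8 or 16).
#' @param order Column order of the sort keys.
#' @return The full table sorted, with attribute \code{"selected"} = the
#'   top-k gene names; also column \code{rank}.
#' @export
rank_and_select <- function(stats, k,
                            order = c("concordance", "rtt_variance",
                                      "tree_length")) {
  if (k > nrow(stats)) stop("k exceeds the number of genes")
  signs <- c(concordance = -1, rtt_variance = 1, tree_length = -1)
  keys <- lapply(order, function(cn) signs[[cn]] * stats[[cn]])
  keys$decreasing <- FALSE
  ord <- do.call(base::order, keys)
  out <- stats[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "selected") <- out$gene[seq_len(k)]
  out
}
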