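# Rooted-tree input/output. Trees are ape "phylo" objects throughout; the
# branch-length unit is carried in attr(tree, "length_kind"):
#   "subst" -- expected substitutions per site (gene/species trees)
#   "time"  -- millions of years (chronograms; tips at age 0)

#' Read a rooted tree from Newick text or a file
#'
#' Thin validating wrapper around \code{\link[ape]{read.tree}}. The tree must
#' be rooted and (by default) fully bifurcating; polytomies arise in gene
#' trees where poorly supported branches were collapsed, and can be admitted
#' with \code{allow_polytomy = TRUE}.
#'
#' @param source Newick string, or path to a file containing one tree.
#' @param length_kind Unit of the branch lengths: \code{"subst"}
#'   (substitutions/site) or \code{"time"} (millions of years).
#' @param allow_polytomy Admit multifurcating nodes (including a basal
#'   polytomy, i.e. an effectively unrooted tree)?
#' @return An object of class \code{phylo} with a \code{length_kind}
#'   attribute. Branch lengths are taken as given.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
read_newick <- function(source, length_kind = c("subst", "time"),
                        allow_polytomy = FALSE) {
  length_kind <- match.arg(length_kind)
  text <- source
  if (length(source) == 1L && !grepl("\\(", source) || file.exists(source[1L])) {
    if (!file.exists(source[1L]))
      stop("'", source, "' is neither Newick text nor an existing file")
    text <- paste(readLines(source[1L], warn = FALSE), collapse = "")
  }
  text <- paste(text, collapse = "")
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error")
  validate_tree(tree, allow_polytomy = allow_polytomy)
  attr(tree, "length_kind") <- length_kind
  tree
}

# Cheap syntax scan so parse errors carry a character offset, which
# ape::read.tree does not report.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at character ",
         length(chars))
  if (!grepl(";", text))
    stop("Newick parse error: missing terminal ';' at character ",
         length(chars))
  invisible(TRUE)
}

#' Validate a rooted tree
#'
#' Checks the invariants assumed throughout the package: a single root,
#' unique tip labels, non-negative branch lengths, and (unless allowed)
#' strictly bifurcating internal nodes.
#'
#' @param tree A \code{phylo} object.
#' @param allow_polytomy Admit multifurcations?
#' @return The tree, invisibly; errors otherwise.
#' @export
validate_tree <- function(tree, allow_polytomy = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  tab <- tabulate(tree$edge[, 1L], nbins = ape::Ntip(tree) + tree$Nnode)
  root <- ape::Ntip(tree) + 1L
  if (!allow_polytomy) {
    bad <- which(tab > 2L)
    if (length(bad))
      stop("polytomy at node ", bad[1L],
           if (bad[1L] == root) " (basal polytomy: tree is unrooted)" else "",
           "; pass allow_polytomy = TRUE to accept")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  invisible(tree)
}

#' Node ages of a chronogram
#'
#' Ages in millions of years before present, tips at age 0. Requires a
#' time-calibrated (ultrametric) tree.
#'
#' @param tree A \code{phylo} whose branch lengths are durations (My).
#' @param tol Tip-age tolerance for the ultrametricity check.
#' @return Numeric vector of length \code{Ntip + Nnode}, indexed by ape node
#'   id (tips first); tip entries are exactly 0.
#' @export
node_ages <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  h <- max(depth[seq_len(ntip)])
  if (any(abs(depth[seq_len(ntip)] - h) > tol * max(h, 1)))
    stop("tree is not ultrametric; tip ages differ by more than tol")
  ages <- h - depth
  ages[seq_len(ntip)] <- 0
  ages
}

# Build a chronogram from a topology (phylo, lengths ignored) and a vector of
# internal node ages indexed by ape node id. Tips sit at age 0.
#' @keywords internal
.tree_with_ages <- function(tree, ages) {
  ntip <- ape::Ntip(tree)
  full <- numeric(ntip + tree$Nnode)
  full[as.integer(names(ages))] <- ages
  tree$edge.length <- full[tree$edge[, 1L]] - full[tree$edge[, 2L]]
  if (any(tree$edge.length <= 0))
    stop("parent age must exceed child age for every branch")
  attr(tree, "length_kind") <- "time"
  tree
}

#' Write a tree as Newick text
#'
#' @param tree A \code{phylo}.
#' @param file Optional path; when \code{NULL} the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 15L) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Most recent common ancestor of two tips
#'
#' Resolves a calibration row (or any tip pair) to the ape node id of the
#' MRCA, the node a fossil constraint attaches to.
#'
#' @param tree A \code{phylo}.
#' @param tip_a,tip_b Tip labels.
#' @return Integer node id.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' resolve_mrca(tr, "A", "C")  # the root
#' @export
resolve_mrca <- function(tree, tip_a, tip_b) {
  for (lab in c(tip_a, tip_b))
    if (!lab %in% tree$tip.label) stop("tip not found: ", lab)
  if (tip_a == tip_b) stop("calibration tips must differ")
  ape::getMRCA(tree, c(tip_a, tip_b))
}

## ---- annotated (FigTree-dialect) NEXUS trees --------------------------------

#' Write a node-annotated NEXUS tree
#'
#' Emits a FigTree-dialect NEXUS file in which internal nodes carry bracketed
#' comments, e.g. \code{[&age=298,hpd_lower=237,hpd_upper=349]}. This is the
#' format used for chronogram output (posterior mean age plus 95\% HPD).
#'
#' @param tree A \code{phylo}.
#' @param annotations Named list keyed by node id (as character); each element
#'   a named numeric vector of annotation values. May be empty.
#' @param file Optional output path.
#' @return The NEXUS text, invisibly when written to a file.
#' @export
write_annotated_tree <- function(tree, annotations = list(), file = NULL) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ids <- suppressWarnings(as.integer(names(annotations)))
  if (length(annotations) && (anyNA(ids) || any(ids < 1L | ids > n_nodes)))
    stop("annotation for unknown node id: ",
         paste(names(annotations)[is.na(ids) | ids < 1L | ids > n_nodes],
               collapse = ", "))
  body <- .newick_annotated(tree, annotations)
  txt <- c("#NEXUS", "begin trees;",
           paste0("  tree TREE1 = [&R] ", body), "end;")
  if (is.null(file)) return(paste(txt, collapse = "\n"))
  writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}

.fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

.newick_annotated <- function(tree, annotations) {
  ntip <- ape::Ntip(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  has_len <- !is.null(tree$edge.length)
  rec <- function(v) {
    ann <- annotations[[as.character(v)]]
    comment <- if (!is.null(ann) && length(ann))
      paste0("[&", paste0(names(ann), "=", .fmt_num(ann), collapse = ","), "]")
    else ""
    lab <- if (v <= ntip) tree$tip.label[v] else ""
    core <- if (v <= ntip) paste0(lab, comment)
            else paste0("(", paste(vapply(children[[as.character(v)]], rec, ""),
                                   collapse = ","), ")", comment)
    if (has_len && v != ntip + 1L)
      paste0(core, ":", .fmt_num(elen[v])) else core
  }
  paste0(rec(ntip + 1L), ";")
}

#' Read a node-annotated NEXUS tree written by \code{write_annotated_tree}
#'
#' @param file Path (or the NEXUS text itself).
#' @return A list with \code{tree} (phylo, \code{length_kind = "time"}) and
#'   \code{annotations} (named list keyed by node id, as written).
#' @export
read_annotated_tree <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               file.exists(file)) readLines(file, warn = FALSE)
  else unlist(strsplit(paste(file, collapse = "\n"), "\n"))
  treeline <- grep("^\\s*tree\\s+\\S+\\s*=", lines, value = TRUE)
  if (!length(treeline)) stop("no tree block found")
  newick <- sub("^\\s*tree\\s+\\S+\\s*=\\s*(\\[&R\\]\\s*)?", "",
                treeline[1L])

  # Pull out [&...] comments in reading order, then parse the stripped tree.
  # Comments are re-attached by walking the stripped Newick in the same order
  # and recording which node each comment follows.
  stripped <- gsub("\\[&[^]]*\\]", "", newick)
  tree <- ape::read.tree(text = stripped)
  attr(tree, "length_kind") <- "time"

  ann <- list()
  # map: traverse newick text; maintain a stack mirroring read.tree's node
  # numbering. Simpler: annotate by matching each comment to the tip label or
  # closing-paren clade immediately preceding it.
  pos <- gregexpr("\\[&([^]]*)\\]", newick)[[1]]
  if (pos[1L] != -1L) {
    lens <- attr(pos, "match.length")
    for (k in seq_along(pos)) {
      inner <- substr(newick, pos[k] + 2L, pos[k] + lens[k] - 2L)
      before <- substr(newick, 1L, pos[k] - 1L)
      node <- .node_before(tree, before)
      pairs <- strsplit(strsplit(inner, ",")[[1]], "=")
      vals <- vapply(pairs, function(p) as.numeric(p[2L]), 0)
      names(vals) <- vapply(pairs, `[[`, "", 1L)
      ann[[as.character(node)]] <- vals
    }
  }
  list(tree = tree, annotations = ann)
}

# Identify the node whose tip label or subtree closes immediately before a
# comment: either the text ends with a label (tip) or with ")" (the clade of
# tips seen since the matching "(").
.node_before <- function(tree, before) {
  before <- sub("^tree[^=]*=\\s*(\\[&R\\]\\s*)?", "", before)
  if (grepl("\\)$", before)) {
    # clade: find matching '(' and collect tip labels inside
    chars <- strsplit(before, "")[[1]]
    depth <- 0L
    start <- NA_integer_
    for (i in rev(seq_along(chars))) {
      if (chars[i] == ")") depth <- depth + 1L
      if (chars[i] == "(") {
        depth <- depth - 1L
        if (depth == 0L) { start <- i; break }
      }
    }
    clade <- substr(before, start, nchar(before))
    clade <- gsub("\\[&[^]]*\\]", "", clade)
    labs <- regmatches(clade, gregexpr("[A-Za-z_][A-Za-z0-9_.|-]*", clade))[[1]]
    labs <- intersect(labs, tree$tip.label)
    ape::getMRCA(tree, labs)
  } else {
    lab <- regmatches(before, regexpr("[A-Za-z_][A-Za-z0-9_.|-]*$", before))
    match(lab, tree$tip.label)
  }
}
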