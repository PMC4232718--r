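#' Read and write FASTA sequence sets
#'
#' Thin wrappers around [Biostrings::readBStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character vectors,
#' which is the representation used across the package. Names and sequences
#' round-trip byte-exactly (sequences are upper-cased when
#' `case_normalize = TRUE`, the default); gap characters `-` are preserved,
#' so aligned FASTA is supported.
#'
#' @param path File path.
#' @param case_normalize Upper-case sequences on read (default `TRUE`).
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path, case_normalize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))  # first token, FASTA convention
  if (any(duplicated(names(seqs))))
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence record in ", path)
  if (case_normalize) seqs <- toupper(seqs)
  seqs
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @return `write_fasta`: the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (any(duplicated(names(seqs)))) stop("duplicate sequence names")
  if (any(!nzchar(seqs))) stop("refusing to write empty sequence record")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write Newick trees with branch partition tags
#'
#' Trees are `ape` \code{"phylo"} objects carrying an extra integer vector
#' `tags` (one entry per edge, in `tree$edge` row order) that assigns every
#' branch to a model partition: 0 = background, 1, 2, ... = foreground /
#' clade partitions. On file, a tag is encoded as a `#k` suffix on the tip
#' or internal node label subtending the branch (e.g. `(A#1:1,B:1);` puts
#' the branch leading to A in partition 1); untagged branches are
#' partition 0.
#'
#' @param path File path (or, for `read_newick`, a Newick string when
#'   `text = TRUE`).
#' @param text Interpret `path` as Newick text rather than a file name.
#' @return `read_newick`: a tagged tree (class `phylo`, with a `tags`
#'   component and attribute `tagged = TRUE`).
#' @examples
#' tr <- read_newick("((A#1:0.1,B#1:0.1)AB#1:0.05,C:0.2)root;", text = TRUE)
#' branch_tags(tr)
#' @export
read_newick <- function(path, text = FALSE) {
  txt <- if (text) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick input")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in tree")
  ## extract "#k" suffixes from labels
  tip_tags <- rep(0L, length(tr$tip.label))
  m <- regmatches(tr$tip.label, regexpr("#[0-9]+$", tr$tip.label))
  has <- grepl("#[0-9]+$", tr$tip.label)
  tip_tags[has] <- as.integer(sub("#", "", m))
  tr$tip.label <- sub("#[0-9]+$", "", tr$tip.label)
  node_tags <- rep(0L, tr$Nnode)
  if (!is.null(tr$node.label)) {
    has_n <- grepl("#[0-9]+$", tr$node.label)
    mn <- regmatches(tr$node.label, regexpr("#[0-9]+$", tr$node.label))
    node_tags[has_n] <- as.integer(sub("#", "", mn))
    tr$node.label <- sub("#[0-9]+$", "", tr$node.label)
  }
  if (any(duplicated(tr$tip.label))) stop("duplicate tip labels")
  ## tag per edge, indexed by child node of the edge (a tag on the root
  ## label has no subtending branch and is ignored)
  all_tags <- c(tip_tags, node_tags)
  tags <- all_tags[tr$edge[, 2L]]
  tr$tags <- as.integer(tags)
  attr(tr, "tagged") <- TRUE
  tr
}

#' @param tree A tagged tree from [read_newick()] or [tag_branches()].
#' @rdname read_newick
#' @return `write_newick`: the path, invisibly (or the Newick string when
#'   `path` is `NULL`).
#' @export
write_newick <- function(tree, path = NULL) {
  tr <- tree
  tags <- branch_tags(tr)
  ntip <- length(tr$tip.label)
  child <- tr$edge[, 2L]
  for (i in seq_along(tags)) {
    if (tags[i] != 0L) {
      k <- child[i]
      if (k <= ntip) {
        tr$tip.label[k] <- paste0(tr$tip.label[k], "#", tags[i])
      } else {
        if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
        j <- k - ntip
        tr$node.label[j] <- paste0(tr$node.label[j], "#", tags[i])
      }
    }
  }
  tr$tags <- NULL
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Branch partition tags of a tree
#'
#' @param tree A `phylo` tree, possibly carrying a `tags` component.
#' @return Integer vector, one tag per edge in `tree$edge` row order
#'   (all zero if the tree carries no tags).
#' @export
branch_tags <- function(tree) {
  if (!is.null(tree$tags)) {
    stopifnot(length(tree$tags) == nrow(tree$edge))
    return(as.integer(tree$tags))
  }
  rep(0L, nrow(tree$edge))
}

#' Tag branches of a tree by clade membership
#'
#' Assigns partition `tag` to the branches of the clade spanned by `taxa`:
#' all branches whose descendant tips are wholly inside `taxa`, plus
#' (optionally) the stem branch of their most recent common ancestor.
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of tip labels defining the clade.
#' @param tag Integer partition id to assign (default 1).
#' @param include_stem Tag the stem branch of the MRCA as well (default
#'   `TRUE`).
#' @return The tree with an updated `tags` component.
#' @export
tag_branches <- function(tree, taxa, tag = 1L, include_stem = TRUE) {
  stopifnot(all(taxa %in% tree$tip.label))
  tags <- branch_tags(tree)
  ntip <- length(tree$tip.label)
  tipset <- descendant_tips(tree)
  for (i in seq_len(nrow(tree$edge))) {
    below <- tipset[[tree$edge[i, 2L]]]
    if (all(tree$tip.label[below] %in% taxa)) tags[i] <- as.integer(tag)
  }
  if (!include_stem && length(taxa) > 1L) {
    node <- ape::getMRCA(tree, taxa)
    stem <- which(tree$edge[, 2L] == node)
    if (length(stem)) tags[stem] <- 0L
  }
  tree$tags <- tags
  tree
}

## Internal: list over all nodes (1..ntip+Nnode) of tip indices below each
## node (a tip's own index for tips).
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  out <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  ## postorder over edges: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

## Internal: label for the branch subtending node `k`: tip label, node
## label when present, otherwise "node<k>".
branch_label <- function(tree, k) {
  ntip <- length(tree$tip.label)
  if (k <= ntip) return(tree$tip.label[k])
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[k - ntip]
    if (!is.na(lab) && nzchar(lab)) return(lab)
  }
  paste0("node", k)
}
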