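## Placement of shared inactivation events on the species tree under the
## Dollo (no-reversal) assumption, and per-gene summaries of
## pseudogenization timing.

#' Most recent common ancestor of a taxon set
#'
#' @param tree A `phylo` tree.
#' @param taxa Non-empty character vector of tip labels.
#' @return The node id: the tip itself for a single taxon, otherwise the
#'   MRCA node (the root when `taxa` spans all tips).
#' @export
mrca_node <- function(tree, taxa) {
  if (!length(taxa)) stop("empty taxon set")
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Map an inactivation event onto the species tree
#'
#' Places the origin(s) of a derived loss character carried by `carriers`
#' under strict Dollo parsimony (a loss arises once per origin branch and
#' never reverts): if the carriers form a clade the single origin is the
#' stem branch of their MRCA; otherwise the origins are the stem branches
#' of the maximal clades whose tips all carry the event. When exactly one
#' non-carrier tip nests inside the carrier MRCA, the alternative
#' explanation "single origin on the MRCA stem plus one reversal" is
#' recorded as a note (point stops can revert; indels essentially never
#' do).
#'
#' @param tree A `phylo` tree.
#' @param carriers Character vector of carrier tip labels (or a one-row
#'   event data.frame from [find_shared_events()], whose `carriers`
#'   column is split on commas).
#' @return An object of class `mapped_event`: list with `carriers`,
#'   `origin_nodes` (child node ids of the origin branches),
#'   `origin_branches` (their labels), `monophyletic`,
#'   `n_independent_origins`, `note`.
#' @export
map_event <- function(tree, carriers) {
  event <- NULL
  if (is.data.frame(carriers)) {
    stopifnot(nrow(carriers) == 1L)
    event <- carriers
    carriers <- strsplit(carriers$carriers, ",", fixed = TRUE)[[1L]]
  }
  bad <- setdiff(carriers, tree$tip.label)
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  if (!length(carriers)) stop("empty carrier set")
  tipsets <- descendant_tips(tree)
  ntip <- length(tree$tip.label)
  carrier_id <- match(carriers, tree$tip.label)

  is_carrier_clade <- function(node)
    all(tipsets[[node]] %in% carrier_id)

  mrca <- mrca_node(tree, carriers)
  mono <- length(tipsets[[mrca]]) == length(carrier_id)

  if (mono) {
    origins <- mrca
  } else {
    ## maximal carrier-only clades: carrier-pure nodes whose parent is not
    parent_of <- integer(ntip + tree$Nnode)
    parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
    pure <- which(vapply(seq_len(ntip + tree$Nnode), is_carrier_clade, TRUE))
    origins <- pure[!(parent_of[pure] %in% pure) ]
    origins <- origins[vapply(origins, function(n)
      length(tipsets[[n]]) > 0L, TRUE)]
  }
  note <- ""
  if (!mono) {
    inside <- tipsets[[mrca]]
    non_carriers <- setdiff(inside, carrier_id)
    if (length(non_carriers) == 1L)
      note <- paste0("alternative: single origin on stem ",
                     branch_label(tree, mrca), " with one reversal in ",
                     tree$tip.label[non_carriers])
  }
  structure(list(
    event = event, carriers = sort(carriers),
    origin_nodes = origins,
    origin_branches = vapply(origins, function(n) branch_label(tree, n), ""),
    monophyletic = mono, n_independent_origins = length(origins),
    note = note), class = "mapped_event")
}

#' @export
print.mapped_event <- function(x, ...) {
  cat("Mapped event: ", length(x$carriers), " carriers, ",
      x$n_independent_origins, " origin(s) [",
      paste(x$origin_branches, collapse = ", "), "]",
      if (x$monophyletic) " (monophyletic)" else "", "\n", sep = "")
  if (nzchar(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Map all shared events of a gene and write a mapping table
#'
#' @param tree A `phylo` tree.
#' @param events Event data.frame from [find_shared_events()].
#' @return A data.frame: one row per event x origin branch with columns
#'   gene, kind, ref_nt_start, length_nt, origin_branch, monophyletic,
#'   n_independent_origins, note.
#' @export
map_events <- function(tree, events) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    me <- map_event(tree, events[i, , drop = FALSE])
    data.frame(gene = events$gene[i], kind = events$kind[i],
               ref_nt_start = events$ref_nt_start[i],
               length_nt = events$length_nt[i],
               stop_codon = events$stop_codon[i],
               origin_branch = paste(me$origin_branches, collapse = ";"),
               monophyletic = me$monophyletic,
               n_independent_origins = me$n_independent_origins,
               note = me$note, carriers = paste(me$carriers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene summary of pseudogenization timing across lineages
#'
#' For each gene and each named lineage (a set of tips, e.g. the cetacean
#' clade vs. the hippopotamid lineage), reports the origin branch closest
#' to the root among the gene's mapped events involving that lineage, and
#' flags lineage pairs with no shared event as independent
#' pseudogenizations.
#'
#' @param tree A `phylo` tree.
#' @param mapped A data.frame from [map_events()] (may cover several
#'   genes).
#' @param lineages Named list of tip-label vectors.
#' @return A list with `per_lineage` (gene, lineage, earliest origin
#'   branch, n events) and `independence` (gene, lineage pair,
#'   independent flag).
#' @export
gene_loss_summary <- function(tree, mapped, lineages) {
  if (!nrow(mapped)) stop("no mapped events")
  stopifnot(length(lineages) >= 1L, !is.null(names(lineages)))
  depth <- node_depths(tree)
  per <- list(); indep <- list()
  for (g in unique(mapped$gene)) {
    mg <- mapped[mapped$gene == g, , drop = FALSE]
    ev_carriers <- lapply(strsplit(mg$carriers, ",", fixed = TRUE), identity)
    for (ln in names(lineages)) {
      touches <- vapply(ev_carriers, function(cs)
        any(cs %in% lineages[[ln]]), TRUE)
      if (!any(touches)) next
      ## earliest = minimum root distance among the origin branches of the
      ## lineage's events (origins restricted to branches within/at the
      ## lineage: carriers intersected with the lineage, remapped)
      cand <- lapply(which(touches), function(i) {
        cs <- intersect(ev_carriers[[i]], lineages[[ln]])
        me <- map_event(tree, cs)
        me$origin_nodes
      })
      nodes <- unlist(cand)
      best <- nodes[which.min(depth[nodes])]
      per[[length(per) + 1L]] <- data.frame(
        gene = g, lineage = ln,
        earliest_origin = branch_label(tree, best),
        n_events = sum(touches), stringsAsFactors = FALSE)
    }
    lns <- names(lineages)
    if (length(lns) >= 2L) {
      for (a in seq_along(lns)) for (b in seq_along(lns)) {
        if (b <= a) next
        ta <- vapply(ev_carriers, function(cs) any(cs %in% lineages[[lns[a]]]), TRUE)
        tb <- vapply(ev_carriers, function(cs) any(cs %in% lineages[[lns[b]]]), TRUE)
        if (!any(ta) || !any(tb)) next
        shared <- any(ta & tb)
        indep[[length(indep) + 1L]] <- data.frame(
          gene = g, lineage_a = lns[a], lineage_b = lns[b],
          independent = !shared, stringsAsFactors = FALSE)
      }
    }
  }
  list(per_lineage = if (length(per)) do.call(rbind, per) else NULL,
       independence = if (length(indep)) do.call(rbind, indep) else NULL)
}

## number of edges from the root to each node
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  depth <- integer(n)
  ed <- postorder_edges(tree)$edge
  for (e in rev(seq_len(nrow(ed))))  # preorder
    depth[ed[e, 2L]] <- depth[ed[e, 1L]] + 1L
  depth
}
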