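# Parsimony duplication-loss reconciliation of a rooted binary gene tree
# against a rooted binary species tree by LCA mapping. Each gene node maps
# to the lowest common ancestor (in the species tree) of its descendant
# species; an internal gene node is a duplication iff it maps to the same
# species node as one of its children; losses are counted per gene-tree
# edge from the species-path length. Branch lengths are ignored.

# per-node children lists and a root check for an ape phylo object
tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (r in seq_len(nrow(tree$edge)))
    ch[[tree$edge[r, 1]]] <- c(ch[[tree$edge[r, 1]]], tree$edge[r, 2])
  ch
}

assert_binary <- function(tree, what) {
  ch <- tree_children(tree)
  n_child <- lengths(ch)
  internal <- (ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)
  if (any(n_child[internal] != 2L))
    stop(what, " is not binary (node with ",
         paste(unique(n_child[internal][n_child[internal] != 2L]),
               collapse = "/"), " children)")
  invisible(ch)
}

# depth (edges from root) and ancestor chains for every species-tree node
species_index <- function(species_tree) {
  ch <- tree_children(species_tree)
  ntip <- ape::Ntip(species_tree)
  root <- ntip + 1L
  n_nodes <- ntip + species_tree$Nnode
  parent <- integer(n_nodes)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  parent[root] <- 0L
  depth <- integer(n_nodes)
  # breadth-first from the root
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (c in ch[[v]]) {
      depth[c] <- depth[v] + 1L
      queue <- c(queue, c)
    }
  }
  list(parent = parent, depth = depth, root = root, ntip = ntip)
}

species_lca <- function(a, b, idx) {
  while (a != b) {
    if (idx$depth[a] >= idx$depth[b]) a <- idx$parent[a]
    else b <- idx$parent[b]
  }
  a
}

# default leaf map: species = leaf label prefix up to the first underscore
default_leaf_map <- function(labels) {
  sp <- sub("_.*$", "", labels)
  stats::setNames(sp, labels)
}

#' LCA mapping of a gene tree onto a species tree
#'
#' @param gene_tree rooted binary `phylo` gene tree.
#' @param species_tree rooted binary `phylo` species tree with unique leaf
#'   labels.
#' @param leaf_map named character vector mapping gene leaf labels to
#'   species leaf labels; by default the species is the gene-leaf label
#'   prefix up to the first underscore.
#' @return integer vector: for every gene-tree node (ape numbering), the
#'   species-tree node it maps to.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_map = NULL) {
  assert_binary(gene_tree, "gene tree")
  assert_binary(species_tree, "species tree")
  if (anyDuplicated(species_tree$tip.label))
    stop("duplicate leaf labels in the species tree")
  if (is.null(leaf_map)) leaf_map <- default_leaf_map(gene_tree$tip.label)
  missing_leaves <- setdiff(gene_tree$tip.label, names(leaf_map))
  if (length(missing_leaves))
    stop("unmapped gene leaves: ", paste(missing_leaves, collapse = ", "))
  sp_of <- leaf_map[gene_tree$tip.label]
  bad <- !sp_of %in% species_tree$tip.label
  if (any(bad))
    stop("species absent from species tree: ",
         paste(unique(sp_of[bad]), collapse = ", "))
  idx <- species_index(species_tree)
  sp_tip_id <- stats::setNames(seq_len(ape::Ntip(species_tree)),
                               species_tree$tip.label)
  ntip_g <- ape::Ntip(gene_tree)
  M <- integer(ntip_g + gene_tree$Nnode)
  M[seq_len(ntip_g)] <- sp_tip_id[sp_of]
  edges <- ape::reorder.phylo(gene_tree, "postorder")$edge
  ch <- tree_children(gene_tree)
  root <- setdiff(edges[, 1], edges[, 2])
  for (v in c(edges[, 2], root)) {       # postorder: children before parents
    if (v <= ntip_g) next
    kids <- ch[[v]]
    M[v] <- species_lca(M[kids[1]], M[kids[2]], idx)
  }
  M
}

#' Duplication-loss reconciliation
#'
#' Events: an internal gene node is a `duplication` iff its LCA mapping
#' equals that of at least one child, else a `speciation`. Losses on the
#' gene-tree edge from `u` to `v`, where `d` is the number of species-tree
#' edges between the mappings of `u` and `v`: `max(d - 1, 0)` when `u` is a
#' speciation and `d` when `u` is a duplication; totals are summed over all
#' edges.
#'
#' @inheritParams lca_map
#' @return object of class `tdna_reconciliation`: `mapping` (gene node ->
#'   species node), `events` (per internal gene node), `duplications`,
#'   `losses`, and `edge_losses` (per-edge breakdown).
#' @export
reconcile_dl <- function(gene_tree, species_tree, leaf_map = NULL) {
  M <- lca_map(gene_tree, species_tree, leaf_map)
  idx <- species_index(species_tree)
  ch <- tree_children(gene_tree)
  ntip <- ape::Ntip(gene_tree)
  internal <- (ntip + 1L):(ntip + gene_tree$Nnode)
  events <- stats::setNames(rep("speciation", length(internal)), internal)
  for (v in internal)
    if (any(M[ch[[v]]] == M[v])) events[as.character(v)] <- "duplication"
  edge_losses <- data.frame(parent = gene_tree$edge[, 1],
                            child = gene_tree$edge[, 2],
                            losses = 0L)
  for (r in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[r, 1]; v <- gene_tree$edge[r, 2]
    d <- idx$depth[M[v]] - idx$depth[M[u]]
    edge_losses$losses[r] <- if (events[as.character(u)] == "duplication") d
                             else max(d - 1L, 0L)
  }
  structure(list(mapping = M, events = events,
                 duplications = sum(events == "duplication"),
                 losses = sum(edge_losses$losses),
                 edge_losses = edge_losses,
                 gene_tree = gene_tree, species_tree = species_tree),
            class = "tdna_reconciliation")
}

#' @export
print.tdna_reconciliation <- function(x, ...) {
  cat("<tdna_reconciliation> ", x$duplications, " duplication(s), ",
      x$losses, " loss(es) over ", ape::Ntip(x$gene_tree),
      " gene leaves / ", ape::Ntip(x$species_tree), " species\n", sep = "")
  invisible(x)
}
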