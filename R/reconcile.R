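# --- small rooted-tree helpers on ape::phylo -------------------------------

tree_parents <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

tree_depths <- function(tree) {
  parent <- tree_parents(tree)
  n_all <- length(parent)
  depth <- rep(NA_integer_, n_all)
  root <- which(is.na(parent))
  depth[root] <- 0L
  # repeated sweeps are fine for the tree sizes used here
  repeat {
    todo <- which(is.na(depth) & !is.na(depth[parent]))
    if (length(todo) == 0) break
    depth[todo] <- depth[parent[todo]] + 1L
  }
  depth
}

node_name <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  lab <- tree$node.label
  if (!is.null(lab) && !is.na(lab[node - nt]) && nzchar(lab[node - nt])) {
    lab[node - nt]
  } else {
    paste0("node_", node)
  }
}

lca_fun <- function(tree) {
  parent <- tree_parents(tree)
  depth <- tree_depths(tree)
  function(a, b) {
    while (a != b) {
      if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
    }
    a
  }
}

#' Root a gene tree for reconciliation
#'
#' Midpoint rooting by default (via [phangorn::midpoint()]); pass an
#' `outgroup` tip label to root on it instead.
#'
#' @param tree An [ape::phylo] gene tree.
#' @param outgroup Optional tip label.
#' @return A rooted [ape::phylo].
#' @export
root_gene_tree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) {
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  }
  if (ape::is.rooted(tree) && ape::is.binary(tree)) return(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  phangorn::midpoint(tree)
}

#' Reconcile a gene tree against a species tree
#'
#' Standard duplication-loss parsimony by LCA mapping: each gene-tree
#' node maps to the LCA of its children's mappings; a node is a
#' duplication iff it maps to the same species node as one of its
#' children. Losses are counted per gene-tree edge as
#' `depth(M(child)) - depth(M(node)) - 1 + is_duplication(node)` and
#' attributed to the species branches skipped along the way. Ancestral
#' copy numbers count, at every species node, the gene lineages whose
#' mapping passes through it plus the duplications mapped to it.
#'
#' @param gene_tree Rooted binary [ape::phylo]; see [root_gene_tree()].
#' @param species_tree Rooted [ape::phylo] whose internal nodes may carry
#'   labels (e.g. V, E, T, A, G, Eu, R).
#' @param leaf_map Named character vector mapping gene tip labels to
#'   species tip labels.
#' @return Object of class `pf_recon`: list with `n_duplications`,
#'   `n_losses`, `duplications` (tibble `gene_node`, `species_node`),
#'   `losses` (tibble `species_node`, `n`), `counts` (tibble
#'   `species_node`, `count` — ancestral copy number), `mapping`, and the
#'   input trees.
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map) {
  if (!ape::is.rooted(gene_tree)) abort("gene tree must be rooted")
  if (!ape::is.rooted(species_tree)) abort("species tree must be rooted")
  gt <- gene_tree; st <- species_tree
  ng_tip <- length(gt$tip.label)
  ns_tip <- length(st$tip.label)
  unmapped <- setdiff(gt$tip.label, names(leaf_map))
  if (length(unmapped) > 0) {
    abort(paste0("unmapped gene leaves: ", paste(unmapped, collapse = ", ")))
  }
  missing_sp <- setdiff(unname(leaf_map[gt$tip.label]), st$tip.label)
  if (length(missing_sp) > 0) {
    abort(paste0("species not in species tree: ",
                 paste(missing_sp, collapse = ", ")))
  }
  s_parent <- tree_parents(st)
  s_depth <- tree_depths(st)
  s_lca <- lca_fun(st)
  g_parent <- tree_parents(gt)
  g_children <- split(gt$edge[, 2], gt$edge[, 1])

  n_gnode <- ng_tip + gt$Nnode
  M <- rep(NA_integer_, n_gnode)
  M[seq_len(ng_tip)] <- match(unname(leaf_map[gt$tip.label]), st$tip.label)
  g_order <- order(tree_depths(gt), decreasing = TRUE)   # postorder-ish
  for (g in g_order) {
    if (!is.na(M[g])) next
    ch <- g_children[[as.character(g)]]
    m <- M[ch[1]]
    for (c2 in ch[-1]) m <- s_lca(m, M[c2])
    M[g] <- m
  }

  internal <- (ng_tip + 1):n_gnode
  is_dup <- rep(FALSE, n_gnode)
  for (g in internal) {
    ch <- g_children[[as.character(g)]]
    is_dup[g] <- any(M[ch] == M[g])
  }

  # losses per gene edge, attributed to the sibling species branch at each
  # skipped speciation
  loss_at <- integer(ns_tip + st$Nnode)
  s_children <- split(st$edge[, 2], st$edge[, 1])
  for (g in internal) {
    for (c1 in g_children[[as.character(g)]]) {
      top <- M[g]; bot <- M[c1]
      # nodes strictly between bot and top, plus top itself when g is a
      # duplication and the child maps strictly below it
      x <- bot
      while (x != top) {
        p <- s_parent[x]
        if (p != top || is_dup[g]) {
          sib <- setdiff(s_children[[as.character(p)]], x)
          loss_at[sib] <- loss_at[sib] + 1L
        }
        x <- p
      }
    }
  }

  # ancestral copy numbers: lineages passing through + duplications at node
  count_at <- integer(ns_tip + st$Nnode)
  for (g in seq_len(n_gnode)) {
    p <- g_parent[g]
    top <- if (is.na(p)) M[g] else M[p]
    x <- M[g]
    if (is.na(p)) {
      count_at[x] <- count_at[x] + 1L     # root lineage enters at its mapping
    } else {
      while (x != top) {
        count_at[x] <- count_at[x] + 1L
        x <- s_parent[x]
      }
    }
  }
  for (g in internal) if (is_dup[g]) count_at[M[g]] <- count_at[M[g]] + 1L

  s_names <- vapply(seq_along(count_at), function(i) node_name(st, i), character(1))
  dup_nodes <- internal[is_dup[internal]]
  structure(list(
    n_duplications = length(dup_nodes),
    n_losses = sum(loss_at),
    duplications = tibble(gene_node = dup_nodes,
                          species_node = s_names[M[dup_nodes]]),
    losses = tibble(species_node = s_names, n = loss_at),
    counts = tibble(species_node = s_names, count = count_at),
    mapping = setNames(s_names[M], vapply(seq_len(n_gnode), function(i)
      node_name(gt, i), character(1))),
    gene_tree = gt, species_tree = st
  ), class = "pf_recon")
}

#' @export
print.pf_recon <- function(x, ...) {
  cat("<pf_recon> ", x$n_duplications, " duplication(s), ",
      x$n_losses, " loss(es)\n", sep = "")
  invisible(x)
}

#' @method tidy pf_recon
#' @export
tidy.pf_recon <- function(x, ...) {
  left_join(x$counts,
            x$losses |> rename(losses = "n"),
            by = "species_node") |>
    left_join(x$duplications |> count(.data$species_node, name = "gains"),
              by = "species_node") |>
    mutate(gains = tidyr::replace_na(.data$gains, 0L))
}

#' @method glance pf_recon
#' @export
glance.pf_recon <- function(x, ...) {
  tibble(n_duplications = x$n_duplications, n_losses = x$n_losses,
         n_gene_leaves = length(x$gene_tree$tip.label))
}

#' Sum ancestral copy numbers and per-branch events over families
#'
#' Combines reconciliations of many families over one labelled species
#' tree into total ancestral copy numbers at the named internal nodes and
#' per-branch gains (duplications mapped to the branch) and losses.
#'
#' @param recons List of `pf_recon` objects sharing a species tree.
#' @param labels Internal-node labels to report (default: all named
#'   nodes); an unknown label is an error.
#' @return Tibble `species_node`, `count`, `gains`, `losses`.
#' @export
ancestral_counts <- function(recons, labels = NULL) {
  if (length(recons) == 0) {
    if (is.null(labels)) abort("need labels when no reconciliations are given")
    return(tibble(species_node = labels, count = 0L, gains = 0L, losses = 0L))
  }
  st <- recons[[1]]$species_tree
  all_names <- recons[[1]]$counts$species_node
  if (is.null(labels)) {
    nt <- length(st$tip.label)
    labels <- all_names[(nt + 1):length(all_names)]
  }
  bad <- setdiff(labels, all_names)
  if (length(bad) > 0) {
    abort(paste0("label(s) not in species tree: ", paste(bad, collapse = ", ")))
  }
  per <- purrr::map(recons, tidy) |> bind_rows()
  per |>
    group_by(.data$species_node) |>
    summarise(count = sum(.data$count), gains = sum(.data$gains),
              losses = sum(.data$losses), .groups = "drop") |>
    filter(.data$species_node %in% labels) |>
    arrange(match(.data$species_node, labels))
}
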