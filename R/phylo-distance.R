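#' Pairwise protein distances from a multiple alignment
#'
#' Computes the p-distance (fraction of differing residues over columns
#' where neither sequence has a gap) for every pair, optionally corrected
#' for multiple hits with Kimura's formula
#' `d = -log(1 - p - p^2/5)`.
#'
#' @param aln Named character vector or tibble (`id`, `seq`) of aligned,
#'   equal-length protein sequences; `-` marks gaps.
#' @param correction `"kimura"` (default) or `"p"`.
#' @return Symmetric numeric matrix with taxon dimnames; `Inf` (with a
#'   warning) where p exceeds the Kimura domain.
#' @export
protein_distance <- function(aln, correction = c("kimura", "p")) {
  correction <- match.arg(correction)
  if (is.data.frame(aln)) aln <- setNames(aln$seq, aln$id)
  n <- length(aln)
  if (n < 2) abort("need at least two sequences")
  if (length(unique(nchar(aln))) != 1) abort("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) abort(paste0("no comparable columns between ",
                                 names(aln)[i], " and ", names(aln)[j]))
      p <- mean(mat[i, ok] != mat[j, ok])
      d <- if (correction == "p") p else {
        arg <- 1 - p - p^2 / 5
        if (arg <= 0) { saturated <- TRUE; Inf } else -log(arg)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (saturated) warn("some pairs exceed the Kimura correction domain (distance = Inf)")
  D
}

#' Neighbor-joining tree estimation
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix: at each step
#' the pair minimising `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is joined
#' (ties broken by the lowest current index pair). Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling
#' branch, so pairwise path lengths are preserved.
#'
#' @param D Symmetric numeric matrix with taxon dimnames (at least 3
#'   taxa); `NaN` forbidden.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (any(!is.finite(D))) abort("distance matrix contains non-finite entries")
  if (!isTRUE(all.equal(D, t(D)))) abort("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  nodes <- labs                       # newick fragment per active node
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3) {
    r <- rowSums(D)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- paste0("(", nodes[i], ":", fmt(li), ",",
                       nodes[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], new_frag)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    n <- n - 1
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  clamp <- pmax(c(la, lb, lc), 0)
  txt <- paste0("(", nodes[1], ":", fmt(clamp[1]), ",",
                nodes[2], ":", fmt(clamp[2]), ",",
                nodes[3], ":", fmt(clamp[3]), ");")
  ape::read.tree(text = txt)
}

# canonical split encoding: sorted tip labels of the side NOT containing
# the alphabetically first taxon
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  nt <- length(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(nt))
  out <- character()
  for (node in internal) {
    clade <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    if (length(side) >= 2 && length(side) <= nt - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate (replicate `r` is seeded with `seed + r`), and maps split
#' frequencies onto the point-estimate tree.
#'
#' @param aln Named character vector or tibble (`id`, `seq`) of aligned
#'   proteins.
#' @param n_reps Number of bootstrap replicates (`>= 1`).
#' @param seed Integer base seed.
#' @param correction Distance correction, see [protein_distance()].
#' @return List with `tree` (point estimate, `node.label` carrying
#'   percent support for internal splits) and `splits` (tibble `split`,
#'   `support`).
#' @export
nj_bootstrap <- function(aln, n_reps = 100L, seed = 1L,
                         correction = c("kimura", "p")) {
  correction <- match.arg(correction)
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (is.data.frame(aln)) aln <- setNames(aln$seq, aln$id)
  aln <- aln[order(names(aln))]        # invariance to taxon order
  point <- neighbor_joining(protein_distance(aln, correction))
  focal <- tree_splits(point)
  hits <- setNames(numeric(length(focal)), focal)
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(mat) <- names(aln)
  ncol_aln <- ncol(mat)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_aln <- setNames(apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""),
                        rownames(mat))
    rep_tree <- neighbor_joining(protein_distance(rep_aln, correction))
    rep_splits <- tree_splits(rep_tree)
    present <- focal %in% rep_splits
    hits[present] <- hits[present] + 1
  }
  support <- 100 * hits / n_reps
  # decorate the point tree: node labels for internal nodes
  nt <- length(point$tip.label)
  n_internal <- point$Nnode
  labels <- rep("", n_internal)
  tips_sorted <- sort(point$tip.label)
  ref <- tips_sorted[1]
  for (node in (nt + 1):(nt + n_internal)) {
    clade <- point$tip.label[phangorn::Descendants(point, node, "tips")[[1]]]
    side <- if (ref %in% clade) setdiff(tips_sorted, clade) else clade
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labels[node - nt] <- format(round_half_up(support[[key]], 1))
    }
  }
  point$node.label <- labels
  list(tree = point,
       splits = tibble(split = names(support), support = unname(support)))
}
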