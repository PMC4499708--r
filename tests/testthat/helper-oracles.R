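# Independent brute-force oracles used to check the implementations.
# These are written against the definitions, not against the package code.

GC <- Biostrings::GENETIC_CODE
NTS <- c("A", "C", "G", "T")
SENSE_CODONS <- names(GC)[GC != "*"]

# --- NG86 oracle: exhaustive neighbor/pathway enumeration ------------------

oracle_sites <- function(codon) {
  aa <- GC[[codon]]
  syn <- 0; non <- 0
  for (pos in 1:3) {
    for (nt in NTS) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (GC[[mut]] == "*") next
      if (GC[[mut]] == aa) syn <- syn + 1 else non <- non + 1
    }
  }
  c(s = syn / 3, n = non / 3)
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_pair_diffs <- function(ca, cb) {
  da <- strsplit(ca, "")[[1]]; db <- strsplit(cb, "")[[1]]
  pos <- which(da != db)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  count_path <- function(order, skip_stops) {
    cur <- da; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- db[p]
      aa_cur <- GC[[paste(cur, collapse = "")]]
      aa_nxt <- GC[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && skip_stops) return(NULL)
      if (aa_nxt != "*" && aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- Filter(Negate(is.null), lapply(perms_of(pos), count_path, skip_stops = TRUE))
  if (length(paths) == 0) {
    paths <- lapply(perms_of(pos), count_path, skip_stops = FALSE)
  }
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  sa <- rowSums(sapply(ca, oracle_sites))
  sb <- rowSums(sapply(cb, oracle_sites))
  S <- (sa[["s"]] + sb[["s"]]) / 2
  N <- (sa[["n"]] + sb[["n"]]) / 2
  d <- rowSums(mapply(oracle_pair_diffs, ca, cb))
  list(S = S, N = N, Sd = d[["sd"]], Nd = d[["nd"]],
       pS = d[["sd"]] / S, pN = d[["nd"]] / N)
}

# random gap-free codon sequence without stops
random_codons <- function(n, rng_seeded = TRUE) {
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

# mutate k random positions of a codon string, never creating a stop
mutate_codons <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  for (i in seq_len(k)) {
    repeat {
      p <- sample(length(v), 1)
      old <- v[p]
      v[p] <- sample(setdiff(NTS, v[p]), 1)
      cod_i <- (p - 1) %/% 3
      cod <- paste(v[(cod_i * 3 + 1):(cod_i * 3 + 3)], collapse = "")
      if (GC[[cod]] != "*") break
      v[p] <- old
    }
  }
  paste(v, collapse = "")
}

# --- duplication-loss reconciliation oracle --------------------------------

# brute-force minimum (duplications + losses) over every valid map of the
# gene tree's internal nodes to species-tree nodes
oracle_dl_min <- function(gene_tree, species_tree, leaf_map) {
  st <- species_tree; gt <- gene_tree
  ns_tip <- length(st$tip.label)
  ns_all <- ns_tip + st$Nnode
  s_parent <- rep(NA_integer_, ns_all)
  s_parent[st$edge[, 2]] <- st$edge[, 1]
  s_depth <- rep(NA_integer_, ns_all)
  s_root <- which(is.na(s_parent))
  s_depth[s_root] <- 0L
  repeat {
    todo <- which(is.na(s_depth) & !is.na(s_depth[s_parent]))
    if (!length(todo)) break
    s_depth[todo] <- s_depth[s_parent[todo]] + 1L
  }
  ancestors_of <- function(x) {       # x and everything above it
    out <- x
    while (!is.na(s_parent[x])) { x <- s_parent[x]; out <- c(out, x) }
    out
  }
  is_anc_or_eq <- function(a, b) a %in% ancestors_of(b)   # a above-or-equal b

  ng_tip <- length(gt$tip.label)
  ng_all <- ng_tip + gt$Nnode
  g_parent <- rep(NA_integer_, ng_all)
  g_parent[gt$edge[, 2]] <- gt$edge[, 1]
  g_children <- split(gt$edge[, 2], gt$edge[, 1])
  g_depth <- rep(NA_integer_, ng_all)
  g_root <- which(is.na(g_parent))
  g_depth[g_root] <- 0L
  repeat {
    todo <- which(is.na(g_depth) & !is.na(g_depth[g_parent]))
    if (!length(todo)) break
    g_depth[todo] <- g_depth[g_parent[todo]] + 1L
  }
  internal <- which(seq_len(ng_all) > ng_tip)
  internal <- internal[order(g_depth[internal], decreasing = TRUE)]

  M_leaf <- match(unname(leaf_map[gt$tip.label]), st$tip.label)

  s_lca <- function(a, b) {
    aa <- ancestors_of(a)
    bb <- ancestors_of(b)
    intersect(aa, bb)[1]        # both ordered bottom-up
  }

  cost_of <- function(M) {
    dup <- logical(ng_all)
    total <- 0
    for (g in internal) {
      ch <- g_children[[as.character(g)]]
      # a valid speciation requires M(g) to be the children's LCA with the
      # children separated into distinct subtrees (neither equal to M(g));
      # anything else forces a duplication
      dup[g] <- !(M[g] == s_lca(M[ch[1]], M[ch[2]]) &&
                    M[ch[1]] != M[g] && M[ch[2]] != M[g])
    }
    total <- sum(dup)
    for (g in internal) {
      for (c1 in g_children[[as.character(g)]]) {
        total <- total + (s_depth[M[c1]] - s_depth[M[g]] - 1 + dup[g])
      }
    }
    total
  }

  best <- Inf
  M <- rep(NA_integer_, ng_all)
  M[seq_len(ng_tip)] <- M_leaf
  recurse <- function(idx) {
    if (idx > length(internal)) {
      best <<- min(best, cost_of(M))
      return(invisible())
    }
    g <- internal[idx]
    ch <- g_children[[as.character(g)]]
    # candidates: every species node that is ancestor-or-equal of all children
    cand <- Reduce(intersect, lapply(ch, function(c1) ancestors_of(M[c1])))
    for (s in cand) {
      M[g] <<- s
      recurse(idx + 1)
    }
    M[g] <<- NA_integer_
  }
  recurse(1)
  best
}

# enumerate all rooted binary tree newicks over a label multiset
all_rooted_trees <- function(labels) {
  n <- length(labels)
  if (n == 1) return(labels)
  out <- character()
  # split: first label always in part A to avoid double counting
  rest <- labels[-1]
  for (k in 0:(n - 2)) {
    combos <- if (k == 0) list(integer()) else utils::combn(seq_along(rest), k, simplify = FALSE)
    for (cm in combos) {
      a <- c(labels[1], rest[cm])
      b <- if (k == 0) rest else rest[-cm]
      if (length(b) == 0) next
      for (ta in all_rooted_trees(a)) {
        for (tb in all_rooted_trees(b)) {
          out <- c(out, paste0("(", ta, ",", tb, ")"))
        }
      }
    }
  }
  out
}

# --- geometry oracles ------------------------------------------------------

# longest monotone subsequence with gap bounds, by trying all subsets
oracle_lis <- function(ord_a, ord_b, max_gap) {
  n <- length(ord_a)
  best <- integer()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= length(best)) next
    idx <- idx[order(ord_a[idx])]
    da <- diff(ord_a[idx]); db <- diff(ord_b[idx])
    ok <- length(idx) < 2 ||
      (all(da > 0 & da <= max_gap) &&
         ((all(db > 0 & db <= max_gap)) || (all(db < 0 & -db <= max_gap))))
    if (ok) best <- idx
  }
  best
}

# single-linkage clusters by transitive closure over pairwise adjacency
oracle_clusters <- function(ordinals, max_intervening) {
  n <- length(ordinals)
  adj <- abs(outer(ordinals, ordinals, "-")) <= max_intervening + 1
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && grp[j] != grp[i]) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}

# brute-force ALR windows: mark every qualifying window, merge by union
oracle_alr <- function(seq, window, frac) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  if (n < window) return(matrix(numeric(), ncol = 2))
  covered <- rep(FALSE, n)
  qualifying <- rep(FALSE, max(0, n - window + 1))
  for (s in seq_len(n - window + 1)) {
    w <- v[s:(s + window - 1)]
    if (mean(w %in% c("P", "A", "S", "T")) >= frac) qualifying[s] <- TRUE
  }
  # merge runs of qualifying starts closer than one window apart
  starts <- which(qualifying)
  if (!length(starts)) return(matrix(numeric(), ncol = 2))
  brk <- c(0, which(diff(starts) > window), length(starts))
  t(sapply(seq_len(length(brk) - 1), function(i) {
    run <- starts[(brk[i] + 1):brk[i + 1]]
    c(run[1] - 1, run[length(run)] + window - 1)
  }))
}

# random additive tree with strictly positive branch lengths
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.2, 2)
  tr
}
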