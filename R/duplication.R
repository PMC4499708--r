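#' Synonymous molecular-clock rates
#'
#' Default clock-like rates lambda (synonymous substitutions per site per
#' year): 1.5e-8 for *Arabidopsis* and 6.5e-9 for maize.
#'
#' @return Tibble with `species`, `lambda`.
#' @export
default_clock_rates <- function() {
  tibble(species = c("Arabidopsis thaliana", "Zea mays"),
         lambda = c(1.5e-8, 6.5e-9))
}

#' Date a duplication event from synonymous divergence
#'
#' Applies the synonymous molecular clock `T = Ks / (2 * lambda)` and
#' reports the age in million years, rounded half-up to 2 decimals.
#'
#' @param ks Synonymous substitutions per synonymous site (`>= 0`).
#' @param lambda Clock rate in synonymous substitutions/site/year.
#' @param saturated Logical; saturated estimates are returned as `NA`.
#' @return Age(s) in million years (vectorised).
#' @export
#' @examples
#' date_duplication(0.59184, 1.5e-8)  # 19.73 Myr
date_duplication <- function(ks, lambda = 1.5e-8, saturated = FALSE) {
  if (any(ks < 0, na.rm = TRUE)) abort("Ks must be nonnegative")
  if (any(lambda <= 0)) abort("lambda must be positive")
  t_myr <- ks / (2 * lambda) / 1e6
  t_myr <- round_half_up(t_myr, 2)
  t_myr[saturated | is.na(ks)] <- NA_real_
  t_myr
}

#' Classify the selection regime from a Ka/Ks ratio
#'
#' @param ratio Ka/Ks ratio (vectorised); `NA` (undefined, e.g. `Ks = 0`)
#'   yields `"unclassified"`.
#' @param tol Tolerance around 1 for the neutral call.
#' @return Character vector in
#'   `{"purifying", "positive", "neutral", "unclassified"}`.
#' @export
classify_selection <- function(ratio, tol = 1e-9) {
  dplyr::case_when(
    is.na(ratio) ~ "unclassified",
    abs(ratio - 1) <= tol ~ "neutral",
    ratio < 1 ~ "purifying",
    TRUE ~ "positive"
  )
}

#' Find tandem clusters of family genes
#'
#' Single-linkage clustering of family members along each chromosome:
#' two genes are linked when at most `max_intervening` non-family genes
#' lie between them (ordinal difference `<= max_intervening + 1`).
#' Clusters of at least two genes are reported.
#'
#' @param genes Gene-model tibble with `gene_id`, `chromosome`, `ordinal`
#'   (ordinals counted over all genes of the genome).
#' @param max_intervening Maximum intervening non-family genes (default 5).
#' @return Tibble `gene_id`, `chromosome`, `ordinal`, `cluster` (id, or
#'   `NA` for singletons).
#' @export
find_tandem_clusters <- function(genes, max_intervening = 5L) {
  out <- genes |>
    group_by(.data$chromosome) |>
    arrange(.data$ordinal, .by_group = TRUE) |>
    mutate(.new = c(TRUE, diff(.data$ordinal) > max_intervening + 1L),
           .grp = cumsum(.data$.new)) |>
    group_by(.data$chromosome, .data$.grp) |>
    mutate(.size = n()) |>
    ungroup() |>
    mutate(cluster = ifelse(.data$.size >= 2,
                            paste0(.data$chromosome, ":", .data$.grp), NA)) |>
    select("gene_id", "chromosome", "ordinal", "cluster")
  out
}

#' Chain collinear anchors into synteny blocks
#'
#' Given within-genome paralog anchors (gene pairs with chromosome and
#' gene-ordinal coordinates on both copies), finds maximal monotone
#' chains: anchors sorted by ordinal on the first chromosome whose
#' ordinals on the second chromosome are strictly monotone (increasing =
#' `same` orientation, decreasing = `inverted`), with per-step ordinal
#' gaps of at most `max_ordinal_gap` on both chromosomes. Chains are
#' extracted as longest monotone subsequences (best chain first, then the
#' remainder re-chained); chains with at least `min_anchors` anchors are
#' reported.
#'
#' @param anchors Tibble with `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `ord_a`, `ord_b`.
#' @param min_anchors Minimum anchors per reported block (default 3).
#' @param max_ordinal_gap Maximum per-step ordinal gap (default 20).
#' @return Tibble of anchors in blocks: input columns plus `block` (id),
#'   `orientation`; zero rows when nothing chains.
#' @export
chain_collinear_anchors <- function(anchors, min_anchors = 3L,
                                    max_ordinal_gap = 20L) {
  if (nrow(anchors) == 0) return(dplyr::mutate(anchors, block = character(),
                                               orientation = character()))
  blocks <- list()
  bi <- 0L
  grp <- anchors |> mutate(.key = paste0(.data$chrom_a, "~", .data$chrom_b))
  for (key in unique(grp$.key)) {
    sub <- grp |> filter(.data$.key == key) |> arrange(.data$ord_a, .data$ord_b)
    repeat {
      if (nrow(sub) < min_anchors) break
      best <- longest_monotone_chain(sub$ord_a, sub$ord_b, max_ordinal_gap)
      if (length(best$idx) < min_anchors) break
      bi <- bi + 1L
      blk <- sub[best$idx, ] |>
        mutate(block = paste0("block_", bi), orientation = best$orientation)
      blocks[[bi]] <- blk
      sub <- sub[-best$idx, ]
    }
  }
  if (length(blocks) == 0) {
    return(dplyr::mutate(anchors[0, ], block = character(),
                         orientation = character()) |> select(-dplyr::any_of(".key")))
  }
  bind_rows(blocks) |> select(-".key")
}

# longest strictly monotone subsequence in ord_b (anchors pre-sorted by
# ord_a) with per-step gaps <= max_gap on both axes; O(n^2) DP
longest_monotone_chain <- function(ord_a, ord_b, max_gap) {
  n <- length(ord_a)
  run <- function(dir) {
    len <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        step_a <- ord_a[i] - ord_a[j]
        step_b <- dir * (ord_b[i] - ord_b[j])
        if (step_a > 0 && step_a <= max_gap && step_b > 0 && step_b <= max_gap &&
            len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    k <- which.max(len)
    idx <- integer()
    while (!is.na(k)) { idx <- c(k, idx); k <- prev[k] }
    idx
  }
  up <- run(1L); down <- run(-1L)
  if (length(up) >= length(down)) {
    list(idx = up, orientation = "same")
  } else {
    list(idx = down, orientation = "inverted")
  }
}

#' Classify the duplication mechanism of a paralog pair
#'
#' Precedence: **tandem** when both genes sit in one tandem cluster;
#' else **segmental** when the pair is itself an anchor of a synteny
#' block, or both genes fall inside the gene-ordinal span of one block;
#' else **retrotransposition** for dispersed pairs (the residual
#' category), with `retro_support = TRUE` when exactly one gene of the
#' pair lacks the conserved intron; `unknown` when either gene is not
#' placed.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param genes Gene-model tibble (`gene_id`, `chromosome`, `ordinal`).
#' @param clusters Output of [find_tandem_clusters()].
#' @param blocks Output of [chain_collinear_anchors()] (may have 0 rows).
#' @param intron_evidence Optional tibble `gene_id`, `has_conserved_intron`.
#' @return `pairs` with `mechanism` and `retro_support` columns.
#' @export
classify_duplication_pair <- function(pairs, genes, clusters, blocks,
                                      intron_evidence = NULL) {
  loc <- genes |> select("gene_id", "chromosome", "ordinal")
  cl <- setNames(clusters$cluster, clusters$gene_id)
  spans <- NULL
  if (!is.null(blocks) && nrow(blocks) > 0) {
    spans <- blocks |>
      group_by(.data$block) |>
      summarise(chrom_a = .data$chrom_a[1], chrom_b = .data$chrom_b[1],
                a_lo = min(.data$ord_a), a_hi = max(.data$ord_a),
                b_lo = min(.data$ord_b), b_hi = max(.data$ord_b),
                .groups = "drop")
  }
  intr <- if (is.null(intron_evidence)) NULL else
    setNames(intron_evidence$has_conserved_intron, intron_evidence$gene_id)

  one <- function(a, b) {
    ia <- match(a, loc$gene_id); ib <- match(b, loc$gene_id)
    if (is.na(ia) || is.na(ib)) return(list(mech = "unknown", support = NA))
    ca <- unname(cl[a]); cb <- unname(cl[b])
    if (!is.na(ca) && !is.na(cb) && identical(ca, cb)) {
      return(list(mech = "tandem", support = NA))
    }
    in_block <- FALSE
    if (!is.null(spans)) {
      is_anchor <- any((blocks$gene_a == a & blocks$gene_b == b) |
                         (blocks$gene_a == b & blocks$gene_b == a))
      within <- function(chr, ord, s_chr, lo, hi) {
        chr == s_chr & ord >= lo & ord <= hi
      }
      in_span <- any(
        (within(loc$chromosome[ia], loc$ordinal[ia], spans$chrom_a, spans$a_lo, spans$a_hi) &
           within(loc$chromosome[ib], loc$ordinal[ib], spans$chrom_b, spans$b_lo, spans$b_hi)) |
          (within(loc$chromosome[ib], loc$ordinal[ib], spans$chrom_a, spans$a_lo, spans$a_hi) &
             within(loc$chromosome[ia], loc$ordinal[ia], spans$chrom_b, spans$b_lo, spans$b_hi))
      )
      in_block <- is_anchor || in_span
    }
    if (in_block) return(list(mech = "segmental", support = NA))
    support <- NA
    if (!is.null(intr)) {
      ha <- unname(intr[a]); hb <- unname(intr[b])
      support <- isTRUE(xor(isTRUE(ha), isTRUE(hb)))
    }
    list(mech = "retrotransposition", support = support)
  }
  res <- purrr::map2(pairs$gene_a, pairs$gene_b, one)
  pairs$mechanism <- purrr::map_chr(res, "mech")
  pairs$retro_support <- purrr::map_lgl(res, function(r) isTRUE(r$support))
  pairs
}

#' Lineage gain/loss from extant versus ancestral copy numbers
#'
#' @param extant,ancestral Nonnegative copy numbers (vectorised).
#' @return Tibble with `gained` (`extant - ancestral` when positive, else
#'   0) and `lost` (the reverse).
#' @export
#' @examples
#' lineage_gain(77, 7)   # poplar gained 70 since the family's origin
lineage_gain <- function(extant, ancestral) {
  if (any(extant < 0) || any(ancestral < 0)) abort("counts must be nonnegative")
  d <- extant - ancestral
  tibble(extant = extant, ancestral = ancestral,
         gained = pmax(d, 0), lost = pmax(-d, 0))
}

#' Percent decrease from an ancestral copy number
#'
#' `100 * (ancestral - extant) / ancestral`, rounded half-up to one
#' decimal.
#'
#' @param ancestral Ancestral copy number (`> 0`).
#' @param extant Extant copy number.
#' @return Percent decrease (1 decimal).
#' @export
#' @examples
#' percent_change(109, 38)  # 65.1
percent_change <- function(ancestral, extant) {
  if (any(ancestral <= 0)) abort("ancestral count must be positive")
  round_half_up(100 * (ancestral - extant) / ancestral, 1)
}

#' Assemble a dated, mechanism-classified paralog-pair table
#'
#' Joins Ka/Ks estimates, mechanism calls and clock dating into the
#' standard per-pair report (pair, Ka, Ks, Ka/Ks, mechanism, age in Myr,
#' selection call).
#'
#' @param pairs Tibble with `gene_a`, `gene_b`, `Ka`, `Ks`, `ratio`, and
#'   (optionally) `mechanism`.
#' @param lambda Clock rate passed to [date_duplication()].
#' @return Tibble of class `pf_pairs` with `t_mya` and `selection` added.
#' @export
date_pair_table <- function(pairs, lambda = 1.5e-8) {
  sat <- if ("saturated_s" %in% names(pairs)) pairs$saturated_s else FALSE
  pairs$t_mya <- date_duplication(pairs$Ks, lambda, saturated = sat)
  pairs$selection <- classify_selection(pairs$ratio)
  class(pairs) <- c("pf_pairs", setdiff(class(pairs), "pf_pairs"))
  pairs
}
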