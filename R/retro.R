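#' Locate introns relative to a protein domain
#'
#' Converts each intron of a gene model to protein coordinates (the
#' insertion point after `K` coding bases lies at residue `K/3`) and
#' reports the introns falling inside a domain span, with their phase
#' (`K mod 3`). Coordinates are walked on the spliced 5'->3' transcript,
#' so minus-strand genes are handled on the coding orientation.
#'
#' @param model One-row gene-model tibble (as from [read_gff3()]); the
#'   `exons` list-column is taken as the coding segments.
#' @param pcld_span 0-based half-open protein interval `c(start, end)` of
#'   the domain.
#' @return One-row tibble: `gene_id`, `has_conserved_intron`, `phase`
#'   (`NA` when no intron falls in the domain), `pos_res` (fractional
#'   residue position of that intron).
#' @export
map_introns_to_domain <- function(model, pcld_span) {
  cds <- arrange(model$exons[[1]], .data$start)
  lens <- cds$end - cds$start + 1L
  total <- sum(lens)
  if (total %% 3 != 0) abort("coding length is not a multiple of 3")
  prot_len <- total / 3
  if (pcld_span[2] > prot_len + 1e-9) {
    abort("domain span extends beyond the protein")
  }
  if (length(lens) < 2) {
    return(tibble(gene_id = model$gene_id, has_conserved_intron = FALSE,
                  phase = NA_integer_, pos_res = NA_real_))
  }
  upstream <- if (identical(model$strand, "-")) {
    total - cumsum(lens)[-length(lens)]
  } else {
    cumsum(lens)[-length(lens)]
  }
  pos_res <- upstream / 3
  inside <- pos_res >= pcld_span[1] & pos_res < pcld_span[2]
  if (!any(inside)) {
    return(tibble(gene_id = model$gene_id, has_conserved_intron = FALSE,
                  phase = NA_integer_, pos_res = NA_real_))
  }
  first <- which(inside)[1]
  tibble(gene_id = model$gene_id, has_conserved_intron = TRUE,
         phase = as.integer(upstream[first] %% 3L),
         pos_res = pos_res[first])
}

#' Build intron evidence for many genes
#'
#' @param models Gene-model tibble from [read_gff3()].
#' @param domain_spans Named list (or single interval recycled) of 0-based
#'   half-open protein spans per gene.
#' @return Tibble with one row per gene (see [map_introns_to_domain()]).
#' @export
intron_evidence <- function(models, domain_spans) {
  purrr::map(seq_len(nrow(models)), function(i) {
    span <- if (is.list(domain_spans)) domain_spans[[models$gene_id[i]]] else domain_spans
    map_introns_to_domain(models[i, ], span)
  }) |> bind_rows()
}

#' Infer retrogene donors from intron presence in a clade
#'
#' Retrocopies arise by reverse transcription of a spliced mRNA, so they
#' lack the conserved intron their donor carries and cluster with the
#' donor in the gene tree. This finds every maximal intronless subclade,
#' labels its stem `R` (retroposition), and identifies the donor as the
#' closest intron-bearing gene outside it (smallest number of nodes to
#' the common ancestor; ties broken by lexicographic id). Subclades whose
#' members form one tandem cluster additionally get `T` (tandem
#' expansion after retroposition). An intron-bearing gene is never
#' labelled a retrocopy.
#'
#' @param tree Rooted [ape::phylo] of the clade (>= 1 intron-bearing gene
#'   required for donor calls).
#' @param evidence Tibble `gene_id`, `has_conserved_intron` covering the
#'   tips.
#' @param clusters Optional tandem-cluster table from
#'   [find_tandem_clusters()].
#' @return Tibble of events: `event` (`"R"`), `donor`, `members`
#'   (list-column of retrocopy ids), `n_members`, `tandem_expansion`.
#'   Zero rows when there is nothing intronless; donor is `NA` (with a
#'   warning) when the clade has no intron-bearing gene.
#' @export
infer_retro_donors <- function(tree, evidence, clusters = NULL) {
  has_intron <- setNames(evidence$has_conserved_intron, evidence$gene_id)
  tips <- tree$tip.label
  if (any(!tips %in% names(has_intron))) {
    abort("evidence missing for some tips")
  }
  intronless_tip <- !has_intron[tips]
  empty <- tibble(event = character(), donor = character(),
                  members = list(), n_members = integer(),
                  tandem_expansion = logical())
  if (!any(intronless_tip)) return(empty)

  nt <- length(tips)
  n_all <- nt + tree$Nnode
  parent <- tree_parents(tree)
  desc_tips <- function(v) {
    if (v <= nt) v else phangorn::Descendants(tree, v, "tips")[[1]]
  }
  all_intronless <- vapply(seq_len(n_all), function(v) {
    all(intronless_tip[desc_tips(v)])
  }, logical(1))
  # maximal intronless subtrees: intronless node whose parent is not
  maximal <- which(all_intronless &
                     (is.na(parent) | !all_intronless[ifelse(is.na(parent), 1L, parent)]))

  if (!any(!intronless_tip)) {
    warn("no intron-bearing gene in clade: donor cannot be called")
  }
  depth <- tree_depths(tree)
  events <- purrr::map(maximal, function(u) {
    members <- tips[desc_tips(u)]
    # donor: closest intron-bearing tip outside the subtree
    donor <- NA_character_
    anc <- u
    while (!is.na(parent[anc])) {
      anc <- parent[anc]
      cand_tips <- tips[desc_tips(anc)]
      cand <- setdiff(cand_tips[has_intron[cand_tips]], members)
      if (length(cand) > 0) {
        cand_depth <- depth[match(cand, tips)]
        cand <- sort(cand[cand_depth == min(cand_depth)])
        donor <- cand[1]
        break
      }
    }
    tandem <- FALSE
    if (!is.null(clusters) && length(members) >= 2) {
      cl <- clusters$cluster[match(members, clusters$gene_id)]
      tandem <- !anyNA(cl) && length(unique(cl)) == 1
    }
    n_mem <- length(members)
    tibble(event = "R", donor = donor, members = list(members),
           n_members = n_mem, tandem_expansion = tandem)
  }) |> bind_rows()
  events
}
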