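#' Run the full simulated analysis pipeline
#'
#' Chains the whole toolkit on one simulated family: simulate ->
#' genome layout -> architecture typing -> codon-pair Ka/Ks for every
#' recoverable paralog pair -> clock dating -> mechanism classification
#' (tandem clusters + collinear blocks + intron evidence) -> gene-tree/
#' species-tree reconciliation -> retrogene donor inference, and returns
#' the summary tables. With `out_dir` set, every table is also written
#' as TSV alongside the simulated standard-format inputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param lambda Clock rate for dating (defaults to the Arabidopsis rate).
#' @return List: `family`, `layout`, `architecture` (typed calls),
#'   `type_histogram`, `pair_table` (pair, Ka, Ks, ratio, mechanism,
#'   age), `reconciliation`, `gain_loss` (per labelled ancestor), and
#'   `retro_events`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         lambda = 1.5e-8) {
  family <- simulate_family(config)
  layout <- simulate_genome_layout(family)

  calls <- layout$features |>
    annotate_alr(layout$proteins) |>
    classify_architecture()
  type_hist <- calls |> count(.data$type, name = "n")

  ks_true <- true_ks_matrix(family)
  pair_rows <- purrr::map(seq_len(nrow(layout$pairs)), function(i) {
    a <- layout$pairs$gene_a[i]; b <- layout$pairs$gene_b[i]
    cp <- simulate_codon_pair(ks_true[a, b], target_ratio = 0.3,
                              n_codons = config$n_codons,
                              seed = config$seed + 31L * i)
    ng86_pair(cp$seq_a, cp$seq_b)
  }) |> bind_rows()
  pairs <- dplyr::bind_cols(layout$pairs, pair_rows)

  clusters <- find_tandem_clusters(layout$genes)
  blocks <- chain_collinear_anchors(layout$anchors)
  pairs <- classify_duplication_pair(pairs, layout$genes, clusters, blocks,
                                     intron_evidence = layout$intron)
  pairs <- date_pair_table(pairs, lambda = lambda)

  leaf_map <- setNames(family$genes$species, family$genes$gene_id)
  recon <- reconcile(root_gene_tree(family$gene_tree),
                     family$config$species_tree, leaf_map)
  gain_loss <- ancestral_counts(list(recon),
                                labels = c("V", "E", "T", "A", "G", "Eu", "R"))

  retro <- infer_retro_donors(
    root_gene_tree(family$gene_tree),
    family$genes |> select("gene_id", "has_conserved_intron") |>
      rename(gene_id = "gene_id"),
    clusters = NULL)

  out <- list(family = family, layout = layout, architecture = calls,
              type_histogram = type_hist, pair_table = pairs,
              reconciliation = recon, gain_loss = gain_loss,
              retro_events = retro)
  if (!is.null(out_dir)) {
    write_simulated_run(family, layout, out_dir)
    readr::write_tsv(type_hist, file.path(out_dir, "type_histogram.tsv"))
    readr::write_tsv(pairs |> select(-dplyr::any_of(c("pcld_spans"))),
                     file.path(out_dir, "pair_table.tsv"))
    readr::write_tsv(gain_loss, file.path(out_dir, "gain_loss.tsv"))
  }
  out
}

#' @method tidy pf_family
#' @export
tidy.pf_family <- function(x, ...) x$events

#' @method glance pf_family
#' @export
glance.pf_family <- function(x, ...) {
  tibble(n_genes = nrow(x$genes), n_duplications = nrow(x$events),
         n_losses = nrow(x$losses),
         n_species = length(unique(x$genes$species)),
         attempts = x$attempts %||% 1L)
}

#' @method glance pf_pairs
#' @export
glance.pf_pairs <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_tandem = sum(x$mechanism == "tandem", na.rm = TRUE),
         n_segmental = sum(x$mechanism == "segmental", na.rm = TRUE),
         n_retro = sum(x$mechanism == "retrotransposition", na.rm = TRUE),
         n_positive = sum(x$selection == "positive", na.rm = TRUE),
         median_t_mya = stats::median(x$t_mya, na.rm = TRUE))
}
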