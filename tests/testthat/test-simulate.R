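test_that("family simulation is deterministic and internally consistent", {
  cfg <- sim_config(seed = 5)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(sim_config(seed = 5))
  expect_identical(ape::write.tree(f1$gene_tree), ape::write.tree(f2$gene_tree))
  expect_identical(f1$events, f2$events)
  expect_identical(f1$genes, f2$genes)
  # every extant gene appears exactly once as a tree tip
  expect_setequal(f1$gene_tree$tip.label, f1$genes$gene_id)
  # retro children are intronless; other children inherit the intron
  intron <- setNames(f1$genes$has_conserved_intron, f1$genes$lineage)
  for (i in seq_len(nrow(f1$events))) {
    ev <- f1$events[i, ]
    child <- ev$child_lineage
    if (child %in% names(intron)) {
      if (ev$mechanism == "retrotransposition") {
        expect_false(intron[[child]])
      }
    }
  }
})

test_that("loss-free simulation yields exactly the recorded duplications", {
  cfg <- sim_config(seed = 6, birth = 0.3, loss = 0)
  fam <- simulate_family(cfg)
  expect_equal(fam$gene_tree$Nnode, length(fam$gene_tree$tip.label) - 1)
  expect_equal(nrow(fam$losses), 0)
  # tips = speciation copies; duplication count matches the event list
  r <- reconcile(root_gene_tree(fam$gene_tree), cfg$species_tree,
                 setNames(fam$genes$species, fam$genes$gene_id))
  expect_equal(r$n_duplications, nrow(fam$events))
})

test_that("true pairwise Ks scales with divergence time", {
  cfg <- sim_config(seed = 8)
  fam <- simulate_family(cfg)
  ks <- true_ks_matrix(fam)
  expect_true(isSymmetric(ks))
  expect_true(all(diag(ks) == 0))
  coph <- ape::cophenetic.phylo(fam$gene_tree)
  expect_equal(ks, coph * cfg$ks_rate)
})

test_that("codon pairs carry exact event bookkeeping and never stops", {
  cp0 <- simulate_codon_pair(0, n_codons = 50, seed = 1)
  expect_identical(cp0$seq_a, cp0$seq_b)
  expect_equal(cp0$true_syn_events, 0)
  for (seed in 1:10) {
    cp <- simulate_codon_pair(0.3, 0.3, 120, seed = seed)
    for (s in c(cp$seq_a, cp$seq_b)) {
      cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
    }
    # realized synonymous differences: third-position mismatch count can be
    # below the event count only through multiple hits, never above
    a3 <- substring(cp$seq_a, seq(3, nchar(cp$seq_a), 3), seq(3, nchar(cp$seq_a), 3))
    b3 <- substring(cp$seq_b, seq(3, nchar(cp$seq_b), 3), seq(3, nchar(cp$seq_b), 3))
    expect_lte(sum(a3 != b3), cp$true_syn_events)
    expect_equal(cp$true_ks, cp$true_syn_events / cp$n_codons)
  }
  expect_error(simulate_codon_pair(0.5, n_codons = 5), "too short")
  same <- simulate_codon_pair(0.4, 0.3, 90, seed = 3)
  again <- simulate_codon_pair(0.4, 0.3, 90, seed = 3)
  expect_identical(same, again)
})

test_that("genome layouts realize each mechanism's signature", {
  fam <- simulate_family(sim_config(seed = 9))
  lay <- simulate_genome_layout(fam)
  loc <- setNames(split(lay$genes[, c("chromosome", "ordinal")],
                        seq_len(nrow(lay$genes))), lay$genes$gene_id)
  for (i in seq_len(nrow(lay$pairs))) {
    p <- lay$pairs[i, ]
    a <- lay$genes[lay$genes$gene_id == p$gene_a, ]
    b <- lay$genes[lay$genes$gene_id == p$gene_b, ]
    if (p$mechanism_true == "tandem") {
      expect_equal(a$chromosome, b$chromosome)
      expect_lte(abs(a$ordinal - b$ordinal), 6)
    } else {
      expect_false(a$chromosome == b$chromosome)
    }
    if (p$mechanism_true == "retrotransposition") {
      expect_equal(b$n_exons, 1L)   # retrogene: single exon, no introns
      expect_equal(b$n_introns, 0L)
    }
  }
  # intron truth is consistent with the emitted gene structures
  for (i in seq_len(nrow(lay$genes))) {
    g <- lay$genes[i, ]
    truth <- lay$intron$has_conserved_intron[lay$intron$gene_id == g$gene_id]
    expect_equal(g$n_introns > 0, truth)
  }
})

test_that("emitted files round-trip through the readers unchanged", {
  fam <- simulate_family(sim_config(seed = 10))
  lay <- simulate_genome_layout(fam)
  dir <- withr::local_tempdir()
  write_simulated_run(fam, lay, dir)
  gm <- read_gff3(file.path(dir, "genes.gff3"), species = lay$focal_species)
  expect_setequal(gm$gene_id, lay$genes$gene_id)
  idx <- match(lay$genes$gene_id, gm$gene_id)
  expect_equal(gm$chromosome[idx], lay$genes$chromosome)
  expect_equal(gm$n_introns[idx], lay$genes$n_introns)
  expect_equal(gm$start[idx], lay$genes$start)
  # intron phases survive the GFF3 round trip
  for (g in lay$genes$gene_id[lay$genes$n_introns > 0]) {
    expect_equal(gm$introns[[match(g, gm$gene_id)]]$phase,
                 lay$genes$introns[[match(g, lay$genes$gene_id)]]$phase)
  }
  ft <- read_feature_table(file.path(dir, "features.tsv"))
  idx2 <- match(lay$features$gene_id, ft$gene_id)
  expect_equal(ft$pcld_count[idx2], lay$features$pcld_count)
  expect_equal(ft$has_sp[idx2], lay$features$has_sp)
  pr <- read_fasta(file.path(dir, "proteins.fa"), kind = "protein")
  expect_equal(sort(pr$id), sort(lay$proteins$id))
  gt <- read_newick(file.path(dir, "gene_tree.nwk"))
  expect_setequal(gt$tip.label, fam$gene_tree$tip.label)
  # ordinal truth: GFF3 re-ranks within chromosomes but preserves order
  for (chr in unique(lay$genes$chromosome)) {
    mine <- lay$genes |> dplyr::filter(chromosome == chr) |>
      dplyr::arrange(ordinal) |> dplyr::pull(gene_id)
    theirs <- gm |> dplyr::filter(chromosome == chr) |>
      dplyr::arrange(ordinal) |> dplyr::pull(gene_id)
    expect_equal(mine, theirs)
  }
})

test_that("the full pipeline runs end to end and reports consistently", {
  out <- run_pipeline(sim_config(seed = 11), out_dir = withr::local_tempdir())
  expect_equal(sum(out$type_histogram$n), nrow(out$layout$features))
  expect_equal(out$pair_table$mechanism, out$pair_table$mechanism_true)
  expect_true(all(out$pair_table$t_mya >= 0, na.rm = TRUE))
  expect_equal(nrow(out$gain_loss), 7)
  expect_s3_class(glance(out$family), "tbl_df")
  expect_s3_class(glance(out$pair_table), "tbl_df")
  expect_s3_class(autoplot(out$pair_table), "ggplot")
  expect_s3_class(autoplot(out$reconciliation), "ggplot")
})
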