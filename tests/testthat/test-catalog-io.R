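test_that("FASTA reading preserves order, uppercases, and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g2 some description", "ATGAAA", ">g1", "atgccc"), fa)
  rec <- read_fasta(fa, kind = "cds")
  expect_equal(rec$id, c("g2", "g1"))
  expect_equal(rec$seq, c("ATGAAA", "ATGCCC"))

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "ATG", ">g1", "AAA"), dup)
  expect_error(read_fasta(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "AT#G"), bad)
  expect_error(read_fasta(bad, kind = "cds"), "non-IUPAC")
})

test_that("FASTA write/read round-trips", {
  rec <- tibble::tibble(id = c("a", "b"), kind = "protein",
                        seq = c("MKV", "MKKL"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rec, fa)
  back <- read_fasta(fa, kind = "protein")
  expect_equal(back$id, rec$id)
  expect_equal(back$seq, rec$seq)
})

make_gff <- function(genes) {
  # genes: list of list(id, chrom, strand, exons = matrix start/end)
  lines <- "##gff-version 3"
  for (g in genes) {
    ex <- g$exons
    lines <- c(lines,
      paste(g$chrom, "src", "gene", min(ex[, 1]), max(ex[, 2]), ".",
            g$strand, ".", paste0("ID=", g$id), sep = "\t"),
      paste(g$chrom, "src", "mRNA", min(ex[, 1]), max(ex[, 2]), ".",
            g$strand, ".", paste0("ID=", g$id, ".t;Parent=", g$id), sep = "\t"))
    for (i in seq_len(nrow(ex))) {
      for (tp in c("exon", "CDS")) {
        lines <- c(lines,
          paste(g$chrom, "src", tp, ex[i, 1], ex[i, 2], ".", g$strand,
                if (tp == "CDS") "0" else ".",
                paste0("Parent=", g$id, ".t"), sep = "\t"))
      }
    }
  }
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

test_that("GFF3 gene models derive introns, phases, and ordinals", {
  path <- make_gff(list(
    list(id = "single", chrom = "chr1", strand = "+",
         exons = cbind(10, 309)),
    list(id = "two_exon", chrom = "chr1", strand = "+",
         exons = cbind(c(500, 700), c(599, 899))),   # first CDS 100 bp
    list(id = "late", chrom = "chr1", strand = "+",
         exons = cbind(900, 1199))
  ))
  gm <- read_gff3(path)
  expect_equal(gm$n_introns[gm$gene_id == "single"], 0L)
  two <- gm[gm$gene_id == "two_exon", ]
  expect_equal(two$n_introns, 1L)
  expect_equal(two$introns[[1]]$phase, 1L)            # 100 mod 3
  expect_equal(two$introns[[1]]$start, 600L)
  expect_equal(two$introns[[1]]$end, 699L)
  # ordinals follow start order within the chromosome
  expect_equal(gm$ordinal[order(gm$start)], 1:3)
})

test_that("intron phase derivation agrees with a per-base codon walk", {
  set.seed(42)
  for (rep in 1:20) {
    n_ex <- sample(2:4, 1)
    lens <- sample(20:90, n_ex, replace = TRUE)
    lens[n_ex] <- lens[n_ex] + (3 - sum(lens) %% 3) %% 3   # total in frame
    starts <- cumsum(c(100, head(lens, -1) + sample(50:80, n_ex - 1, replace = TRUE)))
    exons <- tibble::tibble(start = starts, end = starts + lens - 1)
    strand <- sample(c("+", "-"), 1)
    introns <- derive_introns(exons, strand)
    # oracle: walk every coding base in transcript order, track codon pos
    ex_order <- if (strand == "-") rev(seq_len(n_ex)) else seq_len(n_ex)
    codon_pos <- 0L
    phases <- integer()
    for (k in seq_along(ex_order)) {
      codon_pos <- (codon_pos + lens[ex_order[k]]) %% 3L
      if (k < n_ex) phases <- c(phases, codon_pos)
    }
    expect_equal(introns$phase,
                 if (strand == "-") rev(phases) else phases)
  }
})

test_that("GFF3 validation catches overlap and frame errors", {
  bad_frame <- make_gff(list(
    list(id = "g", chrom = "c", strand = "+", exons = cbind(1, 100))))
  expect_error(read_gff3(bad_frame), "multiple of 3")
  overlap <- make_gff(list(
    list(id = "g", chrom = "c", strand = "+",
         exons = cbind(c(1, 50), c(60, 150)))))
  expect_error(read_gff3(overlap), "overlapping")
})

test_that("feature tables parse spans and skip unknown ids", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\thas_sp\thas_gas\tpcld_spans",
               "g1\t1\t0\t10-110",
               "g2\t0\t1\t10-110;130-230",
               "gX\t1\t1\t5-50"), tsv)
  expect_warning(ft <- read_feature_table(tsv, valid_ids = c("g1", "g2")),
                 "unknown gene_id")
  expect_equal(nrow(ft), 2)
  expect_true(ft$has_sp[ft$gene_id == "g1"])
  expect_false(ft$has_gas[ft$gene_id == "g1"])
  expect_equal(ft$pcld_count, c(1L, 2L))
  # 1-based inclusive "10-110" becomes 0-based half-open [9, 110)
  expect_equal(ft$pcld_spans[[1]]$start, 9L)
  expect_equal(ft$pcld_spans[[1]]$end, 110L)
  expect_equal(attr(ft, "skipped"), "gX")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\thas_sp\thas_gas\tpcld_spans", "g1\t1\t0\t110-10"), bad)
  expect_error(read_feature_table(bad), "exceeds end")
})

test_that("Newick round-trips preserve topology, lengths and labels", {
  nw <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", nw)
  tr <- read_newick(nw)
  expect_equal(length(tr$tip.label), 3)
  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, out)
  expect_identical(readLines(out), "((A:1,B:1):1,C:2);")

  lab <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B)E,C)V;", lab)
  tr2 <- read_newick(lab)
  expect_setequal(tr2$node.label, c("E", "V"))

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1:1,C:2);", bad)
  expect_error(read_newick(bad), "unbalanced|parse")

  # shipped species tree has the ten study taxa and the labelled ancestors
  st <- read_newick(system.file("extdata", "species_tree.nwk",
                                package = "phytofam"))
  expect_equal(length(st$tip.label), 10)
  expect_true(all(c("V", "E", "T", "A", "G", "Eu", "R") %in% st$node.label))
})

test_that("catalog construction validates per-species counts", {
  sp <- tibble::tibble(species = c("A", "B"), genome_size_mb = c(100, 200),
                       n_predicted_genes = c(1000, 2000),
                       n_family_genes = c(2, 1))
  genes <- tibble::tibble(gene_id = c("a1", "a2", "b1"),
                          species = c("A", "A", "B"))
  cat <- build_catalog(sp, genes)
  expect_s3_class(cat, "pf_catalog")
  sp_bad <- dplyr::mutate(sp, n_family_genes = c(3, 1))
  expect_error(build_catalog(sp_bad, genes), "mismatch")
})
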