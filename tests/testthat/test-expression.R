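test_that("gene-wise z-scoring matches closed form and flags constants", {
  m <- tibble::tibble(gene_id = c("g1", "g2"),
                      s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  z <- genewise_normalize(m)
  expect_equal(unlist(z[1, c("s1", "s2", "s3")], use.names = FALSE),
               c(-1, 0, 1))
  expect_false(z$constant[1])
  expect_equal(unlist(z[2, c("s1", "s2", "s3")], use.names = FALSE),
               c(0, 0, 0))
  expect_true(z$constant[2])
  # non-flagged rows have mean 0, sd 1
  expect_equal(mean(unlist(z[1, c("s1", "s2", "s3")])), 0)
  expect_equal(sd(unlist(z[1, c("s1", "s2", "s3")])), 1)
  expect_error(genewise_normalize(m[, 1:2]), "two samples")
})

test_that("z-scoring is idempotent on already-normalized rows", {
  set.seed(20)
  m <- tibble::tibble(gene_id = paste0("g", 1:5))
  vals <- matrix(rnorm(50), 5)
  m <- dplyr::bind_cols(m, tibble::as_tibble(vals, .name_repair = ~paste0("s", 1:10)))
  z1 <- genewise_normalize(m)
  z2 <- genewise_normalize(z1[, 1:11])
  expect_lt(max(abs(as.matrix(z1[, 2:11]) - as.matrix(z2[, 2:11]))), 1e-12)
})

test_that("min-max scaling is available as the alternative", {
  m <- tibble::tibble(gene_id = "g", s1 = 2, s2 = 4, s3 = 6)
  mm <- genewise_normalize(m, method = "minmax")
  expect_equal(unlist(mm[1, c("s1", "s2", "s3")], use.names = FALSE),
               c(0, 0.5, 1))
})

make_ct <- function(target_ck, target_tr, ref_ck = c(20, 20, 20),
                    ref_tr = ref_ck, cond = "salt") {
  n <- length(target_ck)
  dplyr::bind_rows(
    tibble::tibble(gene = "gA", condition = "CK", replicate = 1:n, ct = target_ck),
    tibble::tibble(gene = "gA", condition = cond, replicate = 1:n, ct = target_tr),
    tibble::tibble(gene = "ref", condition = "CK", replicate = 1:n, ct = ref_ck),
    tibble::tibble(gene = "ref", condition = cond, replicate = 1:n, ct = ref_tr))
}

test_that("ddCt reproduces hand-computed relative expression", {
  # target 24 -> 26, reference 20 -> 21: ddCt = 1, RQ = 0.5
  ct <- make_ct(c(24, 24, 24), c(26, 26, 26), ref_ck = c(20, 20, 20),
                ref_tr = c(21, 21, 21))
  rq <- ddct(ct, "ref")
  expect_equal(rq$rq[rq$condition == "salt"], 0.5)
  expect_equal(rq$ddct[rq$condition == "salt"], 1)
  # identical condition -> RQ 1
  expect_equal(rq$rq[rq$condition == "CK"], 1)
  # missing reference replicate errors
  bad <- ct[!(ct$gene == "ref" & ct$replicate == 2 & ct$condition == "salt"), ]
  expect_error(ddct(bad, "ref"), "missing reference replicate")
})

test_that("ddCt is invariant to per-replicate constant shifts", {
  set.seed(22)
  ct <- make_ct(rnorm(3, 24, 0.1), rnorm(3, 25, 0.1))
  rq0 <- ddct(ct, "ref")
  shift <- ct |>
    dplyr::group_by(replicate, condition) |>
    dplyr::mutate(ct = ct + replicate * 0.7) |>
    dplyr::ungroup()
  rq1 <- ddct(shift, "ref")
  expect_equal(rq0$rq, rq1$rq)
})

test_that("log2 RQ is additive across chained calibrators", {
  ct <- dplyr::bind_rows(
    make_ct(c(24, 24, 24), c(25, 25, 25), cond = "mid"),
    tibble::tibble(gene = "gA", condition = "high", replicate = 1:3, ct = 27),
    tibble::tibble(gene = "ref", condition = "high", replicate = 1:3, ct = 20))
  rq_ck <- ddct(ct, "ref", calibrator = "CK")
  rq_mid <- ddct(ct, "ref", calibrator = "mid")
  lg <- function(tbl, cond) log2(tbl$rq[tbl$condition == cond])
  expect_equal(lg(rq_ck, "high"), lg(rq_ck, "mid") + lg(rq_mid, "high"))
})

test_that("regulation calls respond to effect size and noise", {
  set.seed(23)
  # strong knockdown with small noise: down with at least one star almost always
  hits <- 0
  for (i in 1:50) {
    ct <- simulate_qpcr(tibble::tibble(gene = "gA", condition = "salt", rq = 0.25),
                        n_reps = 3, noise_sd = 0.15, seed = 3000 + i)
    out <- call_regulation(ddct(ct, "Actin1"))
    row <- out[out$condition == "salt", ]
    if (row$regulation == "down" && row$stars != "") hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
  # identical groups are ns
  ct0 <- make_ct(c(24, 24, 24), c(24, 24, 24))
  out0 <- call_regulation(ddct(ct0, "ref"))
  expect_equal(out0$regulation[out0$condition == "salt"], "ns")
  # strong induction is up
  ct4 <- simulate_qpcr(tibble::tibble(gene = "gA", condition = "drought", rq = 4),
                       n_reps = 3, noise_sd = 0.1, seed = 77)
  out4 <- call_regulation(ddct(ct4, "Actin1"))
  expect_equal(out4$regulation[out4$condition == "drought"], "up")
})

test_that("Ct tables round-trip through TSV", {
  ct <- simulate_qpcr(tibble::tibble(gene = "gA", condition = "salt", rq = 0.5),
                      seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ct, path)
  back <- read_ct_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ct), tolerance = 1e-12)
})
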