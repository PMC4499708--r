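#' Gene-wise normalization of an expression matrix
#'
#' Centers and scales each gene (row) across samples: z-score by default
#' (`(x - mean)/sd`), or min-max scaling to `[0, 1]`. Constant rows are
#' set to all zeros and flagged rather than producing NaN.
#'
#' @param m Tibble whose first column is `gene_id` and remaining columns
#'   are numeric sample intensities, or a numeric matrix with rownames.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return Tibble `gene_id`, sample columns (normalized), and a logical
#'   `constant` flag.
#' @export
genewise_normalize <- function(m, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (is.matrix(m)) {
    m <- tibble(gene_id = rownames(m)) |> dplyr::bind_cols(as_tibble(m))
  }
  vals <- as.matrix(m[, -1, drop = FALSE])
  if (ncol(vals) < 2) abort("need at least two samples to normalize")
  if (anyNA(m$gene_id)) abort("missing gene ids")
  all_nan <- apply(vals, 1, function(r) all(is.na(r)))
  if (any(all_nan)) abort("all-NA expression row(s) present")
  ctr <- rowMeans(vals)
  s <- apply(vals, 1, sd)
  constant <- s == 0
  out <- vals
  if (method == "zscore") {
    out <- (vals - ctr) / ifelse(constant, 1, s)
  } else {
    lo <- apply(vals, 1, min); hi <- apply(vals, 1, max)
    out <- (vals - lo) / ifelse(constant, 1, hi - lo)
  }
  out[constant, ] <- 0
  res <- tibble(gene_id = m$gene_id) |> dplyr::bind_cols(as_tibble(out))
  res$constant <- constant
  res
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' For each target gene and condition, computes replicate-paired
#' `dCt = Ct_target - Ct_reference`, then
#' `ddCt = mean(dCt_condition) - mean(dCt_calibrator)` and
#' `RQ = 2^-ddCt`, with dispersion propagated from the replicate SD of
#' dCt (`rq_lo = 2^-(ddCt + sd)`, `rq_hi = 2^-(ddCt - sd)`).
#'
#' @param ct Tibble with columns `gene`, `condition`, `replicate`, `ct`
#'   (`ct > 0`).
#' @param ref_gene Reference (housekeeping) gene id; must be measured in
#'   every condition/replicate where a target is measured.
#' @param calibrator Calibrator condition (default `"CK"`).
#' @return Tibble of class `pf_rq`: `gene`, `condition`, `n`, `ddct`,
#'   `rq`, `rq_lo`, `rq_hi`, and a list-column `dct` of the replicate dCt
#'   values (used for significance calls).
#' @export
ddct <- function(ct, ref_gene, calibrator = "CK") {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    abort(paste0("ct table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(ct$ct <= 0)) abort("Ct values must be positive")
  if (!ref_gene %in% ct$gene) abort(paste0("reference gene ", ref_gene, " absent"))
  ref <- ct |> filter(.data$gene == ref_gene) |>
    select("condition", "replicate", ref_ct = "ct")
  tgt <- ct |> filter(.data$gene != ref_gene) |>
    left_join(ref, by = c("condition", "replicate"))
  if (anyNA(tgt$ref_ct)) {
    miss <- tgt |> filter(is.na(.data$ref_ct)) |> head(1)
    abort(paste0("missing reference replicate for condition ",
                 miss$condition, ", replicate ", miss$replicate))
  }
  dct <- tgt |>
    mutate(dct = .data$ct - .data$ref_ct) |>
    group_by(.data$gene, .data$condition) |>
    summarise(n = n(), mean_dct = mean(.data$dct), sd_dct = sd(.data$dct),
              dct = list(.data$dct), .groups = "drop")
  cal <- dct |> filter(.data$condition == calibrator) |>
    select("gene", cal_mean = "mean_dct", cal_dct = "dct")
  if (nrow(cal) == 0) abort(paste0("calibrator condition ", calibrator, " absent"))
  out <- dct |>
    left_join(cal, by = "gene") |>
    mutate(ddct = .data$mean_dct - .data$cal_mean,
           rq = 2^(-.data$ddct),
           rq_lo = 2^(-(.data$ddct + dplyr::coalesce(.data$sd_dct, 0))),
           rq_hi = 2^(-(.data$ddct - dplyr::coalesce(.data$sd_dct, 0)))) |>
    select("gene", "condition", "n", "ddct", "rq", "rq_lo", "rq_hi",
           "dct", "cal_dct")
  class(out) <- c("pf_rq", class(out))
  out
}

#' Significance calls for relative expression
#'
#' Two-sided Welch t-test of the replicate dCt values of each condition
#' against the calibrator's; `down` when `RQ < 1` and `p < alpha[1]`,
#' `up` when `RQ > 1` and `p < alpha[1]`, otherwise `ns`. Stars: `*` at
#' `alpha[1]` (default 0.05), `**` at `alpha[2]` (default 0.01). With
#' degenerate (zero) variance in both groups the call falls back to exact
#' equality: `ns` unless the group means differ.
#'
#' @param rq Output of [ddct()].
#' @param alpha Two significance levels, `c(0.05, 0.01)`.
#' @param calibrator Calibrator condition name (rows for it are `ns`).
#' @return `rq` with `p_value`, `regulation`, `stars` added (the `dct`
#'   list-columns are dropped).
#' @export
call_regulation <- function(rq, alpha = c(0.05, 0.01), calibrator = "CK") {
  res <- purrr::pmap(list(rq$condition, rq$dct, rq$cal_dct, rq$rq),
                     function(cond, d, cal, r) {
    if (cond == calibrator) return(list(p = NA_real_, reg = "ns"))
    if (length(d) < 2 || length(cal) < 2) {
      abort("need >= 2 replicates per group for significance calls")
    }
    p <- if (sd(d) == 0 && sd(cal) == 0) {
      if (isTRUE(all.equal(mean(d), mean(cal)))) 1 else 0
    } else {
      tryCatch(t.test(d, cal)$p.value, error = function(e) 1)
    }
    reg <- if (p < alpha[1] && r < 1) "down" else
      if (p < alpha[1] && r > 1) "up" else "ns"
    list(p = p, reg = reg)
  })
  rq$p_value <- purrr::map_dbl(res, "p")
  rq$regulation <- purrr::map_chr(res, "reg")
  rq$stars <- dplyr::case_when(
    !is.na(rq$p_value) & rq$p_value < alpha[2] & rq$regulation != "ns" ~ "**",
    !is.na(rq$p_value) & rq$p_value < alpha[1] & rq$regulation != "ns" ~ "*",
    TRUE ~ ""
  )
  rq |> select(-"dct", -"cal_dct")
}

#' Read an expression matrix / Ct table from TSV
#'
#' @param path Path to a tab-separated file with a header. The expression
#'   matrix has `gene_id` plus one numeric column per sample; the Ct
#'   table has `gene`, `condition`, `replicate`, `ct`.
#' @return A tibble.
#' @export
read_expression_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_expression_matrix
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene = "c", condition = "c",
                                          replicate = "i", ct = "d"))
}
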