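#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differing sites for multiple hits:
#' `d = -(3/4) * log(1 - 4p/3)`.
#'
#' @param p Observed proportion, `0 <= p < 3/4`.
#' @return Corrected distance `d >= 0`.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) abort("proportion must be nonnegative")
  if (any(p >= 0.75)) abort("saturated: proportion must be below 3/4")
  -0.75 * log(1 - 4 * p / 3)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) abort("sequence length is not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position the three possible single-nucleotide changes
#' are enumerated; changes creating a stop codon are excluded from the
#' site denominator, and the remaining changes are split into synonymous
#' and nonsynonymous fractions (each position contributes up to one site
#' in thirds).
#'
#' @param codon A sense codon (3-letter DNA string).
#' @param code Genetic code, a named character vector codon -> amino acid
#'   with `"*"` for stops (default [Biostrings::GENETIC_CODE]).
#' @return Named numeric vector `c(s, n)`.
#' @export
#' @examples
#' ng86_sites("GTT")  # third position fully synonymous: s = 1, n = 2
ng86_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  aa <- code[[codon]]
  if (is.null(aa) || is.na(aa)) abort(paste0("ambiguous codon: ", codon))
  if (aa == "*") abort("stop codon has no site counts")
  nts <- c("A", "C", "G", "T")
  s <- 0; n <- 0
  for (pos in 1:3) {
    for (alt in setdiff(nts, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      maa <- code[[mut]]
      if (maa == "*") next                 # excluded from the denominator
      if (maa == aa) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(s = s, n = n)
}

# per-session caches: 61 sense codons for sites, codon pairs for pathways
.ng86_cache <- new.env(parent = emptyenv())

ng86_sites_cached <- function(codon, code) {
  if (!identical(code, Biostrings::GENETIC_CODE)) return(ng86_sites(codon, code))
  hit <- .ng86_cache[[paste0("s_", codon)]]
  if (!is.null(hit)) return(hit)
  val <- ng86_sites(codon, code)
  .ng86_cache[[paste0("s_", codon)]] <- val
  val
}

codon_path_diffs_cached <- function(ca, cb, code) {
  if (!identical(code, Biostrings::GENETIC_CODE)) return(codon_path_diffs(ca, cb, code))
  key <- paste0("p_", ca, cb)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- codon_path_diffs(ca, cb, code)
  .ng86_cache[[key]] <- val
  val
}

# all shortest substitution pathways between two codons; returns the mean
# synonymous/nonsynonymous difference counts over pathways that avoid
# stop codons (falling back to all pathways if every one hits a stop)
codon_path_diffs <- function(ca, cb, code = Biostrings::GENETIC_CODE) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else {
    if (k == 2) list(pos, rev(pos)) else {
      idx <- expand.grid(1:3, 1:3, 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3), ]
      lapply(seq_len(nrow(idx)), function(i) pos[unlist(idx[i, ])])
    }
  }
  walk <- function(order) {
    cur <- ca
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (code[[nxt]] == "*") return(NULL)
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- purrr::compact(purrr::map(perms, walk))
  if (length(res) == 0) {       # every pathway passes a stop: count anyway
    res <- purrr::map(perms, function(order) {
      cur <- ca; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, res))
}

#' Pairwise Ka/Ks by Nei-Gojobori counting
#'
#' Counts average synonymous (S) and nonsynonymous (N) sites over the two
#' sequences, tallies synonymous (Sd) and nonsynonymous (Nd) differences —
#' averaging over all shortest substitution pathways for multi-hit
#' codons, excluding pathways through stop codons — and applies the
#' Jukes-Cantor correction to the proportions `pS = Sd/S`, `pN = Nd/N`.
#'
#' @param seq_a,seq_b Codon-aligned CDS strings of equal length (multiple
#'   of 3, no internal stops, no gaps — drop gapped codon columns first,
#'   e.g. via [backtranslate()]).
#' @param code Genetic code table.
#' @return One-row tibble of class `pf_kaks`: `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ka`, `Ks`, `ratio`, `saturated_s`, `saturated_n`. `Ka`/`Ks`
#'   are `NA` when saturated; `ratio` is `NA` unless `Ks > 0`.
#' @export
#' @examples
#' ng86_pair("GTTGACAAA", "GTAGACAAA")  # one synonymous difference
ng86_pair <- function(seq_a, seq_b, code = Biostrings::GENETIC_CODE) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must be equal length")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  if (any(grepl("-", c(ca, cb), fixed = TRUE))) {
    abort("gaps present: drop gapped codon columns before ng86_pair()")
  }
  if (any(code[ca] == "*") || any(code[cb] == "*")) {
    abort("internal stop codon in input")
  }
  sites_a <- vapply(ca, ng86_sites_cached, numeric(2), code = code)
  sites_b <- vapply(cb, ng86_sites_cached, numeric(2), code = code)
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  diffs <- purrr::map2(ca, cb, codon_path_diffs_cached, code = code)
  Sd <- sum(purrr::map_dbl(diffs, "sd"))
  Nd <- sum(purrr::map_dbl(diffs, "nd"))
  pS <- Sd / S
  pN <- Nd / N
  # a pair with no synonymous (or nonsynonymous) sites has an undefined,
  # not saturated, rate
  sat_s <- S > 0 && pS >= 0.75
  sat_n <- N > 0 && pN >= 0.75
  Ks <- if (S == 0 || sat_s) NA_real_ else jukes_cantor(pS)
  Ka <- if (N == 0 || sat_n) NA_real_ else jukes_cantor(pN)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  out <- tibble(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                Ka = Ka, Ks = Ks, ratio = ratio,
                saturated_s = sat_s, saturated_n = sat_n)
  class(out) <- c("pf_kaks", class(out))
  out
}

#' Back-translate a protein alignment onto codon sequences
#'
#' Expands each aligned protein to codons using its CDS (gaps become
#' `---`), after verifying that the CDS translates exactly to the
#' ungapped protein (standard code, terminal stop stripped). Codon
#' columns containing a gap in either sequence are then dropped pairwise.
#'
#' @param aln Named character vector or tibble (`id`, `seq`) of two
#'   aligned protein sequences (equal length, `-` for gaps).
#' @param cds Tibble (`id`, `seq`) of CDS records covering the same ids.
#' @param code Genetic code table.
#' @return List with `seq_a`, `seq_b` (gap-free codon alignment strings),
#'   `ids`, and `n_codons`.
#' @export
backtranslate <- function(aln, cds, code = Biostrings::GENETIC_CODE) {
  if (is.data.frame(aln)) aln <- setNames(aln$seq, aln$id)
  if (length(aln) != 2) abort("backtranslate() expects exactly two aligned proteins")
  if (nchar(aln[[1]]) != nchar(aln[[2]])) abort("aligned proteins differ in length")
  cds_map <- setNames(cds$seq, cds$id)
  expand_one <- function(id, prot_aln) {
    dna <- cds_map[[id]]
    if (is.null(dna)) abort(paste0("no CDS for ", id))
    codons <- split_codons(dna)
    k <- length(codons)
    if (code[[codons[k]]] == "*") codons <- codons[-k]    # strip terminal stop
    prot <- gsub("-", "", prot_aln, fixed = TRUE)
    trans <- unname(code[codons])
    if (length(trans) != nchar(prot)) {
      abort(paste0("CDS/protein length mismatch for ", id))
    }
    pv <- strsplit(prot, "")[[1]]
    bad <- which(trans != pv)
    if (length(bad) > 0) {
      abort(paste0("translation mismatch for ", id, " at residue ", bad[1],
                   ": CDS gives ", trans[bad[1]], ", protein has ", pv[bad[1]]))
    }
    out <- character(nchar(prot_aln))
    j <- 0L
    for (i in seq_len(nchar(prot_aln))) {
      if (substr(prot_aln, i, i) == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- codons[j] }
    }
    out
  }
  ids <- names(aln)
  a <- expand_one(ids[1], aln[[1]])
  b <- expand_one(ids[2], aln[[2]])
  keep <- a != "---" & b != "---"
  list(seq_a = paste(a[keep], collapse = ""),
       seq_b = paste(b[keep], collapse = ""),
       ids = ids, n_codons = sum(keep))
}

#' Ka/Ks for a table of paralog pairs
#'
#' Convenience wrapper running [backtranslate()] + [ng86_pair()] over a
#' tibble of pairs.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param alignments Named list of two-sequence protein alignments keyed
#'   `"<gene_a>|<gene_b>"` (each a named character vector), or `NULL` when
#'   `cds` sequences are already codon-aligned per pair.
#' @param cds CDS tibble (`id`, `seq`).
#' @return `pairs` with the [ng86_pair()] columns appended.
#' @export
kaks_table <- function(pairs, alignments, cds) {
  res <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    key <- paste0(a, "|", b)
    aln <- alignments[[key]]
    if (is.null(aln)) abort(paste0("no alignment for pair ", key))
    bt <- backtranslate(aln, cds)
    ng86_pair(bt$seq_a, bt$seq_b)
  }) |> bind_rows()
  dplyr::bind_cols(pairs, res)
}
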