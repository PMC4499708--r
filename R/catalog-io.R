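#' Read a FASTA file into a tidy sequence table
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns one row
#' per record, uppercases residues, and enforces unique ids.
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"`, `"cds"`, or `"auto"` (guess from residue
#'   composition: sequences that are >= 95% `ACGTUN-` are called `cds`).
#' @return A tibble with columns `id`, `kind`, `seq`, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ATGAAA", ">g2", "atgccc"), fa)
#' read_fasta(fa, kind = "cds")
read_fasta <- function(path, kind = c("auto", "protein", "cds")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) abort(paste0("empty FASTA file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no records in FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  one_kind <- function(s) {
    nuc <- sum(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "U", "N", "-"))
    if (nchar(s) > 0 && nuc / nchar(s) >= 0.95) "cds" else "protein"
  }
  kinds <- if (kind == "auto") vapply(seqs, one_kind, character(1)) else rep(kind, length(seqs))
  ok_chars <- function(s, k) {
    alpha <- if (k == "cds") "ACGTUN-" else
      paste0(paste(Biostrings::AA_ALPHABET, collapse = ""), "")
    all(strsplit(s, "")[[1]] %in% strsplit(alpha, "")[[1]])
  }
  bad <- !mapply(ok_chars, seqs, kinds)
  if (any(bad)) {
    abort(paste0("non-IUPAC characters in record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(id = unname(ids), kind = unname(kinds), seq = unname(seqs))
}

#' Write a tidy sequence table to FASTA
#'
#' @param records Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read gene models (with derived introns and phases) from GFF3
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features via [rtracklayer::import()],
#' keeps one transcript per gene (the first mRNA), derives introns as the
#' gaps between consecutive exons, and computes each intron's phase as the
#' cumulative coding length upstream of the intron modulo 3, walking the
#' spliced transcript 5'->3' (so minus-strand genes are phased on the
#' coding orientation). Ordinals rank genes by start within each
#' chromosome, counting every gene present in the file.
#'
#' @param path Path to a GFF3 file.
#' @param species Species label attached to every gene (single string).
#' @return A tibble with one row per gene: `gene_id`, `species`,
#'   `chromosome`, `strand`, `start`, `end`, `ordinal`, `n_exons`,
#'   `n_introns`, and list-columns `exons` (tibbles with `start`, `end`)
#'   and `introns` (tibbles with `start`, `end`, `phase`).
#' @export
read_gff3 <- function(path, species = NA_character_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  genes <- df |> filter(.data$type == "gene")
  if (nrow(genes) == 0) abort("GFF3 contains no gene features")
  mrna <- df |> filter(.data$type == "mRNA")
  parent_chr <- function(p) vapply(p, function(x) as.character(x)[1], character(1))
  mrna$gene <- parent_chr(mrna$Parent)
  # one transcript per gene: keep the first mRNA encountered
  mrna <- mrna[!duplicated(mrna$gene), ]
  segs <- df |> filter(.data$type %in% c("exon", "CDS"))
  segs$tx <- parent_chr(segs$Parent)

  models <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    tx <- mrna$ID[match(gid, mrna$gene)]
    ex <- segs |> filter(.data$tx == .env$tx, .data$type == "exon") |>
      select("start", "end") |> arrange(.data$start)
    cds <- segs |> filter(.data$tx == .env$tx, .data$type == "CDS") |>
      select("start", "end") |> arrange(.data$start)
    if (nrow(ex) == 0) ex <- tibble(start = g$start, end = g$end)
    if (nrow(cds) == 0) cds <- ex
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(paste0("overlapping exons in gene ", gid))
    }
    cds_len <- sum(cds$end - cds$start + 1)
    if (cds_len %% 3 != 0) {
      abort(paste0("CDS length of gene ", gid, " (", cds_len,
                   " bp) is not a multiple of 3"))
    }
    introns <- derive_introns(cds, strand = g$strand)
    tibble(
      gene_id = gid, species = species, chromosome = g$seqnames,
      strand = g$strand, start = g$start, end = g$end,
      n_exons = nrow(ex), n_introns = nrow(introns),
      exons = list(ex), introns = list(introns)
    )
  }) |> bind_rows()

  models |>
    group_by(.data$chromosome) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(ordinal = row_number()) |>
    ungroup() |>
    select("gene_id", "species", "chromosome", "strand", "start", "end",
           "ordinal", "n_exons", "n_introns", "exons", "introns")
}

#' Derive introns and their phases from coding exon segments
#'
#' Introns are the gaps between consecutive coding segments (genomic
#' order); the phase of an intron is the coding length upstream of it,
#' modulo 3, measured along the spliced 5'->3' transcript.
#'
#' @param cds Tibble of coding segments with `start`, `end` (1-based
#'   inclusive), sorted by genomic start.
#' @param strand `"+"` or `"-"`.
#' @return Tibble with `start`, `end`, `phase` (0/1/2); zero rows for
#'   single-segment genes.
#' @export
derive_introns <- function(cds, strand = "+") {
  cds <- arrange(cds, .data$start)
  k <- nrow(cds)
  if (k < 2) {
    return(tibble(start = integer(), end = integer(), phase = integer()))
  }
  gaps <- tibble(start = cds$end[-k] + 1L, end = cds$start[-1] - 1L)
  lens <- cds$end - cds$start + 1L
  # coding bases upstream of intron i (genomic order) along the transcript:
  # on the minus strand the transcript reads the segments right-to-left
  if (identical(strand, "-")) {
    upstream <- sum(lens) - cumsum(lens)[-k]
  } else {
    upstream <- cumsum(lens)[-k]
  }
  gaps$phase <- as.integer(upstream %% 3L)
  gaps
}

#' Read a per-protein feature annotation table
#'
#' Expects a tab-separated file with a header and columns `gene_id`,
#' `has_sp`, `has_gas`, `pcld_spans` (optionally `n_glyc_sites`). Spans are
#' written 1-based inclusive as `"10-110;130-230"` and parsed to 0-based
#' half-open intervals on the protein, the convention used internally for
#' all protein intervals.
#'
#' @param path Path to the TSV.
#' @param valid_ids Optional character vector; rows whose `gene_id` is not
#'   in it are dropped with a warning and counted in the
#'   `"skipped"` attribute of the result.
#' @return Tibble with `gene_id`, `has_sp`, `has_gas`, `pcld_count`, and a
#'   list-column `pcld_spans` of tibbles with 0-based half-open
#'   `start`/`end`.
#' @export
read_feature_table <- function(path, valid_ids = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("gene_id", "has_sp", "has_gas", "pcld_spans")
  if (!all(need %in% names(raw))) {
    abort(paste0("feature table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  skipped <- character()
  if (!is.null(valid_ids)) {
    bad <- !(raw$gene_id %in% valid_ids)
    if (any(bad)) {
      skipped <- raw$gene_id[bad]
      warn(paste0("skipping ", sum(bad),
                  " feature row(s) with unknown gene_id: ",
                  paste(head(skipped, 5), collapse = ", ")))
      raw <- raw[!bad, ]
    }
  }
  out <- tibble(
    gene_id = raw$gene_id,
    has_sp = as.logical(as.integer(raw$has_sp)),
    has_gas = as.logical(as.integer(raw$has_gas)),
    pcld_spans = purrr::map(raw$pcld_spans, parse_spans)
  )
  out$pcld_count <- purrr::map_int(out$pcld_spans, nrow)
  if ("n_glyc_sites" %in% names(raw)) {
    out$n_glyc_sites <- as.integer(raw$n_glyc_sites)
  }
  attr(out, "skipped") <- skipped
  out[c("gene_id", "has_sp", "has_gas", "pcld_count", "pcld_spans",
        intersect("n_glyc_sites", names(out)))]
}

# "10-110;130-230" (1-based inclusive) -> tibble of 0-based half-open spans
parse_spans <- function(txt) {
  if (is.na(txt) || txt == "" || txt == ".") {
    return(tibble(start = integer(), end = integer()))
  }
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  m <- stringr::str_match(parts, "^(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) abort(paste0("malformed span string: ", txt))
  a <- as.integer(m[, 2]); b <- as.integer(m[, 3])
  if (any(a > b)) abort(paste0("span start exceeds end in: ", txt))
  sp <- tibble(start = a - 1L, end = b) |> arrange(.data$start)
  if (nrow(sp) > 1 && any(sp$start[-1] < sp$end[-nrow(sp)])) {
    abort(paste0("overlapping spans in: ", txt))
  }
  sp
}

#' Read and write Newick trees
#'
#' Wrappers around [ape::read.tree()] / [ape::write.tree()] that keep
#' internal node labels (used for named ancestors such as V, E, T, A, G,
#' Eu, R) and branch lengths, and fail loudly on malformed input.
#'
#' @param path File path.
#' @return `read_newick()` returns an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- stringr::str_count(txt, stringr::fixed("("))
  n_close <- stringr::str_count(txt, stringr::fixed(")"))
  if (n_open != n_close) abort("unbalanced parentheses in Newick file")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) abort(paste0("Newick parse error: ",
                                                  conditionMessage(e))))
  if (is.null(tr)) abort("Newick parse error: no tree found")
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  txt <- ape::write.tree(tree, digits = 6)
  writeLines(txt, path)
  invisible(path)
}

#' Assemble a validated family catalog
#'
#' Binds a species table to the gene records and checks that the declared
#' per-species family size matches the number of gene records.
#'
#' @param species Tibble with `species`, `genome_size_mb`,
#'   `n_predicted_genes`, `n_family_genes`.
#' @param genes Gene-model tibble (as from [read_gff3()]) with a `species`
#'   column.
#' @return A list of class `"pf_catalog"` with elements `species` and
#'   `genes`.
#' @export
build_catalog <- function(species, genes) {
  counts <- genes |> count(.data$species, name = "n_obs")
  chk <- left_join(species, counts, by = "species")
  chk$n_obs[is.na(chk$n_obs)] <- 0L
  bad <- chk$n_family_genes != chk$n_obs
  if (any(bad)) {
    abort(paste0("catalog count mismatch for: ",
                 paste(chk$species[bad], collapse = ", ")))
  }
  structure(list(species = species, genes = genes), class = "pf_catalog")
}

#' @export
print.pf_catalog <- function(x, ...) {
  cat("<pf_catalog> ", nrow(x$genes), " genes across ",
      nrow(x$species), " species\n", sep = "")
  invisible(x)
}
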