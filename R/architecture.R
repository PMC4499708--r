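#' Detect AGP-like (Pro/Ala/Ser/Thr-rich) regions in a protein
#'
#' Slides a fixed-length window along the sequence and merges every
#' maximal run of qualifying windows — windows where the fraction of
#' residues in `{P, A, S, T}` is at least `min_past_fraction` — into a
#' single interval. Intervals are 0-based half-open on the protein.
#'
#' @param seq Protein sequence (single string).
#' @param window_len Window length in residues (default 10).
#' @param min_past_fraction Minimum PAST fraction per window (default 0.5).
#' @param exclude Optional 0-based half-open interval (e.g. a signal
#'   peptide) whose residues are skipped: windows overlapping it do not
#'   qualify.
#' @return Tibble of merged intervals with `start`, `end` (0-based
#'   half-open); zero rows when nothing qualifies or the sequence is
#'   shorter than the window.
#' @export
#' @examples
#' detect_alr("MMMMMPAPASTSTAPMMMMM")
detect_alr <- function(seq, window_len = 10L, min_past_fraction = 0.5,
                       exclude = NULL) {
  n <- nchar(seq)
  if (n < window_len) return(tibble(start = integer(), end = integer()))
  res <- strsplit(seq, "")[[1]]
  is_past <- res %in% c("P", "A", "S", "T")
  if (!is.null(exclude)) {
    is_past[seq.int(exclude[1] + 1L, min(exclude[2], n))] <- NA
  }
  cs <- cumsum(c(0L, ifelse(is.na(is_past), 0L, is_past)))
  blocked <- cumsum(c(0L, is.na(is_past)))
  starts <- seq_len(n - window_len + 1L)
  frac <- (cs[starts + window_len] - cs[starts]) / window_len
  ok <- frac >= min_past_fraction &
    (blocked[starts + window_len] - blocked[starts]) == 0L
  if (!any(ok)) return(tibble(start = integer(), end = integer()))
  # merge overlapping/adjacent qualifying windows into maximal intervals
  idx <- which(ok)
  brk <- c(0L, which(diff(idx) > window_len), length(idx))
  purrr::map(seq_len(length(brk) - 1L), function(i) {
    runs <- idx[(brk[i] + 1L):brk[i + 1L]]
    tibble(start = runs[1] - 1L, end = runs[length(runs)] + window_len - 1L)
  }) |> bind_rows()
}

#' Count arabinogalactan glycomodules within a region
#'
#' Counts non-overlapping occurrences of the configured dipeptides
#' (default `AP, PA, SP, TP, GP, VP`) inside a region of the protein —
#' typically an AGP-like region from [detect_alr()]. A region is called an
#' AG glycomodule carrier when the count reaches `min_count`.
#'
#' @param seq Protein sequence.
#' @param region 0-based half-open interval `c(start, end)`; `NULL` scans
#'   the whole sequence.
#' @param dipeptides Character vector of 2-residue motifs.
#' @param min_count Minimum motif count for the region to qualify.
#' @return List with `count`, `positions` (0-based motif starts), and
#'   `qualifies`.
#' @export
detect_ag_glycomodules <- function(seq, region = NULL,
                                   dipeptides = c("AP", "PA", "SP", "TP", "GP", "VP"),
                                   min_count = 2L) {
  n <- nchar(seq)
  if (is.null(region)) region <- c(0L, n)
  if (region[1] < 0 || region[2] > n || region[1] > region[2]) {
    abort("region outside sequence bounds")
  }
  sub <- substr(seq, region[1] + 1L, region[2])
  pos <- integer()
  i <- 1L
  while (i < nchar(sub)) {
    if (substr(sub, i, i + 1L) %in% dipeptides) {
      pos <- c(pos, region[1] + i - 1L)
      i <- i + 2L   # non-overlapping
    } else {
      i <- i + 1L
    }
  }
  list(count = length(pos), positions = pos,
       qualifies = length(pos) >= min_count)
}

#' Default architecture decision table
#'
#' The ten structural types are keyed on four features: presence of an
#' N-terminal secretion signal (`sp`), number of plastocyanin-like domains
#' (`pcld`, 1-3), presence of an AGP-like region (`alr`), and presence of
#' a C-terminal GPI-anchor signal (`gas`). Any three-domain protein is
#' type V regardless of the other flags. The remaining assignments follow
#' the published textual constraints; where the constraints leave a
#' combination open (some 2-domain cases and the sp-less 1-domain cases)
#' the defaults below are used and can be overridden.
#'
#' @return Tibble with columns `sp`, `pcld`, `alr`, `gas`, `type`, one row
#'   per feature tuple (24 rows: sp x {1,2,3} x alr x gas).
#' @export
default_architecture_table <- function() {
  grid <- tidyr::expand_grid(
    sp = c(TRUE, FALSE), pcld = 1:3,
    alr = c(TRUE, FALSE), gas = c(TRUE, FALSE)
  )
  lab <- function(sp, pcld, alr, gas) {
    if (pcld == 3) return("V")
    if (pcld == 2) {
      if (!sp) return("X")
      if (alr && gas) return("III")
      if (alr && !gas) return("IV")
      return("VIII")          # 2 domains, no ALR
    }
    # single domain
    if (sp && alr && gas) return("I")
    if (sp && alr && !gas) return("II")
    if (sp && !alr && gas) return("VII")
    if (sp && !alr && !gas) return("VI")
    if (!sp && !alr && !gas) return("IX")
    "IX"                       # sp-less single-domain with ALR and/or GAS
  }
  grid$type <- purrr::pmap_chr(grid, lab)
  grid
}

#' Classify protein architectures
#'
#' Assigns each annotated protein one of the ten structural type labels
#' (I-X) from its feature tuple via a decision table; proteins with no
#' domain are `"unclassified"` (and flagged for catalog exclusion), as are
#' proteins with more than three domains (with a warning).
#'
#' @param features Tibble as from [read_feature_table()], with logical
#'   `has_sp`, `has_gas`, integer `pcld_count`, and a logical `has_alr`
#'   column (add one with [annotate_alr()] or supply it directly).
#' @param table Decision table (see [default_architecture_table()]).
#' @return The input with `type` and `agp_candidate` columns added;
#'   `agp_candidate` marks proteins with a secretion signal and a
#'   qualifying AGP-like region.
#' @export
classify_architecture <- function(features, table = default_architecture_table()) {
  if (!"has_alr" %in% names(features)) {
    abort("features must have a has_alr column (see annotate_alr())")
  }
  if (any(features$pcld_count > 3)) {
    warn("proteins with more than 3 domains are left unclassified")
  }
  joined <- features |>
    mutate(.row = row_number(),
           sp = .data$has_sp, alr = .data$has_alr, gas = .data$has_gas,
           pcld = .data$pcld_count) |>
    left_join(table, by = c("sp", "pcld", "alr", "gas")) |>
    arrange(.data$.row)
  features$type <- ifelse(is.na(joined$type), "unclassified", joined$type)
  features$agp_candidate <- features$has_sp & features$has_alr
  features
}

#' Add ALR and AG-glycomodule annotations from sequence
#'
#' Runs [detect_alr()] and [detect_ag_glycomodules()] over each protein
#' and records whether it carries at least one AGP-like region with the
#' required number of AG glycomodules.
#'
#' @param features Feature tibble with `gene_id`.
#' @param proteins Sequence tibble (as from [read_fasta()]) whose `id`
#'   matches `gene_id`.
#' @inheritParams detect_alr
#' @inheritParams detect_ag_glycomodules
#' @return `features` with `has_alr` (logical) and `alr_spans`
#'   (list-column) added. `has_alr` requires a detected region that also
#'   qualifies by glycomodule count.
#' @export
annotate_alr <- function(features, proteins, window_len = 10L,
                         min_past_fraction = 0.5,
                         dipeptides = c("AP", "PA", "SP", "TP", "GP", "VP"),
                         min_count = 2L) {
  seqs <- setNames(proteins$seq, proteins$id)
  res <- purrr::map(features$gene_id, function(g) {
    s <- seqs[[g]]
    if (is.null(s)) return(list(spans = tibble(start = integer(), end = integer()),
                                has = FALSE))
    spans <- detect_alr(s, window_len, min_past_fraction)
    if (nrow(spans) == 0) return(list(spans = spans, has = FALSE))
    qual <- purrr::map_lgl(seq_len(nrow(spans)), function(i) {
      detect_ag_glycomodules(s, c(spans$start[i], spans$end[i]),
                             dipeptides, min_count)$qualifies
    })
    list(spans = spans[qual, , drop = FALSE], has = any(qual))
  })
  features$alr_spans <- purrr::map(res, "spans")
  features$has_alr <- purrr::map_lgl(res, "has")
  features
}

#' Summarise an architecture-typed catalog
#'
#' @param calls Output of [classify_architecture()], optionally with a
#'   `species` column.
#' @return A list with `totals` (one-row tibble: `n`, `n_sp`, `n_gas`,
#'   `n_agp`), `by_type` (type histogram), and `by_species` (per-species
#'   breakdown, when a `species` column is present).
#' @export
summarize_catalog <- function(calls) {
  totals <- tibble(
    n = nrow(calls),
    n_sp = sum(calls$has_sp),
    n_gas = sum(calls$has_gas),
    n_agp = sum(calls$agp_candidate)
  )
  by_type <- calls |> count(.data$type, name = "n") |> arrange(.data$type)
  by_species <- NULL
  if ("species" %in% names(calls)) {
    by_species <- calls |>
      group_by(.data$species) |>
      summarise(n = n(), n_sp = sum(.data$has_sp), n_gas = sum(.data$has_gas),
                n_agp = sum(.data$agp_candidate), .groups = "drop")
  }
  structure(list(totals = totals, by_type = by_type, by_species = by_species),
            class = "pf_catalog_summary")
}

#' @export
print.pf_catalog_summary <- function(x, ...) {
  cat("<architecture summary>\n")
  print(x$totals)
  print(x$by_type)
  invisible(x)
}
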