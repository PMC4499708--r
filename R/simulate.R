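#' Default 10-taxon labelled species tree
#'
#' A fixed species tree mirroring the standard plant lineage structure
#' (alga basal; then moss, lycophyte; grasses rice and maize under G;
#' eudicots under Eu with the rosids under R), with labelled ancestors
#' V (Viridiplantae), E (Embryophyte), T (Tracheophyte), A (Angiosperm),
#' G (Grass), Eu (eudicot), R (Rosid). Branch lengths are arbitrary but
#' fixed time units.
#'
#' @return A rooted [ape::phylo] with 10 tips and labelled internal nodes.
#' @export
default_species_tree <- function() {
  txt <- paste0(
    "(Chlamydomonas_reinhardtii:3.0,(Physcomitrella_patens:2.5,",
    "(Selaginella_moellendorffii:2.0,((Oryza_sativa:1.0,Zea_mays:1.0)G:1.0,",
    "(Solanum_lycopersicum:1.5,(Vitis_vinifera:1.2,(Populus_trichocarpa:1.0,",
    "(Glycine_max:0.8,Arabidopsis_thaliana:0.8):0.2)R:0.3):0.3)",
    "Eu:0.5)A:0.5)T:0.5)E:0.5)V;")
  ape::read.tree(text = txt)
}

#' Simulation configuration
#'
#' @param seed Integer RNG seed.
#' @param species_tree Labelled species tree (default
#'   [default_species_tree()]).
#' @param birth,loss Per-lineage duplication and loss rates per unit
#'   branch length.
#' @param mechanism_mix Named probabilities for
#'   `tandem`/`segmental`/`retrotransposition` (must sum to 1).
#' @param ks_rate True synonymous divergence accumulated per unit time on
#'   each lineage (pairwise Ks = ks_rate * total path length).
#' @param n_codons Codon count for simulated coding pairs.
#' @param type_probs Architecture-type distribution for emitted feature
#'   tables (named over I..X).
#' @param qpcr_noise_sd Gaussian noise SD on simulated Ct values.
#' @return List of class `pf_sim_config`.
#' @export
sim_config <- function(seed = 1L, species_tree = default_species_tree(),
                       birth = 0.4, loss = 0.1,
                       mechanism_mix = c(tandem = 0.3, segmental = 0.4,
                                         retrotransposition = 0.3),
                       ks_rate = 0.15, n_codons = 300L,
                       type_probs = c(I = 0.4, II = 0.15, III = 0.05,
                                      IV = 0.05, V = 0.05, VI = 0.1,
                                      VII = 0.05, VIII = 0.05, IX = 0.05,
                                      X = 0.05),
                       qpcr_noise_sd = 0.15) {
  if (abs(sum(mechanism_mix) - 1) > 1e-9) abort("mechanism_mix must sum to 1")
  if (birth < 0 || loss < 0 || ks_rate < 0) abort("rates must be nonnegative")
  if (abs(sum(type_probs) - 1) > 1e-9) abort("type_probs must sum to 1")
  structure(list(seed = as.integer(seed), species_tree = species_tree,
                 birth = birth, loss = loss, mechanism_mix = mechanism_mix,
                 ks_rate = ks_rate, n_codons = as.integer(n_codons),
                 type_probs = type_probs, qpcr_noise_sd = qpcr_noise_sd),
            class = "pf_sim_config")
}

species_abbrev <- function(sp) {
  parts <- strsplit(sp, "_")[[1]]
  paste0(toupper(substr(parts[1], 1, 1)),
         substr(parts[length(parts)], 1, 2))
}

#' Simulate a gene family by birth-death along the species tree
#'
#' A single ancestral gene enters the root; on every species branch each
#' gene lineage duplicates at rate `birth` (each duplication tagged with
#' a mechanism drawn from `mechanism_mix`; retro children lose the
#' conserved intron) and dies at rate `loss`. Surviving lineages split at
#' speciations. If every lineage dies the simulation retries (up to
#' `max_attempts`) before failing.
#'
#' @param config A [sim_config()].
#' @param max_attempts Retries when the family goes extinct.
#' @return List of class `pf_family`: `gene_tree` (ape::phylo, branch
#'   lengths in time units), `genes` (tibble `gene_id`, `species`,
#'   `lineage`, `has_conserved_intron`), `events` (tibble `time`,
#'   `species_node`, `mechanism`, `parent_lineage`, `child_lineage`),
#'   `losses` (tibble `time`, `species_node`, `lineage`), `config`,
#'   `attempts`.
#' @export
simulate_family <- function(config = sim_config(), max_attempts = 50L) {
  st <- config$species_tree
  set.seed(config$seed)
  for (attempt in seq_len(max_attempts)) {
    res <- try_simulate_family(config, st)
    if (!is.null(res)) {
      res$attempts <- attempt
      return(res)
    }
  }
  abort(paste0("family extinct in all ", max_attempts, " attempts"))
}

try_simulate_family <- function(config, st) {
  nt <- length(st$tip.label)
  s_children <- split(st$edge[, 2], st$edge[, 1])
  blen <- setNames(st$edge.length, st$edge[, 2])
  root <- nt + 1L
  env <- new.env()
  env$next_id <- 1L
  env$events <- list()
  env$losses <- list()
  env$intron <- list()
  env$genes <- list()
  new_lineage <- function(has_intron) {
    id <- paste0("g", env$next_id)
    env$next_id <- env$next_id + 1L
    env$intron[[id]] <- has_intron
    id
  }
  mech_names <- names(config$mechanism_mix)

  # one lineage evolving over remaining time t; survivor leaves are
  # placeholders resolved at the species node below
  evolve <- function(lin, t, t0, snode) {
    rate <- config$birth + config$loss
    wait <- if (rate > 0) rexp(1, rate) else Inf
    if (wait >= t) return(list(type = "survivor", lin = lin, len = t))
    if (runif(1) < config$loss / rate) {
      env$losses[[length(env$losses) + 1L]] <-
        tibble(time = t0 + wait, species_node = node_name(st, snode), lineage = lin)
      return(NULL)
    }
    mech <- sample(mech_names, 1, prob = config$mechanism_mix)
    child <- new_lineage(if (mech == "retrotransposition") FALSE
                         else env$intron[[lin]])
    env$events[[length(env$events) + 1L]] <- tibble(
      time = t0 + wait, species_node = node_name(st, snode),
      mechanism = mech, parent_lineage = lin, child_lineage = child)
    left <- evolve(lin, t - wait, t0 + wait, snode)
    right <- evolve(child, t - wait, t0 + wait, snode)
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) { right$len <- right$len + wait; return(right) }
    if (is.null(right)) { left$len <- left$len + wait; return(left) }
    list(type = "node", len = wait, children = list(left, right))
  }

  # resolve survivor placeholders at a species node (speciate or emit tip)
  resolve <- function(node, snode, t0) {
    if (node$type == "node") {
      ch <- purrr::map(node$children, resolve, snode = snode, t0 = t0)
      ch <- purrr::compact(ch)
      if (length(ch) == 0) return(NULL)
      if (length(ch) == 1) { ch[[1]]$len <- ch[[1]]$len + node$len; return(ch[[1]]) }
      return(list(type = "node", len = node$len, children = ch))
    }
    lin <- node$lin
    if (snode <= nt) {
      sp <- st$tip.label[snode]
      gid <- paste0(species_abbrev(sp), "_", lin)
      env$genes[[length(env$genes) + 1L]] <- tibble(
        gene_id = gid, species = sp, lineage = lin,
        has_conserved_intron = env$intron[[lin]])
      return(list(type = "tip", len = node$len, label = gid))
    }
    ch <- purrr::map(s_children[[as.character(snode)]], function(sc) {
      sub <- evolve(lin, blen[[as.character(sc)]], t0, sc)
      if (is.null(sub)) return(NULL)
      resolve(sub, sc, t0 + blen[[as.character(sc)]])
    })
    ch <- purrr::compact(ch)
    if (length(ch) == 0) return(NULL)
    if (length(ch) == 1) { ch[[1]]$len <- ch[[1]]$len + node$len; return(ch[[1]]) }
    list(type = "node", len = node$len, children = ch)
  }

  g1 <- new_lineage(TRUE)
  tree0 <- resolve(list(type = "survivor", lin = g1, len = 0), root, 0)
  genes <- bind_rows(env$genes)
  if (is.null(tree0) || nrow(genes) < 2) return(NULL)

  to_newick <- function(nd) {
    if (nd$type == "tip") return(paste0(nd$label, ":", sprintf("%.9f", nd$len)))
    inner <- paste(vapply(nd$children, to_newick, character(1)), collapse = ",")
    paste0("(", inner, "):", sprintf("%.9f", nd$len))
  }
  gt <- ape::read.tree(text = paste0(to_newick(tree0), ";"))
  structure(list(
    gene_tree = gt,
    genes = genes,
    events = if (length(env$events)) bind_rows(env$events) else
      tibble(time = numeric(), species_node = character(),
             mechanism = character(), parent_lineage = character(),
             child_lineage = character()),
    losses = if (length(env$losses)) bind_rows(env$losses) else
      tibble(time = numeric(), species_node = character(), lineage = character()),
    config = config
  ), class = "pf_family")
}

#' @export
print.pf_family <- function(x, ...) {
  cat("<pf_family> ", nrow(x$genes), " extant genes, ",
      nrow(x$events), " duplication event(s)\n", sep = "")
  invisible(x)
}

#' True pairwise synonymous divergence of a simulated family
#'
#' Pairwise Ks is the total time separating two genes (patristic
#' distance on the time-scaled gene tree) times the configured `ks_rate`.
#'
#' @param family A `pf_family` from [simulate_family()].
#' @return Symmetric matrix of true Ks values.
#' @export
true_ks_matrix <- function(family) {
  ape::cophenetic.phylo(family$gene_tree) * family$config$ks_rate
}

# codon pool whose synonymous variation is exactly one four-fold
# degenerate third position per codon (no synonymous first positions,
# so the synonymous process is Jukes-Cantor on third positions)
sim_codon_pool <- function() {
  prefixes <- c(V = "GT", S = "TC", P = "CC", T = "AC", A = "GC", G = "GG")
  unname(prefixes)
}

#' Simulate a codon-aligned pair with controlled divergence
#'
#' Draws an ancestral sequence from a codon pool whose synonymous sites
#' are all four-fold degenerate third positions, then applies
#' `Poisson(target_ks * S)` synonymous events (random third-position
#' changes) and `Poisson(target_ka * N)` nonsynonymous events (first/
#' second-position changes that stay inside the pool) to one copy.
#' Synonymous and nonsynonymous events touch disjoint positions, so the
#' realized event counts are exact ground truth and no stop codon can
#' ever arise.
#'
#' @param target_ks Target synonymous substitutions per synonymous site.
#' @param target_ratio Target Ka/Ks ratio (default 0.3).
#' @param n_codons Number of codons (>= 10 when any divergence is
#'   requested).
#' @param seed RNG seed.
#' @return List: `seq_a`, `seq_b`, `n_codons`, `true_syn_events`,
#'   `true_nonsyn_events`, `true_ks` (events per synonymous site),
#'   `true_ka`.
#' @export
simulate_codon_pair <- function(target_ks, target_ratio = 0.3,
                                n_codons = 300L, seed = 1L) {
  if (target_ks < 0) abort("target_ks must be nonnegative")
  if (n_codons < 10 && target_ks > 0) {
    abort("sequence too short for the requested divergence")
  }
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  pool <- sim_codon_pool()
  pre <- sample(pool, n_codons, replace = TRUE)
  third <- sample(nts, n_codons, replace = TRUE)
  anc <- paste0(pre, third)
  b_pre <- pre
  b_third <- third

  S <- n_codons  # every pool codon has exactly one (4-fold) synonymous site
  n_syn <- rpois(1, target_ks * S)
  for (k in seq_len(n_syn)) {
    i <- sample.int(n_codons, 1)
    b_third[i] <- sample(setdiff(nts, b_third[i]), 1)
  }

  N <- sum(vapply(anc, function(cd) ng86_sites(cd)[["n"]], numeric(1)))
  target_ka <- target_ks * target_ratio
  n_non <- rpois(1, target_ka * N)
  for (k in seq_len(n_non)) {
    repeat {
      i <- sample.int(n_codons, 1)
      alt <- sample(setdiff(pool, b_pre[i]), 1)
      # change exactly one of the two prefix positions
      cur <- strsplit(b_pre[i], "")[[1]]
      nxt <- strsplit(alt, "")[[1]]
      if (sum(cur != nxt) == 1) { b_pre[i] <- alt; break }
    }
  }
  list(seq_a = paste(anc, collapse = ""),
       seq_b = paste(paste0(b_pre, b_third), collapse = ""),
       n_codons = n_codons,
       true_syn_events = n_syn, true_nonsyn_events = n_non,
       true_ks = n_syn / S, true_ka = n_non / N)
}

# canonical feature tuple realizing each architecture type
type_feature_tuple <- function(type) {
  switch(type,
         I    = list(sp = TRUE,  pcld = 1L, alr = TRUE,  gas = TRUE),
         II   = list(sp = TRUE,  pcld = 1L, alr = TRUE,  gas = FALSE),
         III  = list(sp = TRUE,  pcld = 2L, alr = TRUE,  gas = TRUE),
         IV   = list(sp = TRUE,  pcld = 2L, alr = TRUE,  gas = FALSE),
         V    = list(sp = TRUE,  pcld = 3L, alr = TRUE,  gas = TRUE),
         VI   = list(sp = TRUE,  pcld = 1L, alr = FALSE, gas = FALSE),
         VII  = list(sp = TRUE,  pcld = 1L, alr = FALSE, gas = TRUE),
         VIII = list(sp = TRUE,  pcld = 2L, alr = FALSE, gas = FALSE),
         IX   = list(sp = FALSE, pcld = 1L, alr = FALSE, gas = FALSE),
         X    = list(sp = FALSE, pcld = 2L, alr = FALSE, gas = FALSE),
         abort(paste0("unknown architecture type: ", type)))
}

# protein whose ALR/glycomodule content realizes the tuple: non-PAST
# background with one PAST-rich AG-module segment appended when alr=TRUE
sim_protein_seq <- function(tuple) {
  bg <- c("M", "K", "L", "V", "E", "D", "F", "I", "N", "R", "W", "Y", "H", "Q")
  n_dom <- tuple$pcld
  body <- paste(sample(bg, 30 + 60 * n_dom, replace = TRUE), collapse = "")
  if (tuple$alr) paste0(body, "APAPSPTPAPAPSPTPAPAP") else body
}

#' Emit a genome layout, feature table and sequences for a simulated family
#'
#' Places the focal species' extant genes on chromosomes so that each
#' duplication mechanism leaves its genomic signature: tandem children
#' adjacent to their parent (few intervening genes), segmental children
#' inside a collinear block with companion filler anchors,
#' retrotransposed children dispersed to another chromosome as
#' intronless single-exon genes. Architecture types are drawn from the
#' configured distribution and realized as feature flags plus protein
#' sequences.
#'
#' @param family A `pf_family` from [simulate_family()].
#' @param focal_species Species whose genome is laid out (default the
#'   species with most extant genes).
#' @param n_chrom Number of chromosomes.
#' @return List of class `pf_layout`: `genes` (gene-model tibble in
#'   [read_gff3()] shape), `pairs` (tibble `gene_a`, `gene_b`,
#'   `mechanism_true` for events with both copies extant in the focal
#'   species), `anchors`, `features`, `proteins`, `truth_types`,
#'   `intron` (per-gene conserved-intron truth), `focal_species`.
#' @export
simulate_genome_layout <- function(family, focal_species = NULL, n_chrom = 5L) {
  genes <- family$genes
  if (is.null(focal_species)) {
    focal_species <- genes |> count(.data$species) |>
      arrange(dplyr::desc(.data$n)) |> pull("species") |> head(1)
  }
  fg <- genes |> filter(.data$species == focal_species)
  if (nrow(fg) == 0) abort(paste0("no extant genes in ", focal_species))
  set.seed(family$config$seed + 7777L)

  lin2gene <- setNames(fg$gene_id, fg$lineage)
  ev <- family$events |>
    filter(.data$parent_lineage %in% fg$lineage,
           .data$child_lineage %in% fg$lineage)
  child_of <- setNames(ev$mechanism, lin2gene[ev$child_lineage])
  parent_of <- setNames(lin2gene[ev$parent_lineage], lin2gene[ev$child_lineage])

  occ <- new.env(); occ$used <- character()
  place <- function(chrom, ord) {
    while (paste0(chrom, ":", ord) %in% occ$used) ord <- ord + 1L
    occ$used <- c(occ$used, paste0(chrom, ":", ord))
    ord
  }
  pos <- list()       # gene_id -> list(chrom, ord)
  zone <- new.env(); zone$nxt <- setNames(rep(1L, n_chrom), paste0("chr", seq_len(n_chrom)))
  fresh_zone <- function(chrom) {
    o <- zone$nxt[[chrom]]
    zone$nxt[[chrom]] <- o + 200L
    o
  }
  anchors <- list()

  # place parents before children
  ordered <- fg$gene_id
  placed <- function(g) !is.null(pos[[g]])
  repeat {
    progress <- FALSE
    for (g in ordered) {
      if (placed(g)) next
      mech <- unname(child_of[g])
      par <- unname(parent_of[g])
      if (!is.na(mech) && !is.na(par) && !placed(par)) next
      if (is.na(mech) || is.na(par)) {
        chrom <- paste0("chr", sample.int(n_chrom, 1))
        pos[[g]] <- list(chrom = chrom, ord = place(chrom, fresh_zone(chrom)))
      } else if (mech == "tandem") {
        p <- pos[[par]]
        pos[[g]] <- list(chrom = p$chrom,
                         ord = place(p$chrom, p$ord + 1L + sample(0:2, 1)))
      } else if (mech == "segmental") {
        p <- pos[[par]]
        other <- setdiff(paste0("chr", seq_len(n_chrom)), p$chrom)
        chrom <- sample(other, 1)
        base <- fresh_zone(chrom)
        ord <- place(chrom, base)
        pos[[g]] <- list(chrom = chrom, ord = ord)
        for (i in 1:3) {     # companion filler anchors, collinear
          fa_ord <- place(p$chrom, p$ord + i * 5L)
          fb_ord <- place(chrom, ord + i * 5L)
          anchors[[length(anchors) + 1L]] <- tibble(
            gene_a = paste0("fill_", g, "_", i, "a"),
            gene_b = paste0("fill_", g, "_", i, "b"),
            chrom_a = p$chrom, chrom_b = chrom,
            ord_a = fa_ord, ord_b = fb_ord)
        }
        anchors[[length(anchors) + 1L]] <- tibble(
          gene_a = par, gene_b = g, chrom_a = p$chrom, chrom_b = chrom,
          ord_a = p$ord, ord_b = ord)
      } else {               # retrotransposition: dispersed
        p <- pos[[par]]
        other <- setdiff(paste0("chr", seq_len(n_chrom)), p$chrom)
        chrom <- sample(other, 1)
        pos[[g]] <- list(chrom = chrom, ord = place(chrom, fresh_zone(chrom)))
      }
      progress <- TRUE
    }
    if (all(vapply(ordered, placed, logical(1)))) break
    if (!progress) abort("could not place all genes (cyclic parentage?)")
  }

  intron_truth <- setNames(fg$has_conserved_intron, fg$gene_id)
  # gene models: 300 bp coding; intron-bearing genes get the conserved
  # phase-1 intron after 100 coding bases (residue 33.3, inside the
  # domain span [20, 80))
  models <- purrr::map(fg$gene_id, function(g) {
    p <- pos[[g]]
    g0 <- p$ord * 10000L
    if (intron_truth[[g]]) {
      exons <- tibble(start = c(g0, g0 + 400L),
                      end = c(g0 + 99L, g0 + 599L))
      introns <- derive_introns(exons, "+")
    } else {
      exons <- tibble(start = g0, end = g0 + 299L)
      introns <- derive_introns(exons, "+")
    }
    tibble(gene_id = g, species = focal_species, chromosome = p$chrom,
           strand = "+", start = g0, end = max(exons$end),
           ordinal = p$ord, n_exons = nrow(exons), n_introns = nrow(introns),
           exons = list(exons), introns = list(introns))
  }) |> bind_rows()

  pairs <- tibble(gene_a = unname(lin2gene[ev$parent_lineage]),
                  gene_b = unname(lin2gene[ev$child_lineage]),
                  mechanism_true = ev$mechanism)

  types <- sample(names(family$config$type_probs), nrow(fg), replace = TRUE,
                  prob = family$config$type_probs)
  tuples <- purrr::map(types, type_feature_tuple)
  proteins <- tibble(
    id = fg$gene_id, kind = "protein",
    seq = purrr::map_chr(tuples, sim_protein_seq))
  features <- tibble(
    gene_id = fg$gene_id,
    has_sp = purrr::map_lgl(tuples, "sp"),
    has_gas = purrr::map_lgl(tuples, "gas"),
    pcld_count = purrr::map_int(tuples, "pcld"),
    pcld_spans = purrr::map(tuples, function(tp) {
      tibble(start = 30L + 60L * (seq_len(tp$pcld) - 1L),
             end = 30L + 60L * (seq_len(tp$pcld) - 1L) + 50L)
    }))

  structure(list(
    genes = models, pairs = pairs,
    anchors = if (length(anchors)) bind_rows(anchors) else
      tibble(gene_a = character(), gene_b = character(),
             chrom_a = character(), chrom_b = character(),
             ord_a = integer(), ord_b = integer()),
    features = features, proteins = proteins,
    truth_types = tibble(gene_id = fg$gene_id, type = types),
    intron = tibble(gene_id = fg$gene_id,
                    has_conserved_intron = unname(intron_truth)),
    focal_species = focal_species
  ), class = "pf_layout")
}

#' Simulate a qPCR Ct table with known relative expression
#'
#' Reference-gene Ct is centred at 20 and target Ct at 24 for the
#' calibrator; a condition with true relative expression `RQ` shifts the
#' target Ct by `-log2(RQ)`. Independent Gaussian noise (`noise_sd`) is
#' added to every Ct, so with `noise_sd = 0` the 2^-ddCt estimate equals
#' the truth exactly.
#'
#' @param true_rq Tibble `gene`, `condition`, `rq` (`rq > 0`); the
#'   calibrator condition is added automatically with `rq = 1`.
#' @param n_reps Replicates per gene/condition (>= 2).
#' @param noise_sd Gaussian Ct noise SD.
#' @param seed RNG seed.
#' @param ref_gene Reference gene id.
#' @param calibrator Calibrator condition name.
#' @return Tibble `gene`, `condition`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(true_rq, n_reps = 3L, noise_sd = 0.15, seed = 1L,
                          ref_gene = "Actin1", calibrator = "CK") {
  if (n_reps < 2) abort("n_reps must be >= 2")
  if (any(true_rq$rq <= 0)) abort("true RQ must be positive")
  set.seed(seed)
  conds <- unique(c(calibrator, true_rq$condition))
  genes <- unique(true_rq$gene)
  full <- tidyr::expand_grid(gene = genes, condition = conds) |>
    left_join(true_rq, by = c("gene", "condition")) |>
    mutate(rq = ifelse(.data$condition == calibrator, 1, .data$rq))
  if (anyNA(full$rq)) abort("true_rq must cover every gene x condition")
  rows <- tidyr::expand_grid(full, replicate = seq_len(n_reps)) |>
    mutate(ct = 24 - log2(.data$rq) + rnorm(n(), 0, noise_sd))
  ref <- tidyr::expand_grid(gene = ref_gene, condition = conds,
                            replicate = seq_len(n_reps)) |>
    mutate(ct = 20 + rnorm(n(), 0, noise_sd))
  bind_rows(rows |> select("gene", "condition", "replicate", "ct"), ref) |>
    arrange(.data$gene, .data$condition, .data$replicate)
}

#' Write a simulated run to disk as standard formats
#'
#' Emits the focal-genome layout as GFF3, the feature table and anchors
#' as TSV, proteins as FASTA, the gene tree and species tree as Newick,
#' and a manifest recording the seed.
#'
#' @param family A `pf_family`.
#' @param layout A `pf_layout` for the same family.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_run <- function(family, layout, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(layout$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(
    layout$features |>
      mutate(pcld_spans = purrr::map_chr(.data$pcld_spans, function(sp) {
        paste(paste0(sp$start + 1L, "-", sp$end), collapse = ";")
      }),
      has_sp = as.integer(.data$has_sp), has_gas = as.integer(.data$has_gas)) |>
      select("gene_id", "has_sp", "has_gas", "pcld_spans"),
    file.path(dir, "features.tsv"))
  readr::write_tsv(layout$anchors, file.path(dir, "anchors.tsv"))
  write_fasta(layout$proteins, file.path(dir, "proteins.fa"))
  write_newick(family$gene_tree, file.path(dir, "gene_tree.nwk"))
  write_newick(family$config$species_tree, file.path(dir, "species_tree.nwk"))
  writeLines(paste0("seed\t", family$config$seed), file.path(dir, "MANIFEST.tsv"))
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param models Gene-model tibble (shape of [read_gff3()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    ex <- g$exons[[1]]
    lines <- c(lines,
      paste(g$chromosome, "phytofam", "gene", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chromosome, "phytofam", "mRNA", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id), sep = "\t"))
    lens <- ex$end - ex$start + 1L
    phases <- c(0L, cumsum(lens) %% 3L)[seq_len(nrow(ex))]
    phases <- (3L - phases) %% 3L
    for (j in seq_len(nrow(ex))) {
      for (tp in c("exon", "CDS")) {
        ph <- if (tp == "CDS") as.character(phases[j]) else "."
        lines <- c(lines,
          paste(g$chromosome, "phytofam", tp, ex$start[j], ex$end[j], ".",
                g$strand, ph, paste0("Parent=", g$gene_id, ".t1"), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
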