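# Synthetic universes with planted signal: latent drug/protein modules
# whose within-module pairs form the positives, plus gene-set collections
# with one planted enriched term.  Everything is reproducible under a seed
# and written in the same plain-text formats the readers consume, so the
# generator doubles as format documentation.

#' Specify a synthetic universe
#'
#' Drugs and proteins are assigned to latent modules; every similarity
#' measure is a clipped Gaussian around the within-module mean for
#' same-module entity pairs and the between-module mean otherwise, with
#' independent noise per measure.  The golden-standard positives are a
#' random fraction of the within-module drug-protein pairs.  Missingness is
#' applied per entity per source.
#'
#' @param n_drugs,n_proteins universe sizes (defaults 60 and 80).
#' @param n_modules number of latent modules (default 4).
#' @param within_module_sim,between_module_sim means of the similarity
#'   distributions (within must exceed between, else the planted signal is
#'   void and generation refuses).
#' @param sim_sd Gaussian noise sd for both regimes.
#' @param availability per-source probability an entity has the source.
#' @param gsp_fraction fraction of within-module drug-protein pairs drawn
#'   as positives.
#' @param seed RNG seed (default 7).
#' @return a `universe_spec` list.
#' @export
universe_spec <- function(n_drugs = 60L, n_proteins = 80L, n_modules = 4L,
                          within_module_sim = 0.65,
                          between_module_sim = 0.20, sim_sd = 0.15,
                          availability = 0.9, gsp_fraction = 0.5,
                          seed = 7L) {
  if (within_module_sim <= between_module_sim)
    stop("within-module similarity must exceed between-module similarity: ",
         "the planted signal would be void")
  if (within_module_sim > 1 || within_module_sim < 0 ||
      between_module_sim > 1 || between_module_sim < 0)
    stop("similarity means must lie in [0, 1]")
  stopifnot(n_drugs >= n_modules, n_proteins >= n_modules,
            availability > 0, availability <= 1,
            gsp_fraction > 0, gsp_fraction <= 1)
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 n_modules = as.integer(n_modules),
                 within_module_sim = within_module_sim,
                 between_module_sim = between_module_sim,
                 sim_sd = sim_sd, availability = availability,
                 gsp_fraction = gsp_fraction, seed = as.integer(seed)),
            class = "universe_spec")
}

clipped_module_sim <- function(modules, within, between, sd) {
  n <- length(modules)
  mu <- matrix(between, n, n)
  same <- outer(modules, modules, `==`)
  mu[same] <- within
  noise <- matrix(0, n, n)
  up <- upper.tri(noise)
  noise[up] <- rnorm(sum(up), 0, sd)
  noise <- noise + t(noise)
  v <- mu + noise
  v[v < 0] <- 0
  v[v > 1] <- 1
  diag(v) <- 1
  v
}

apply_missingness <- function(v, rate) {
  miss <- runif(nrow(v)) > rate
  v[miss, ] <- NA_real_
  v[, miss] <- NA_real_
  v
}

#' Generate a synthetic universe
#'
#' @param spec a [universe_spec()].
#' @return list with `drug_sims` (six measures), `prot_sims` (three
#'   measures), `gsp` ([interaction_set()]), `drug_ids`, `protein_ids`,
#'   `drug_modules`, `protein_modules`, and the `spec`.
#' @export
generate_universe <- function(spec = universe_spec()) {
  stopifnot(inherits(spec, "universe_spec"))
  with_seed(spec$seed, {
    drug_ids <- sprintf("D%03d", seq_len(spec$n_drugs))
    protein_ids <- sprintf("P%03d", seq_len(spec$n_proteins))
    dm <- sort(rep_len(seq_len(spec$n_modules), spec$n_drugs))
    pm <- sort(rep_len(seq_len(spec$n_modules), spec$n_proteins))
    make <- function(ids, modules, measure) {
      v <- clipped_module_sim(modules, spec$within_module_sim,
                              spec$between_module_sim, spec$sim_sd)
      v <- apply_missingness(v, spec$availability)
      dimnames(v) <- list(ids, ids)
      sim_matrix(v, measure)
    }
    drug_sims <- setNames(
      lapply(DRUG_MEASURES, function(m) make(drug_ids, dm, m)),
      DRUG_MEASURES)
    prot_sims <- setNames(
      lapply(PROTEIN_MEASURES, function(m) make(protein_ids, pm, m)),
      PROTEIN_MEASURES)
    within <- expand.grid(compound_id = drug_ids, protein_id = protein_ids,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    within <- within[dm[match(within$compound_id, drug_ids)] ==
                       pm[match(within$protein_id, protein_ids)], ]
    n_pos <- round(spec$gsp_fraction * nrow(within))
    if (n_pos < 10L)
      stop("gsp_fraction yields only ", n_pos,
           " positives; too small to train (need >= 10)")
    gsp <- interaction_set(within[sample.int(nrow(within), n_pos), ],
                           role = "GSP")
    # planted-signal sanity: within-module mean must beat between in every
    # generated measure
    for (sims in list(drug_sims, prot_sims)) {
      mods <- if (identical(sims, drug_sims)) dm else pm
      for (m in names(sims)) {
        v <- unclass(sims[[m]])
        same <- outer(mods, mods, `==`); diag(same) <- NA
        w <- mean(v[which(same)], na.rm = TRUE)
        b <- mean(v[which(!same)], na.rm = TRUE)
        if (!is.finite(w) || !is.finite(b) || w <= b)
          stop("generated measure ", m,
               " lost its planted signal (within <= between)")
      }
    }
    list(drug_sims = drug_sims, prot_sims = prot_sims, gsp = gsp,
         drug_ids = drug_ids, protein_ids = protein_ids,
         drug_modules = setNames(dm, drug_ids),
         protein_modules = setNames(pm, protein_ids), spec = spec)
  })
}

#' Generate a gene-set collection with one planted term
#'
#' Random decoy terms of varied size plus one designated planted term whose
#' id is returned, so tests can assert its recovery after sampling targets
#' from it.
#'
#' @param proteins protein/gene id universe.
#' @param n_terms number of decoy terms (the planted term is extra).
#' @param planted_term_size members of the planted term.
#' @param seed RNG seed.
#' @param category collection category.
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `planted_term` (its id).
#' @export
generate_gene_sets <- function(proteins, n_terms = 30L,
                               planted_term_size = 20L, seed = 7L,
                               category = "pathway") {
  proteins <- unique(as.character(proteins))
  if (planted_term_size > length(proteins))
    stop("planted term larger than the protein universe")
  with_seed(seed, {
    planted <- sample(proteins, planted_term_size)
    sets <- list()
    if (n_terms > 0L) {
      sizes <- sample(seq(5L, max(5L, min(25L, length(proteins)))),
                      n_terms, replace = TRUE)
      sets <- lapply(sizes, function(s) sample(proteins, min(s,
                                                             length(proteins))))
      names(sets) <- sprintf("TERM%03d", seq_len(n_terms))
    }
    sets[["TERM_PLANTED"]] <- planted
    list(collection = gene_set_collection(sets, category = category,
                                          universe = proteins),
         planted_term = "TERM_PLANTED")
  })
}

#' Generate raw compound records (secondary fixture path)
#'
#' Random fingerprints, functional-group counts, side-effect terms, ATC
#' codes and expression signatures, to exercise the raw-data similarity
#' operations end-to-end.  Statistical structure only, no real chemistry.
#'
#' @param n number of compounds.
#' @param seed RNG seed.
#' @param fp_len fingerprint length.
#' @param n_genes expression-signature length.
#' @return list of [compound_record()] objects.
#' @export
generate_compound_records <- function(n = 10L, seed = 7L, fp_len = 64L,
                                      n_genes = 30L) {
  with_seed(seed, {
    vocab_se <- sprintf("SE%02d", 1:20)
    atc_pool <- c("C09AA02", "C09AA05", "N02BA01", "A10BA02", "C07AB03",
                  "J01CA04", "L01XE07", "R03AC02")
    lapply(seq_len(n), function(i) {
      compound_record(
        compound_id = sprintf("CID%04d", i),
        fingerprint = as.integer(runif(fp_len) < 0.3),
        functional_groups = stats::rpois(12L, 1.2),
        side_effects = sample(vocab_se, sample(0:6, 1)),
        atc_codes = sample(atc_pool, sample(0:2, 1)),
        expression_signature = rnorm(n_genes))
    })
  })
}

#' Generate raw protein records and a PPI graph (secondary fixture path)
#'
#' @param n number of proteins.
#' @param seed RNG seed.
#' @param seq_len_range sequence length range.
#' @param edge_prob PPI edge probability (Erdos-Renyi).
#' @return list with `records` ([protein_record()] list) and `ppi`
#'   (undirected igraph over all protein ids).
#' @export
generate_protein_records <- function(n = 8L, seed = 7L,
                                     seq_len_range = c(40L, 80L),
                                     edge_prob = 0.25) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    ids <- sprintf("GENE%03d", seq_len(n))
    go_pool <- sprintf("GO:%07d", 1:25)
    records <- lapply(seq_len(n), function(i) {
      len <- sample(seq(seq_len_range[1], seq_len_range[2]), 1)
      protein_record(
        protein_id = ids[i],
        sequence = paste(sample(aa, len, replace = TRUE), collapse = ""),
        go_terms = sample(go_pool, sample(0:8, 1)),
        in_network = TRUE)
    })
    g <- igraph::sample_gnp(n, edge_prob, directed = FALSE)
    igraph::V(g)$name <- ids
    list(records = records, ppi = g)
  })
}

#' Write a synthetic universe to a directory in interchange formats
#'
#' Writes `drug_<measure>.tsv` and `protein_<measure>.tsv` similarity
#' matrices plus `gsp.tsv`, exactly the files the CLI consumes.
#'
#' @param universe a [generate_universe()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(universe$drug_sims))
    write_sim_matrix(universe$drug_sims[[m]],
                     file.path(dir, paste0("drug_", m, ".tsv")))
  for (m in names(universe$prot_sims))
    write_sim_matrix(universe$prot_sims[[m]],
                     file.path(dir, paste0("protein_", m, ".tsv")))
  write_interactions(universe$gsp, file.path(dir, "gsp.tsv"))
  invisible(dir)
}

#' Read the similarity matrices written by [write_universe()]
#'
#' @param dir directory containing `drug_*.tsv` / `protein_*.tsv` files.
#' @return list with `drug_sims` and `prot_sims`.
#' @export
read_sim_dir <- function(dir) {
  read_side <- function(prefix, measures) {
    out <- list()
    for (m in measures) {
      f <- file.path(dir, paste0(prefix, "_", m, ".tsv"))
      if (file.exists(f)) out[[m]] <- read_sim_matrix(f, m)
    }
    out
  }
  drug_sims <- read_side("drug", DRUG_MEASURES)
  prot_sims <- read_side("protein", PROTEIN_MEASURES)
  if (!length(drug_sims) || !length(prot_sims))
    stop("no similarity matrices found under ", dir)
  list(drug_sims = drug_sims, prot_sims = prot_sims)
}
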