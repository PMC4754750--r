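# Likelihood-ratio predictor: GSN sampling, binned LR estimation, mRMR
# feature selection, max-LR scoring, ranking and cutoff application.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a golden-standard negative set
#'
#' Draws `|GSP|` compound-protein pairs uniformly at random from the
#' combinations of drugs and proteins appearing in the positive set,
#' excluding the positives themselves.  Reproducible under `seed`.
#'
#' @param gsp golden-standard positive [interaction_set()].
#' @param drugs,proteins entity pools; default: entities appearing in `gsp`.
#' @param seed integer RNG seed.
#' @param size number of negatives; default `nrow(gsp)` (equal size).
#' @return an [interaction_set()] with role `"GSN"`.
#' @export
sample_gsn <- function(gsp, drugs = NULL, proteins = NULL, seed = 1L,
                       size = nrow(gsp)) {
  drugs <- sort(unique(drugs %||% gsp$compound_id))
  proteins <- sort(unique(proteins %||% gsp$protein_id))
  n_all <- length(drugs) * length(proteins)
  if (n_all - nrow(gsp) < size)
    stop("not enough non-positive combinations (", n_all - nrow(gsp),
         ") to sample ", size, " negatives")
  all_pairs <- expand.grid(compound_id = drugs, protein_id = proteins,
                           stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  neg_pool <- all_pairs[!(pair_keys(all_pairs) %in% pair_keys(gsp)), ]
  idx <- with_seed(seed, sample.int(nrow(neg_pool), size))
  interaction_set(neg_pool[idx, ], role = "GSN")
}

bin_edges <- function(n_bins) seq(0, 1, length.out = n_bins + 1L)

# Map values in [0,1] to bin index 1..B (NA passes through).
bin_of <- function(x, n_bins) {
  b <- findInterval(x, bin_edges(n_bins), rightmost.closed = TRUE,
                    all.inside = TRUE)
  b[is.na(x)] <- NA_integer_
  b
}

lr_from_counts <- function(pos_counts, neg_counts, pseudocount) {
  B <- length(pos_counts)
  n_pos <- sum(pos_counts); n_neg <- sum(neg_counts)
  ((pos_counts + pseudocount) / (n_pos + pseudocount * B)) /
    ((neg_counts + pseudocount) / (n_neg + pseudocount * B))
}

#' Estimate per-feature binned likelihood ratios
#'
#' For each feature, the value range \[0, 1\] is split into `n_bins`
#' equal-width bins; the bin likelihood ratio is the smoothed relative
#' frequency of the bin among positives divided by that among negatives:
#' \deqn{LR_b = \frac{(c^+_b + \alpha) / (n^+ + \alpha B)}
#'                   {(c^-_b + \alpha) / (n^- + \alpha B)}.}
#' Missing feature values are excluded from the counts.  A feature missing
#' for every pair is dropped with a warning.
#'
#' @param features a [build_feature_table()] result covering all GSP and
#'   GSN pairs.
#' @param gsp,gsn positive / negative interaction sets.
#' @param n_bins number of equal-width bins (>= 2), default 20.
#' @param pseudocount Laplace smoothing \eqn{\alpha}, default 1.
#' @return an `lr_model` (without feature selection; see [mrmr_select()] and
#'   [train_lr_model()]).
#' @export
estimate_lr <- function(features, gsp, gsn, n_bins = 20L, pseudocount = 1) {
  stopifnot(n_bins >= 2L, pseudocount >= 0)
  fkey <- pair_keys(features)
  ip <- match(pair_keys(gsp), fkey)
  ineg <- match(pair_keys(gsn), fkey)
  if (anyNA(ip) || anyNA(ineg))
    stop("feature table must cover all GSP and GSN pairs")
  feats <- list()
  for (f in feature_names(features)) {
    vp <- features[[f]][ip]; vn <- features[[f]][ineg]
    if (all(is.na(vp)) && all(is.na(vn))) {
      warning("feature ", f, " missing for all pairs; dropped")
      next
    }
    pos_counts <- tabulate(bin_of(vp, n_bins), nbins = n_bins)
    neg_counts <- tabulate(bin_of(vn, n_bins), nbins = n_bins)
    feats[[f]] <- list(
      edges = bin_edges(n_bins),
      lr = lr_from_counts(pos_counts, neg_counts, pseudocount),
      pos_counts = pos_counts, neg_counts = neg_counts,
      n_pos = sum(pos_counts), n_neg = sum(neg_counts))
  }
  if (!length(feats)) stop("no usable feature (all missing)")
  structure(list(features = feats, n_bins = as.integer(n_bins),
                 pseudocount = pseudocount,
                 selected_features = names(feats),
                 provenance = list(n_gsp = nrow(gsp), n_gsn = nrow(gsn))),
            class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  cat("<lr_model> ", length(x$features), " features estimated (",
      x$n_bins, " bins, alpha=", x$pseudocount, "); selected: ",
      paste(x$selected_features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Discrete mutual information (natural log) of two equal-length vectors.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Greedy mRMR (MID) feature selection
#'
#' Features are discretized onto the LR bins (missing values become their
#' own level so sample size stays constant).  The first feature maximizes
#' mutual information with the labels; each subsequent feature maximizes
#' relevance minus mean redundancy,
#' \eqn{MI(f; y) - \mathrm{mean}_{s \in S} MI(f; s)} (Peng et al.'s
#' difference form).  Ties break by feature name for determinism.
#'
#' @param features feature table covering the labeled pairs, or a numeric
#'   data frame of feature columns.
#' @param labels logical/0-1 vector, one per feature-table row.
#' @param k number of features to select (>= 1); fewer are returned when
#'   fewer features exist.
#' @param n_bins discretization bins, default 20.
#' @return character vector of feature names in selection order.
#' @export
mrmr_select <- function(features, labels, k = 8L, n_bins = 20L) {
  if (k <= 0L) stop("k must be >= 1")
  fnames <- feature_names(features) %||%
    setdiff(names(features), c("compound_id", "protein_id"))
  if (!length(fnames)) stop("no features to select from")
  if (length(labels) != nrow(features))
    stop("labels must match feature-table rows")
  disc <- lapply(fnames, function(f) {
    b <- bin_of(features[[f]], n_bins)
    b[is.na(b)] <- 0L  # missing as its own level
    b
  })
  names(disc) <- fnames
  relevance <- vapply(disc, mutual_information, 0, y = labels)
  selected <- character(0)
  remaining <- fnames[order(-relevance, fnames)]
  red_sum <- setNames(numeric(length(fnames)), fnames)
  while (length(selected) < min(k, length(fnames))) {
    if (!length(selected)) {
      pick <- remaining[1L]
    } else {
      crit <- relevance[remaining] - red_sum[remaining] / length(selected)
      ord <- order(-crit, remaining)
      pick <- remaining[ord[1L]]
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    for (f in remaining)
      red_sum[f] <- red_sum[f] + mutual_information(disc[[f]], disc[[pick]])
  }
  selected
}

#' Train the full LR prediction model
#'
#' Builds features for GSP and GSN pairs against the GSP references
#' (self-exclusion on), estimates binned likelihood ratios, and selects
#' `n_selected_features` by mRMR.  The reference positive set is stored in
#' the model so that scoring is self-contained given similarity matrices.
#'
#' @param gsp,gsn interaction sets.
#' @param drug_sims,prot_sims named lists of [sim_matrix] objects.
#' @param n_bins,pseudocount see [estimate_lr()].
#' @param n_selected_features mRMR subset size, default 8.
#' @param feature_subset optional explicit feature-name restriction applied
#'   before estimation (e.g. the three structure-involved features); LRs are
#'   then estimated on that subset only.
#' @param exclude_policy self-exclusion policy for feature building.
#' @param seed recorded in provenance (training itself is deterministic).
#' @return an `lr_model` with `selected_features` set and `gsp` attached.
#' @export
train_lr_model <- function(gsp, gsn, drug_sims, prot_sims, n_bins = 20L,
                           pseudocount = 1, n_selected_features = 8L,
                           feature_subset = NULL,
                           exclude_policy = "pair", seed = NA_integer_) {
  pairs <- rbind(as.data.frame(gsp), as.data.frame(gsn))
  ft <- build_feature_table(pairs, gsp, drug_sims, prot_sims,
                            exclude_policy = exclude_policy)
  if (!is.null(feature_subset)) {
    keep <- intersect(feature_names(ft), feature_subset)
    if (!length(keep)) stop("feature_subset matches no computed feature")
    ft <- structure(ft[, c("compound_id", "protein_id", keep)],
                    features = keep, class = class(ft))
  }
  model <- estimate_lr(ft, gsp, gsn, n_bins = n_bins,
                       pseudocount = pseudocount)
  labels <- c(rep(1L, nrow(gsp)), rep(0L, nrow(gsn)))
  avail <- intersect(feature_names(ft), names(model$features))
  ftav <- structure(ft, features = avail, class = class(ft))
  model$selected_features <-
    mrmr_select(ftav, labels, k = n_selected_features, n_bins = n_bins)
  model$gsp <- as.data.frame(gsp)
  model$provenance$seed <- seed
  model$provenance$exclude_policy <- exclude_policy
  model
}

# Max-LR score for rows of a feature table under a fitted model.
lr_scores <- function(model, features) {
  sel <- intersect(model$selected_features, names(model$features))
  sel <- intersect(sel, feature_names(features) %||% names(features))
  if (!length(sel)) stop("model has no selected feature present in the table")
  smat <- matrix(NA_real_, nrow(features), length(sel))
  for (j in seq_along(sel)) {
    f <- sel[j]
    b <- bin_of(features[[f]], model$n_bins)
    ok <- !is.na(b)
    smat[ok, j] <- model$features[[f]]$lr[b[ok]]
  }
  row_max_na(smat)
}

#' Score compound-protein pairs with a trained model
#'
#' The score of a pair is the maximum likelihood ratio over the model's
#' selected features that are non-missing for that pair.  Pairs for which
#' every selected feature is missing get `NA` (unscorable).
#'
#' @param model an `lr_model` from [train_lr_model()].
#' @param pairs data frame with `compound_id`, `protein_id`.
#' @param drug_sims,prot_sims similarity matrices.
#' @param exclude_policy self-exclusion policy for feature building.
#' @return numeric scores, one per pair (`NA` = unscorable).
#' @export
predict_scores <- function(model, pairs, drug_sims, prot_sims,
                           exclude_policy = "pair") {
  if (is.null(model$gsp)) stop("model carries no reference positive set")
  ft <- build_feature_table(pairs, model$gsp, drug_sims, prot_sims,
                            exclude_policy = exclude_policy)
  lr_scores(model, ft)
}

#' Rank candidate targets for one compound
#'
#' Scores every candidate protein and sorts by decreasing score, breaking
#' ties lexicographically by protein id.  Known targets (from a
#' user-supplied known-interaction table) are flagged and always retained,
#' even when unscorable; unscorable non-known candidates are dropped and
#' counted.
#'
#' @param compound compound id.
#' @param candidates character vector of candidate protein ids.
#' @param model trained `lr_model`.
#' @param drug_sims,prot_sims similarity matrices.
#' @param known_targets optional data frame (`compound_id`, `protein_id`).
#' @return a `ranked_targets` data frame (`protein_id`, `score`,
#'   `is_known`) with attributes `compound_id` and `n_unscorable`.
#' @export
rank_targets <- function(compound, candidates, model, drug_sims, prot_sims,
                         known_targets = NULL) {
  if (!length(candidates)) stop("candidate set is empty")
  in_any <- any(vapply(drug_sims, function(m) compound %in% rownames(m),
                       logical(1)))
  if (!in_any)
    stop("compound ", compound,
         " absent from every drug similarity matrix: no basis for prediction")
  candidates <- unique(as.character(candidates))
  known <- character(0)
  if (!is.null(known_targets) && nrow(known_targets))
    known <- known_targets$protein_id[known_targets$compound_id == compound]
  pairs <- data.frame(compound_id = compound, protein_id = candidates,
                      stringsAsFactors = FALSE)
  sc <- predict_scores(model, pairs, drug_sims, prot_sims)
  df <- data.frame(protein_id = candidates, score = sc,
                   is_known = candidates %in% known,
                   stringsAsFactors = FALSE)
  n_unscorable <- sum(is.na(df$score) & !df$is_known)
  df <- df[!is.na(df$score) | df$is_known, , drop = FALSE]
  df <- df[order(-ifelse(is.na(df$score), -Inf, df$score), df$protein_id), ]
  rownames(df) <- NULL
  structure(df, compound_id = compound, n_unscorable = n_unscorable,
            class = c("ranked_targets", "data.frame"))
}

#' Apply the score cutoff to a ranking
#'
#' Returns the union of predicted targets with score strictly above
#' `score_cutoff` and all known targets (kept regardless of score) — the
#' "potential targets" consumed by every downstream analysis.
#'
#' @param ranked a [rank_targets()] result.
#' @param score_cutoff non-negative score threshold.
#' @return subset of `ranked` rows (potential targets).
#' @export
apply_cutoff <- function(ranked, score_cutoff) {
  stopifnot(score_cutoff >= 0)
  keep <- (!is.na(ranked$score) & ranked$score > score_cutoff) |
    ranked$is_known
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize / load an LR model as JSON
#'
#' The JSON document stores bin edges, per-bin LRs and counts, the selected
#' features, the configuration and provenance (seed, set sizes), and the
#' reference positive set; reloading reproduces scoring exactly.
#'
#' @param model an `lr_model`.
#' @param path output path.
#' @return `read_lr_model` returns the model; the writer returns `path`
#'   invisibly.
#' @export
write_lr_model <- function(model, path) {
  doc <- list(
    format = "herbtargets-lr-model", version = 1L,
    n_bins = model$n_bins, pseudocount = model$pseudocount,
    selected_features = as.list(model$selected_features),
    provenance = model$provenance,
    features = model$features,
    gsp = model$gsp)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_lr_model
#' @export
read_lr_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "herbtargets-lr-model"))
    stop("not an LR model file: ", path)
  feats <- lapply(doc$features, function(f) {
    list(edges = as.numeric(f$edges), lr = as.numeric(f$lr),
         pos_counts = as.integer(f$pos_counts),
         neg_counts = as.integer(f$neg_counts),
         n_pos = as.integer(f$n_pos), n_neg = as.integer(f$n_neg))
  })
  structure(list(features = feats, n_bins = as.integer(doc$n_bins),
                 pseudocount = as.numeric(doc$pseudocount),
                 selected_features = as.character(doc$selected_features),
                 provenance = doc$provenance,
                 gsp = as.data.frame(doc$gsp)),
            class = "lr_model")
}
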