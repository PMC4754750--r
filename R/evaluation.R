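# Cross-validation schemes, independent-test protocol and ROC/AUC.
#
# The leave-one-interaction-out scheme is implemented exactly but without
# naive refitting: per-feature query-vs-reference product matrices are
# computed once, self-reference columns of training positives are masked,
# and a fold that removes one reference column only needs the per-row top-2
# maxima to recompute every feature value in O(n) (the held-out pair's own
# reference column is the only column a fold ever excludes).

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic (probability a random positive
#' outscores a random negative, ties counted 1/2), computed from average
#' ranks.  The ROC curve is a score-threshold sweep with tied scores
#' collapsed onto one point; it starts at (0,0) and ends at (1,1).
#'
#' @param scores numeric scores (higher = more positive); `NA` not allowed.
#' @param labels logical or 0/1 labels, both classes present.
#' @return an `evaluation_result` fragment: list with `auc`, `roc`
#'   (data frame `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("NA scores or labels not allowed")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present (", n_pos, " positives, ",
         n_neg, " negatives)")
  r <- rank(scores)  # average ranks: ties counted 1/2 in the U statistic
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), 0L)
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), 0L)
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(auc = auc, roc = roc, n_pos = n_pos, n_neg = n_neg)
}

# Per-row top-2 values and the column of the top value, ignoring NA.
row_top2 <- function(m) {
  n <- nrow(m)
  t1 <- rep(NA_real_, n); c1 <- rep(NA_integer_, n); t2 <- rep(NA_real_, n)
  for (j in seq_len(ncol(m))) {
    v <- m[, j, drop = TRUE]
    ok <- !is.na(v)
    better <- ok & (is.na(t1) | v > t1)
    t2[better] <- t1[better]
    t1[better] <- v[better]
    c1[better] <- j
    second <- ok & !better & (is.na(t2) | v > t2)
    t2[second] <- v[second]
  }
  list(top1 = t1, col1 = c1, top2 = t2)
}

# Shared fold engine: masked product matrices + per-fold LR scoring.
cv_engine <- function(gsp, gsn, drug_sims, prot_sims, n_bins, pseudocount,
                      n_selected_features, feature_subset, select_per_fold,
                      leak_self) {
  pairs <- rbind(as.data.frame(gsp)[, c("compound_id", "protein_id")],
                 as.data.frame(gsn)[, c("compound_id", "protein_id")])
  labels <- c(rep(TRUE, nrow(gsp)), rep(FALSE, nrow(gsn)))
  grid <- feature_grid(names(drug_sims), names(prot_sims))
  if (!is.null(feature_subset)) {
    grid <- grid[grid$feature %in% feature_subset, , drop = FALSE]
    if (!nrow(grid)) stop("feature_subset matches no feature")
  }
  prods <- pair_ref_products(pairs, gsp, drug_sims, prot_sims, grid)
  self_col <- match(pair_keys(pairs), pair_keys(gsp))  # NA for negatives
  if (!leak_self) {
    has <- which(!is.na(self_col))
    for (f in names(prods))
      prods[[f]][cbind(has, self_col[has])] <- NA_real_
  }
  list(pairs = pairs, labels = labels, grid = grid, prods = prods,
       self_col = self_col)
}

# Baseline (no fold exclusion) feature table from an engine.
engine_features <- function(eng) {
  ft <- eng$pairs
  for (f in names(eng$prods)) ft[[f]] <- row_max_na(eng$prods[[f]])
  structure(ft, features = names(eng$prods),
            class = c("feature_table", "data.frame"))
}

# LR score of rows `score_rows` using bins/counts from rows `train_rows`,
# feature values supplied per feature in `vals` (list of numeric vectors).
fold_scores <- function(vals, labels, train_rows, score_rows, selected,
                        n_bins, pseudocount) {
  smat <- matrix(NA_real_, length(score_rows), length(selected))
  for (j in seq_along(selected)) {
    v <- vals[[selected[j]]]
    b <- bin_of(v, n_bins)
    bp <- b[train_rows][labels[train_rows]]
    bn <- b[train_rows][!labels[train_rows]]
    lr <- lr_from_counts(tabulate(bp[!is.na(bp)], n_bins),
                         tabulate(bn[!is.na(bn)], n_bins), pseudocount)
    bi <- b[score_rows]
    ok <- !is.na(bi)
    smat[ok, j] <- lr[bi[ok]]
  }
  row_max_na(smat)
}

new_evaluation_result <- function(scheme, scores, labels, n_folds, n_skipped,
                                  config) {
  frag <- roc_auc(scores, labels)
  structure(list(scheme = scheme, scores = scores, labels = labels,
                 auc = frag$auc, roc = frag$roc, n_folds = n_folds,
                 n_skipped = n_skipped, config = config),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> scheme=", x$scheme, ", AUC=",
      formatC(x$auc, digits = 4, format = "f"), ", ", x$n_folds, " folds (",
      x$n_skipped, " skipped), ", sum(x$labels), "+/", sum(!x$labels),
      "- pooled\n", sep = "")
  invisible(x)
}

#' Leave-one-interaction-out cross-validation
#'
#' Each pair of the golden-standard dataset (positives and negatives alike)
#' is held out in turn; features and likelihood ratios are recomputed with
#' that pair removed from its set — and, for positives, from the
#' feature-reference positives — and the pair is scored.  All (score,
#' label) pairs are pooled into one ROC/AUC.  Feature selection is run once
#' on the full data by default (`select_per_fold = TRUE` gives the strict,
#' slower protocol).
#'
#' @param gsp,gsn interaction sets.
#' @param drug_sims,prot_sims similarity matrices.
#' @param n_bins,pseudocount,n_selected_features model configuration.
#' @param feature_subset optional feature-name restriction.
#' @param select_per_fold rerun mRMR inside every fold.
#' @param leak_self test-only switch disabling self-pair exclusion, to
#'   demonstrate that the exclusion matters.
#' @return an `evaluation_result` (pooled scores, ROC points, AUC,
#'   fold/skip counts, config snapshot).
#' @export
loio_cv <- function(gsp, gsn, drug_sims, prot_sims, n_bins = 20L,
                    pseudocount = 1, n_selected_features = 8L,
                    feature_subset = NULL, select_per_fold = FALSE,
                    leak_self = FALSE) {
  if (!nrow(gsp) || !nrow(gsn)) stop("GSP and GSN must be non-empty")
  eng <- cv_engine(gsp, gsn, drug_sims, prot_sims, n_bins, pseudocount,
                   n_selected_features, feature_subset, select_per_fold,
                   leak_self)
  n <- nrow(eng$pairs)
  tops <- lapply(eng$prods, row_top2)
  base_vals <- lapply(tops, `[[`, "top1")
  selected_full <- mrmr_select(engine_features(eng), eng$labels,
                               k = n_selected_features, n_bins = n_bins)
  scores <- rep(NA_real_, n)
  n_skipped <- 0L
  for (h in seq_len(n)) {
    k0 <- eng$self_col[h]  # reference column to drop (NA for negatives)
    if (!is.na(k0) && nrow(gsp) <= 1L) {
      warning("fold ", h, " skipped: no reference pair left")
      n_skipped <- n_skipped + 1L
      next
    }
    if (is.na(k0) || leak_self) {
      vals <- base_vals
    } else {
      vals <- lapply(names(tops), function(f) {
        tp <- tops[[f]]
        v <- tp$top1
        hitk <- which(!is.na(tp$col1) & tp$col1 == k0)
        v[hitk] <- tp$top2[hitk]
        v
      })
      names(vals) <- names(tops)
    }
    train_rows <- setdiff(seq_len(n), h)
    selected <- if (select_per_fold) {
      ftf <- eng$pairs[train_rows, ]
      for (f in names(vals)) ftf[[f]] <- vals[[f]][train_rows]
      ftf <- structure(ftf, features = names(vals),
                       class = c("feature_table", "data.frame"))
      mrmr_select(ftf, eng$labels[train_rows], k = n_selected_features,
                  n_bins = n_bins)
    } else selected_full
    scores[h] <- fold_scores(vals, eng$labels, train_rows, h, selected,
                             n_bins, pseudocount)
  }
  usable <- !is.na(scores)
  n_unscorable <- sum(!usable) - n_skipped
  new_evaluation_result(
    "loio", scores[usable], eng$labels[usable], n_folds = n,
    n_skipped = n_skipped,
    config = list(n_bins = n_bins, pseudocount = pseudocount,
                  selected_features = selected_full,
                  select_per_fold = select_per_fold, leak_self = leak_self,
                  n_unscorable = n_unscorable))
}

#' Leave-one-drug-out cross-validation
#'
#' Folds are the distinct drugs of the golden-standard dataset (a drug
#' appearing only among negatives is still a fold).  All of a drug's pairs
#' are held out together; the remaining pairs train the likelihood ratios
#' and serve as feature references, simulating ab initio prediction for a
#' compound with no known targets.  Pooled scoring as in [loio_cv()].
#'
#' @inheritParams loio_cv
#' @return an `evaluation_result`.
#' @export
lodo_cv <- function(gsp, gsn, drug_sims, prot_sims, n_bins = 20L,
                    pseudocount = 1, n_selected_features = 8L,
                    feature_subset = NULL, select_per_fold = FALSE) {
  if (!nrow(gsp) || !nrow(gsn)) stop("GSP and GSN must be non-empty")
  eng <- cv_engine(gsp, gsn, drug_sims, prot_sims, n_bins, pseudocount,
                   n_selected_features, feature_subset, select_per_fold,
                   leak_self = FALSE)
  drugs <- sort(unique(eng$pairs$compound_id))
  if (length(drugs) < 2L) stop("leave-one-drug-out needs >= 2 distinct drugs")
  selected_full <- mrmr_select(engine_features(eng), eng$labels,
                               k = n_selected_features, n_bins = n_bins)
  n <- nrow(eng$pairs)
  scores <- rep(NA_real_, n)
  n_skipped <- 0L
  for (d in drugs) {
    hold <- which(eng$pairs$compound_id == d)
    drop_cols <- which(gsp$compound_id == d)
    if (length(drop_cols) >= nrow(gsp)) {
      warning("fold for drug ", d, " skipped: no reference pair left")
      n_skipped <- n_skipped + 1L
      next
    }
    vals <- lapply(eng$prods, function(m) {
      if (length(drop_cols))
        row_max_na(m[, -drop_cols, drop = FALSE])
      else row_max_na(m)
    })
    train_rows <- setdiff(seq_len(n), hold)
    selected <- if (select_per_fold) {
      ftf <- eng$pairs[train_rows, ]
      for (f in names(vals)) ftf[[f]] <- vals[[f]][train_rows]
      ftf <- structure(ftf, features = names(vals),
                       class = c("feature_table", "data.frame"))
      mrmr_select(ftf, eng$labels[train_rows], k = n_selected_features,
                  n_bins = n_bins)
    } else selected_full
    scores[hold] <- fold_scores(vals, eng$labels, train_rows, hold, selected,
                                n_bins, pseudocount)
  }
  usable <- !is.na(scores)
  new_evaluation_result(
    "lodo", scores[usable], eng$labels[usable], n_folds = length(drugs),
    n_skipped = n_skipped,
    config = list(n_bins = n_bins, pseudocount = pseudocount,
                  selected_features = selected_full,
                  select_per_fold = select_per_fold,
                  n_unscorable = sum(!usable)))
}

#' Independent-test evaluation
#'
#' Trains one model on the training GSP/GSN, verifies that the test
#' positives (and, if `drugs_disjoint`, the test drugs) do not occur in
#' training, samples test negatives the same way the GSN was built —
#' excluding training GSP/GSN and the test positives — and pools scores
#' into one ROC/AUC.
#'
#' @param train_gsp,train_gsn training interaction sets.
#' @param test_pos test positive interaction set.
#' @param drug_sims,prot_sims similarity matrices.
#' @param drugs_disjoint require no test drug in training (ab initio test).
#' @param seed seed for test-negative sampling (independent of training).
#' @inheritParams loio_cv
#' @return an `evaluation_result`.
#' @export
independent_test <- function(train_gsp, train_gsn, test_pos, drug_sims,
                             prot_sims, drugs_disjoint = FALSE, seed = 1L,
                             n_bins = 20L, pseudocount = 1,
                             n_selected_features = 8L,
                             feature_subset = NULL) {
  overlap <- intersect(pair_keys(test_pos), pair_keys(train_gsp))
  if (length(overlap))
    stop("test positives present in training GSP: ",
         paste(gsub("\t", "/", overlap), collapse = ", "))
  if (drugs_disjoint) {
    shared <- intersect(unique(test_pos$compound_id),
                        unique(c(train_gsp$compound_id,
                                 train_gsn$compound_id)))
    if (length(shared))
      stop("test drugs occur in training: ", paste(shared, collapse = ", "))
  }
  model <- train_lr_model(train_gsp, train_gsn, drug_sims, prot_sims,
                          n_bins = n_bins, pseudocount = pseudocount,
                          n_selected_features = n_selected_features,
                          feature_subset = feature_subset, seed = seed)
  test_drugs <- sort(unique(test_pos$compound_id))
  test_prots <- sort(unique(test_pos$protein_id))
  all_pairs <- expand.grid(compound_id = test_drugs, protein_id = test_prots,
                           stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  forbidden <- c(pair_keys(test_pos), pair_keys(train_gsp),
                 pair_keys(train_gsn))
  pool <- all_pairs[!(pair_keys(all_pairs) %in% forbidden), , drop = FALSE]
  n_neg <- min(nrow(test_pos), nrow(pool))
  if (n_neg == 0L) stop("no candidate test negatives available")
  idx <- with_seed(seed, sample.int(nrow(pool), n_neg))
  test_neg <- pool[idx, , drop = FALSE]
  pairs <- rbind(as.data.frame(test_pos)[, c("compound_id", "protein_id")],
                 test_neg)
  labels <- c(rep(TRUE, nrow(test_pos)), rep(FALSE, n_neg))
  sc <- predict_scores(model, pairs, drug_sims, prot_sims)
  usable <- !is.na(sc)
  new_evaluation_result(
    "independent", sc[usable], labels[usable], n_folds = 1L, n_skipped = 0L,
    config = list(n_bins = n_bins, pseudocount = pseudocount,
                  selected_features = model$selected_features,
                  drugs_disjoint = drugs_disjoint, seed = seed,
                  n_unscorable = sum(!usable)))
}

#' Write an evaluation report (JSON summary + ROC points TSV)
#'
#' @param result an `evaluation_result`.
#' @param json_path,roc_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_evaluation_report <- function(result, json_path = NULL,
                                    roc_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(scheme = result$scheme, auc = result$auc,
           n_folds = result$n_folds, n_skipped = result$n_skipped,
           n_pos = sum(result$labels), n_neg = sum(!result$labels),
           config = result$config),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(roc_path)) {
    write.table(result$roc, roc_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(json = json_path, roc = roc_path))
}
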