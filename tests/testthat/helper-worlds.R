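# Small in-code fixtures shared across test files.

# Hand-built 2-drug / 2-protein world with one similarity measure per side.
tiny_world <- function() {
  ds <- sim_matrix(matrix(c(1, 0.8, 0.8, 1), 2,
                          dimnames = list(c("d1", "d2"), c("d1", "d2"))),
                   "fp2")
  ps <- sim_matrix(matrix(c(1, 0.5, 0.5, 1), 2,
                          dimnames = list(c("t1", "t2"), c("t1", "t2"))),
                   "sequence")
  gsp <- interaction_set(data.frame(compound_id = "d1", protein_id = "t1"))
  list(drug_sims = list(fp2 = ds), prot_sims = list(sequence = ps),
       gsp = gsp)
}

# Small planted-module universe for CV tests that need to stay fast.
small_universe <- function(seed = 7L) {
  generate_universe(universe_spec(n_drugs = 24L, n_proteins = 30L,
                                  n_modules = 3L, seed = seed))
}

# Naive leave-one-interaction-out reference implementation: per fold,
# rebuild the feature table and LR model from scratch. Quadratic; only for
# cross-checking the fast engine on small worlds.
naive_loio <- function(gsp, gsn, drug_sims, prot_sims, n_bins = 20L,
                       pseudocount = 1, selected = NULL) {
  pairs <- rbind(as.data.frame(gsp), as.data.frame(gsn))
  labels <- c(rep(TRUE, nrow(gsp)), rep(FALSE, nrow(gsn)))
  if (is.null(selected)) {
    ft_full <- build_feature_table(pairs, gsp, drug_sims, prot_sims)
    selected <- mrmr_select(ft_full, labels, k = 8L, n_bins = n_bins)
  }
  scores <- rep(NA_real_, nrow(pairs))
  for (h in seq_len(nrow(pairs))) {
    hold <- pairs[h, , drop = FALSE]
    gsp_f <- if (labels[h])
      interaction_set(gsp[pair_keys_test(gsp) != pair_keys_test(hold), ])
    else gsp
    gsn_f <- if (!labels[h])
      interaction_set(gsn[pair_keys_test(gsn) != pair_keys_test(hold), ],
                      role = "GSN")
    else gsn
    ft <- build_feature_table(pairs, gsp_f, drug_sims, prot_sims)
    model <- suppressWarnings(
      estimate_lr(ft, gsp_f, gsn_f, n_bins = n_bins,
                  pseudocount = pseudocount))
    model$selected_features <- intersect(selected, names(model$features))
    scores[h] <- herbtargets:::lr_scores(
      model, structure(ft[h, , drop = FALSE],
                       features = attr(ft, "features"),
                       class = class(ft)))
  }
  list(scores = scores, labels = labels)
}

pair_keys_test <- function(df) paste(df$compound_id, df$protein_id, sep = "\t")
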