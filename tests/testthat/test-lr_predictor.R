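# GSN sampling, LR estimation, mRMR, max-LR scoring, ranking, cutoff.

make_ft <- function(values, prefix = "f") {
  # wrap a named list of numeric vectors into a feature table with fake ids
  n <- length(values[[1]])
  df <- data.frame(compound_id = sprintf("c%04d", seq_len(n)),
                   protein_id = sprintf("p%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  structure(df, features = names(values),
            class = c("feature_table", "data.frame"))
}

split_sets <- function(ft, labels) {
  list(gsp = interaction_set(ft[labels, c("compound_id", "protein_id")]),
       gsn = interaction_set(ft[!labels, c("compound_id", "protein_id")],
                             role = "GSN"))
}

test_that("sample_gsn matches GSP size, avoids positives, is deterministic", {
  uni <- small_universe()
  gsn1 <- sample_gsn(uni$gsp, seed = 5)
  gsn2 <- sample_gsn(uni$gsp, seed = 5)
  expect_equal(nrow(gsn1), nrow(uni$gsp))
  expect_identical(as.data.frame(gsn1), as.data.frame(gsn2))
  for (s in 1:10) {
    g <- sample_gsn(uni$gsp, seed = s)
    expect_length(intersect(pair_keys_test(g), pair_keys_test(uni$gsp)), 0)
    expect_true(all(g$compound_id %in% uni$gsp$compound_id))
    expect_true(all(g$protein_id %in% uni$gsp$protein_id))
  }
  dense <- interaction_set(expand.grid(compound_id = c("a", "b"),
                                       protein_id = c("x", "y"),
                                       stringsAsFactors = FALSE))
  expect_error(sample_gsn(dense, seed = 1), "not enough")
})

test_that("estimate_lr reproduces frequency-ratio LRs and smoothing", {
  # bin frequencies 0.3 (GSP) vs 0.1 (GSN) with alpha = 0 -> LR 3
  centre <- function(b, B = 10) (b - 0.5) / B  # value in bin b of B
  pos <- c(rep(centre(1), 7), rep(centre(5), 3))
  neg <- c(rep(centre(1), 9), rep(centre(5), 1))
  ft <- make_ft(list(f1 = c(pos, neg)))
  ss <- split_sets(ft, c(rep(TRUE, 10), rep(FALSE, 10)))
  m <- estimate_lr(ft, ss$gsp, ss$gsn, n_bins = 10, pseudocount = 0)
  expect_equal(m$features$f1$lr[5], 3)
  expect_equal(m$features$f1$lr[1], 7 / 9)
  # empty GSN bin with alpha > 0 -> finite LR
  m2 <- estimate_lr(ft, ss$gsp, ss$gsn, n_bins = 20, pseudocount = 1)
  expect_true(all(is.finite(m2$features$f1$lr)))
  expect_true(all(m2$features$f1$lr >= 0))
  # all-missing feature dropped with warning
  ft2 <- make_ft(list(f1 = c(pos, neg), dead = rep(NA_real_, 20)))
  expect_warning(m3 <- estimate_lr(ft2, ss$gsp, ss$gsn), "dropped")
  expect_named(m3$features, "f1")
})

test_that("permuted labels drive every bin LR toward 1", {
  set.seed(31)
  x <- runif(2000)
  lab <- sample(c(rep(TRUE, 1000), rep(FALSE, 1000)))
  ft <- make_ft(list(f1 = x))
  ss <- split_sets(ft, lab)
  m <- estimate_lr(ft, ss$gsp, ss$gsn, n_bins = 20, pseudocount = 1)
  expect_true(all(m$features$f1$lr >= 0.5 & m$features$f1$lr <= 2))
})

test_that("mrmr_select defers redundant copies and matches marginal-MI order", {
  set.seed(8)
  n <- 400
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  strong <- ifelse(lab, rbeta(n, 5, 1), rbeta(n, 1, 5))
  weak <- ifelse(lab, rbeta(n, 2, 1), rbeta(n, 1, 2))
  ft <- make_ft(list(A = strong, A_copy = strong, B = weak))
  sel <- mrmr_select(ft, lab, k = 2)
  expect_equal(sel[1], "A")
  expect_equal(sel[2], "B")  # redundant copy deferred
  expect_equal(mrmr_select(make_ft(list(only = strong)), lab, k = 1), "only")
  expect_error(mrmr_select(ft, lab, k = 0), "k must be")
})

test_that("greedy MID matches the brute-force oracle on discrete features", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 200
    df <- data.frame(w = sample(0:1, n, TRUE), x = sample(0:1, n, TRUE),
                     y = sample(0:1, n, TRUE), z = sample(0:1, n, TRUE))
    lab <- as.integer((df$w + df$x + rbinom(n, 1, 0.2)) %% 2 == 0)
    # map 0/1 onto bin representatives so package discretization is identity
    ftvals <- lapply(df, function(v) ifelse(v == 1, 0.975, 0.025))
    ft <- make_ft(ftvals)
    expect_equal(mrmr_select(ft, lab, k = 4, n_bins = 20),
                 mrmr_oracle(df, lab, k = 4))
  }
})

test_that("max-LR scoring takes the max and ignores missing features", {
  # hand-built model: two features with constant known LR per bin
  model <- structure(list(
    features = list(
      f1 = list(edges = seq(0, 1, 0.5), lr = c(2, 5),
                pos_counts = c(1, 1), neg_counts = c(1, 1),
                n_pos = 2, n_neg = 2),
      f2 = list(edges = seq(0, 1, 0.5), lr = c(0.4, 1.2),
                pos_counts = c(1, 1), neg_counts = c(1, 1),
                n_pos = 2, n_neg = 2)),
    n_bins = 2L, pseudocount = 1, selected_features = c("f1", "f2")),
    class = "lr_model")
  ft <- make_ft(list(f1 = c(0.9, NA, NA), f2 = c(0.1, 0.1, NA)))
  sc <- herbtargets:::lr_scores(model, ft)
  expect_equal(sc[1], 5)      # max(5, 0.4)
  expect_equal(sc[2], 0.4)    # degenerate max on the only available feature
  expect_true(is.na(sc[3]))   # unscorable
  # invariance to feature order
  model2 <- model
  model2$selected_features <- c("f2", "f1")
  expect_equal(herbtargets:::lr_scores(model2, ft), sc)
})

test_that("train/predict round trip and structure-only restriction work", {
  uni <- small_universe()
  gsn <- sample_gsn(uni$gsp, seed = 2)
  model <- train_lr_model(uni$gsp, gsn, uni$drug_sims, uni$prot_sims,
                          seed = 2)
  expect_s3_class(model, "lr_model")
  expect_length(model$selected_features, 8)
  expect_true(all(model$selected_features %in% feature_grid()$feature))
  sc <- predict_scores(model, as.data.frame(gsn)[1:10, ], uni$drug_sims,
                       uni$prot_sims)
  expect_length(sc, 10)
  structure_feats <- c("fp2-closeness", "functional_group-sequence",
                       "functional_group-go")
  m2 <- train_lr_model(uni$gsp, gsn, uni$drug_sims, uni$prot_sims,
                       feature_subset = structure_feats, seed = 2)
  expect_true(all(names(m2$features) %in% structure_feats))
  expect_true(all(m2$selected_features %in% structure_feats))

  path <- withr::local_tempfile(fileext = ".json")
  write_lr_model(model, path)
  back <- read_lr_model(path)
  expect_equal(predict_scores(back, as.data.frame(gsn)[1:10, ],
                              uni$drug_sims, uni$prot_sims), sc)
})

test_that("rank_targets orders by score with lexicographic tie-break", {
  uni <- small_universe()
  gsn <- sample_gsn(uni$gsp, seed = 2)
  model <- train_lr_model(uni$gsp, gsn, uni$drug_sims, uni$prot_sims)
  rk <- rank_targets(uni$gsp$compound_id[1], uni$protein_ids, model,
                     uni$drug_sims, uni$prot_sims)
  expect_true(all(diff(rk$score) <= 1e-12))
  ties <- split(rk$protein_id, rk$score)
  for (grp in ties) expect_equal(grp, sort(grp))
  expect_false(any(rk$is_known))  # no known-target table supplied
  expect_error(rank_targets("NOT_A_DRUG", uni$protein_ids, model,
                            uni$drug_sims, uni$prot_sims),
               "absent from every drug similarity matrix")
  expect_error(rank_targets(uni$gsp$compound_id[1], character(0), model,
                            uni$drug_sims, uni$prot_sims), "empty")
})

test_that("apply_cutoff unions above-cutoff predictions with known targets", {
  ranked <- structure(
    data.frame(protein_id = c("t1", "t2", "t3"),
               score = c(3, 1.5, 0.2),
               is_known = c(FALSE, FALSE, TRUE)),
    class = c("ranked_targets", "data.frame"))
  out <- apply_cutoff(ranked, 2)
  expect_setequal(out$protein_id, c("t1", "t3"))  # t3 known, below cutoff
  expect_equal(nrow(apply_cutoff(ranked, 10)), 1)  # only the known target
  expect_equal(nrow(apply_cutoff(ranked, 0)), 3)
  no_known <- ranked; no_known$is_known <- FALSE
  expect_equal(nrow(apply_cutoff(no_known, 10)), 0)
})

test_that("training is deterministic given config and seed", {
  uni <- small_universe()
  gsn <- sample_gsn(uni$gsp, seed = 9)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_lr_model(train_lr_model(uni$gsp, gsn, uni$drug_sims, uni$prot_sims,
                                seed = 9), p1)
  write_lr_model(train_lr_model(uni$gsp, gsn, uni$drug_sims, uni$prot_sims,
                                seed = 9), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
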