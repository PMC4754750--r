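# Similarity measures and the max-similarity-product feature table.

test_that("tanimoto_similarity matches bit enumeration and edge cases", {
  expect_equal(tanimoto_similarity(c(1, 0, 1, 1), c(1, 0, 1, 1)), 1)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto_similarity(c(1, 0, 1, 1), c(0, 0, 1, 1)), 2 / 3)
  expect_warning(z <- tanimoto_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_error(tanimoto_similarity(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("functional_group_similarity is min/max sum on counts", {
  expect_equal(functional_group_similarity(c(2, 0, 1), c(2, 0, 1)), 1)
  expect_equal(functional_group_similarity(c(2, 0, 1), c(1, 1, 0)), 0.25)
  expect_warning(z <- functional_group_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_equal(suppressWarnings(
    functional_group_similarity(c(0, 0), c(3, 1))), 0)
})

test_that("set_similarity is Jaccard with empty-set missingness", {
  expect_equal(set_similarity(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(set_similarity(c("a", "b"), "c"), 0)
  expect_equal(set_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_true(is.na(set_similarity(character(0), character(0))))
})

test_that("atc_similarity counts matching leading levels, max over codes", {
  expect_equal(atc_similarity("C09AA02", "C09AA02"), 1)
  expect_equal(atc_similarity("C09AA02", "C09AA05"), 0.8)
  expect_equal(atc_similarity("C09AA02", "N02BA01"), 0)
  # max over cross pairs
  expect_equal(atc_similarity(c("N02BA01", "C09AA05"), "C09AA02"), 0.8)
  expect_true(is.na(atc_similarity(character(0), "C09AA02")))
  expect_error(atc_similarity("C09A", "C09AA02"), "invalid ATC")
})

test_that("expression_similarity rescales Pearson correlation", {
  sig <- c(0.3, -1.2, 2.4, 0.1)
  expect_equal(expression_similarity(sig, sig), 1)
  expect_equal(expression_similarity(sig, -sig), 0)
  # direct Pearson formula as oracle
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(expression_similarity(a, b), (r + 1) / 2)
  expect_equal(round(expression_similarity(a, b), 5), 0.99099)
  expect_true(is.na(expression_similarity(c(1, 1, 1), a)))
  expect_error(expression_similarity(c(1, 2), c(1, 2)), "length >= 3")
})

test_that("sequence_similarity is normalized Smith-Waterman", {
  expect_equal(sequence_similarity("HEAGAWGHEE", "HEAGAWGHEE"), 1)
  # regression value computed by the independent DP oracle:
  # SW = 17, self-scores 62 and 44
  expect_equal(sw_oracle("HEAGAWGHEE", "PAWHEAE"), 17)
  expect_equal(sequence_similarity("HEAGAWGHEE", "PAWHEAE"),
               17 / sqrt(62 * 44), tolerance = 1e-12)
  expect_true(is.na(sequence_similarity("", "PAWHEAE")))
  # no positive-scoring local alignment
  expect_equal(sequence_similarity("WWWW", "PPPP"), 0)
})

test_that("sequence_similarity agrees with the DP oracle on random pairs", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(42)
  for (i in 1:5) {
    a <- paste(sample(aa, sample(8:15, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:15, 1), TRUE), collapse = "")
    expected <- max(0, sw_oracle(a, b)) /
      sqrt(sw_oracle(a, a) * sw_oracle(b, b))
    expect_equal(sequence_similarity(a, b), min(1, expected),
                 tolerance = 1e-12, label = paste(a, b))
  }
})

test_that("network_closeness decays with shortest-path distance", {
  g <- igraph::make_graph(~ a - b, b - c)
  g <- igraph::add_vertices(g, 1, name = "z")
  expect_equal(network_closeness("a", "a", g), 1)
  expect_equal(network_closeness("a", "b", g), 0.5)
  expect_equal(network_closeness("a", "c", g), 0.25)
  expect_equal(network_closeness("a", "z", g), 0)  # disconnected
  expect_true(is.na(network_closeness("a", "missing", g)))
})

test_that("every measure is symmetric and bounded on random inputs", {
  set.seed(99)
  for (i in 1:20) {
    fa <- as.integer(runif(16) < 0.4); fb <- as.integer(runif(16) < 0.4)
    ga <- rpois(8, 1); gb <- rpois(8, 1)
    sa <- sample(letters, sample(1:6, 1)); sb <- sample(letters, sample(1:6, 1))
    ea <- rnorm(5); eb <- rnorm(5)
    vals <- c(suppressWarnings(tanimoto_similarity(fa, fb)),
              suppressWarnings(tanimoto_similarity(fb, fa)),
              suppressWarnings(functional_group_similarity(ga, gb)),
              suppressWarnings(functional_group_similarity(gb, ga)),
              set_similarity(sa, sb), set_similarity(sb, sa),
              expression_similarity(ea, eb), expression_similarity(eb, ea))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(vals[seq(1, 7, 2)], vals[seq(2, 8, 2)])
  }
})

test_that("compute_*_similarities honour availability and self-similarity", {
  recs <- generate_compound_records(n = 6, seed = 3)
  recs[[2]] <- compound_record("CID0002")  # nothing available
  sims <- compute_drug_similarities(recs)
  expect_setequal(names(sims),
                  c("fp2", "functional_group", "side_effect", "atc",
                    "expression"))
  for (m in names(sims)) {
    v <- unclass(sims[[m]])
    expect_true(all(is.na(v[2, ])), label = m)  # unavailable source
    fin <- v[!is.na(v)]
    expect_true(all(fin >= 0 & fin <= 1))
    expect_equal(v, t(v))
  }
  expect_equal(unclass(sims$fp2)[1, 1], 1)

  pr <- generate_protein_records(n = 5, seed = 3)
  psims <- compute_protein_similarities(pr$records, ppi = pr$ppi)
  expect_setequal(names(psims), c("sequence", "closeness", "go"))
  for (m in names(psims)) {
    v <- unclass(psims[[m]])
    expect_equal(v, t(v))
    fin <- v[!is.na(v)]
    expect_true(all(fin >= -1e-12 & fin <= 1 + 1e-12))
  }
  expect_equal(diag(unclass(psims$closeness)), setNames(rep(1, 5),
               rownames(psims$closeness)))
})

test_that("rescale_text_mining divides by the maximum and fixes diagonal", {
  m <- matrix(c(5, 2, 2, 5), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tm <- rescale_text_mining(m)
  expect_equal(unclass(tm)["a", "b"], 0.4)
  expect_equal(diag(unclass(tm)), c(a = 1, b = 1))
  expect_error(rescale_text_mining(matrix(0, 1, 1,
    dimnames = list("a", "a"))), "no positive")
})

test_that("sim_matrix validates symmetry and range", {
  expect_error(sim_matrix(matrix(c(1, 0.2, 0.4, 1), 2,
    dimnames = list(c("a", "b"), c("a", "b"))), "fp2"), "symmetric")
  expect_error(sim_matrix(matrix(c(1, 2, 2, 1), 2,
    dimnames = list(c("a", "b"), c("a", "b"))), "fp2"), "\\[0, 1\\]")
})

test_that("build_feature_table takes the max product over references", {
  w <- tiny_world()
  q <- data.frame(compound_id = "d2", protein_id = "t2")
  ft <- build_feature_table(q, w$gsp, w$drug_sims, w$prot_sims)
  expect_equal(ft[["fp2-sequence"]], 0.8 * 0.5)

  # self-exclusion: a lone GSP pair cannot score itself
  ft_self <- build_feature_table(as.data.frame(w$gsp), w$gsp, w$drug_sims,
                                 w$prot_sims)
  expect_true(is.na(ft_self[["fp2-sequence"]]))
  # with exclusion off it scores 1 (itself is the best reference)
  ft_leak <- build_feature_table(as.data.frame(w$gsp), w$gsp, w$drug_sims,
                                 w$prot_sims, exclude_policy = "none")
  expect_equal(ft_leak[["fp2-sequence"]], 1)

  # max over two reference pairs
  gsp2 <- interaction_set(data.frame(compound_id = c("d1", "d2"),
                                     protein_id = c("t1", "t1")))
  ds <- sim_matrix(matrix(c(1, 0.3, 0.6, 0.3, 1, 0.2, 0.6, 0.2, 1), 3,
    dimnames = list(c("d1", "d2", "d3"), c("d1", "d2", "d3"))), "fp2")
  q3 <- data.frame(compound_id = "d3", protein_id = "t2")
  ft2 <- build_feature_table(q3, gsp2, list(fp2 = ds), w$prot_sims)
  expect_equal(ft2[["fp2-sequence"]], max(0.6 * 0.5, 0.2 * 0.5))
})

test_that("feature table obeys bounds, monotonicity and empty-GSP error", {
  w <- tiny_world()
  expect_error(build_feature_table(data.frame(compound_id = "d2",
                                              protein_id = "t2"),
                                   w$gsp, w$drug_sims, w$prot_sims,
                                   exclude = w$gsp),
               "empty after exclusions")
  uni <- small_universe()
  pairs <- rbind(as.data.frame(uni$gsp)[1:20, ],
                 data.frame(compound_id = "D001", protein_id = "P030"))
  ft <- build_feature_table(pairs, uni$gsp, uni$drug_sims, uni$prot_sims)
  vals <- unlist(ft[feature_names(ft)])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  # adding a strictly better reference pair cannot lower any feature
  better <- interaction_set(rbind(as.data.frame(uni$gsp),
                                  data.frame(compound_id = "D001",
                                             protein_id = "P001")))
  ft2 <- build_feature_table(pairs, better, uni$drug_sims, uni$prot_sims)
  for (f in feature_names(ft)) {
    both <- !is.na(ft[[f]]) & !is.na(ft2[[f]])
    expect_true(all(ft2[[f]][both] >= ft[[f]][both] - 1e-12), label = f)
  }
})

test_that("feature tables round-trip through TSV", {
  w <- tiny_world()
  q <- data.frame(compound_id = c("d2", "d1"), protein_id = c("t2", "t2"))
  ft <- build_feature_table(q, w$gsp, w$drug_sims, w$prot_sims)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft))
  expect_equal(feature_names(back), feature_names(ft))
})
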