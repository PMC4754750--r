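# Max-similarity-product pair features.
#
# Feature (i, j) of a query pair (d, t) is the maximum over reference
# positives (d', t') of S_i(d, d') * S_j(t, t'): "how similar is this
# candidate interaction to the most similar known interaction", factored
# through one drug measure and one protein measure.

#' The drug-measure x protein-measure feature grid
#'
#' @param drug_measures,protein_measures measure names to cross.
#' @return data frame with columns `feature` (e.g. `"fp2-sequence"`),
#'   `drug_measure`, `protein_measure`.
#' @export
feature_grid <- function(drug_measures = DRUG_MEASURES,
                         protein_measures = PROTEIN_MEASURES) {
  g <- expand.grid(drug_measure = drug_measures,
                   protein_measure = protein_measures,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(match(g$drug_measure, DRUG_MEASURES),
               match(g$protein_measure, PROTEIN_MEASURES)), ]
  g$feature <- paste(g$drug_measure, g$protein_measure, sep = "-")
  rownames(g) <- NULL
  g[, c("feature", "drug_measure", "protein_measure")]
}

# Row-wise max ignoring NA; rows that are entirely NA give NA.
row_max_na <- function(m) {
  if (ncol(m) == 0L) return(rep(NA_real_, nrow(m)))
  do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j, drop = TRUE]),
                  list(na.rm = TRUE)))
}

# Per-feature query-vs-reference product matrices (n_pairs x n_refs).
# Entry [p, k] = S_drug(d_p, d'_k) * S_prot(t_p, t'_k); NA when either
# similarity is missing. Shared by build_feature_table and the CV engine.
pair_ref_products <- function(pairs, refs, drug_sims, prot_sims,
                              grid = NULL) {
  if (is.null(grid))
    grid <- feature_grid(names(drug_sims), names(prot_sims))
  out <- vector("list", nrow(grid))
  names(out) <- grid$feature
  for (f in seq_len(nrow(grid))) {
    Dm <- drug_sims[[grid$drug_measure[f]]]
    Pm <- prot_sims[[grid$protein_measure[f]]]
    Sd <- Dm[match(pairs$compound_id, rownames(Dm)),
             match(refs$compound_id, rownames(Dm)), drop = FALSE]
    Sp <- Pm[match(pairs$protein_id, rownames(Pm)),
             match(refs$protein_id, rownames(Pm)), drop = FALSE]
    out[[f]] <- unclass(Sd) * unclass(Sp)
  }
  out
}

#' Build the pair feature table
#'
#' For every query pair, computes each feature as the maximum
#' similarity-product against the reference positive set.  The query pair
#' itself is always removed from the reference set under the default
#' `"pair"` exclusion policy, so a training positive never scores itself;
#' `"drug"` / `"target"` additionally drop references sharing the query
#' drug / target, and `"none"` disables exclusion (used only to demonstrate
#' leakage in evaluation).
#'
#' @param pairs data frame with `compound_id`, `protein_id` columns.
#' @param gsp reference positive [interaction_set()].
#' @param drug_sims,prot_sims named lists of [sim_matrix] objects.
#' @param exclude optional interaction set removed from the references
#'   (e.g. a held-out cross-validation fold).
#' @param exclude_policy self-exclusion policy, see above.
#' @return a `feature_table`: data frame of pair ids plus one numeric
#'   column per feature (`NA` = missing).
#' @export
build_feature_table <- function(pairs, gsp, drug_sims, prot_sims,
                                exclude = NULL,
                                exclude_policy = c("pair", "drug", "target",
                                                   "none")) {
  exclude_policy <- match.arg(exclude_policy)
  pairs <- as.data.frame(pairs)[, c("compound_id", "protein_id")]
  refs <- as.data.frame(gsp)
  if (!is.null(exclude) && nrow(exclude)) {
    refs <- refs[!(pair_keys(refs) %in% pair_keys(exclude)), , drop = FALSE]
  }
  if (nrow(refs) == 0L)
    stop("reference positive set is empty after exclusions")
  grid <- feature_grid(names(drug_sims), names(prot_sims))
  prods <- pair_ref_products(pairs, refs, drug_sims, prot_sims, grid)
  out <- pairs
  refkey <- pair_keys(refs)
  pkey <- pair_keys(pairs)
  for (f in grid$feature) {
    m <- prods[[f]]
    if (exclude_policy == "pair") {
      hit <- match(pkey, refkey)
      has <- which(!is.na(hit))
      m[cbind(has, hit[has])] <- NA_real_
    } else if (exclude_policy == "drug") {
      drop <- outer(pairs$compound_id, refs$compound_id, `==`) |
        outer(pkey, refkey, `==`)
      m[drop] <- NA_real_
    } else if (exclude_policy == "target") {
      drop <- outer(pairs$protein_id, refs$protein_id, `==`) |
        outer(pkey, refkey, `==`)
      m[drop] <- NA_real_
    }
    out[[f]] <- row_max_na(m)
  }
  structure(out, features = grid$feature,
            class = c("feature_table", "data.frame"))
}

feature_names <- function(ft) attr(ft, "features")

#' Write / read a feature table as TSV
#'
#' @param ft a feature table from [build_feature_table()].
#' @param path file path.
#' @return `read_feature_table` returns the feature table; the writer
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(ft, path) {
  write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  df$compound_id <- as.character(df$compound_id)
  df$protein_id <- as.character(df$protein_id)
  structure(df, features = setdiff(names(df), c("compound_id", "protein_id")),
            class = c("feature_table", "data.frame"))
}
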