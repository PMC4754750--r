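# Pairwise similarity measures and the sim_matrix container.
#
# All measures return values in [0, 1], are symmetric, and use NA (never 0)
# for "no data": absence of evidence is not evidence of dissimilarity.

DRUG_MEASURES <- c("fp2", "functional_group", "side_effect", "atc",
                   "expression", "text_mining")
PROTEIN_MEASURES <- c("sequence", "closeness", "go")

#' Tanimoto similarity of two bit fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|} over equal-length 0/1 vectors (FP2
#' convention).  If both fingerprints are all-zero there is no shared
#' chemistry evidence and the score is defined as 0, with a warning.
#'
#' @param fp_a,fp_b numeric/integer/logical vectors of equal length containing
#'   only 0 and 1.
#' @return a score in \[0, 1\].
#' @export
#' @examples
#' tanimoto_similarity(c(1, 0, 1, 1), c(0, 0, 1, 1))  # 2/3
tanimoto_similarity <- function(fp_a, fp_b) {
  fp_a <- as.logical(fp_a); fp_b <- as.logical(fp_b)
  if (length(fp_a) != length(fp_b))
    stop("fingerprints must have equal length (", length(fp_a), " vs ",
         length(fp_b), ")")
  u <- sum(fp_a | fp_b)
  if (u == 0L) {
    warning("both fingerprints all-zero; Tanimoto defined as 0")
    return(0)
  }
  sum(fp_a & fp_b) / u
}

#' Weighted Tanimoto similarity of functional-group count vectors
#'
#' \eqn{\sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)} over non-negative
#' count vectors on a shared group vocabulary.
#'
#' @param g_a,g_b non-negative integer count vectors of equal length.
#' @return a score in \[0, 1\].
#' @export
functional_group_similarity <- function(g_a, g_b) {
  if (length(g_a) != length(g_b))
    stop("count vectors must share the vocabulary length")
  if (any(g_a < 0) || any(g_b < 0)) stop("counts must be non-negative")
  denom <- sum(pmax(g_a, g_b))
  if (denom == 0) {
    warning("both count vectors all-zero; similarity defined as 0")
    return(0)
  }
  sum(pmin(g_a, g_b)) / denom
}

#' Jaccard similarity of two term sets
#'
#' Used for side-effect terms and for GO annotation sets.  Two empty sets
#' carry no information, so the result is `NA` (missing), not 0.
#'
#' @param s_a,s_b character vectors treated as sets.
#' @return a score in \[0, 1\], or `NA` if both sets are empty.
#' @export
set_similarity <- function(s_a, s_b) {
  s_a <- unique(s_a); s_b <- unique(s_b)
  if (length(s_a) == 0L && length(s_b) == 0L) return(NA_real_)
  length(intersect(s_a, s_b)) / length(union(s_a, s_b))
}

# One ATC code splits into 5 levels: A | 10 | B | A | 07.
atc_levels <- function(code) {
  c(substr(code, 1, 1), substr(code, 2, 3), substr(code, 4, 4),
    substr(code, 5, 5), substr(code, 6, 7))
}

#' ATC therapeutic similarity
#'
#' For each cross pair of codes, the number of matching leading ATC levels
#' (anatomical, therapeutic, pharmacological, chemical subgroup, substance;
#' 0-5) divided by 5; the drug-level score is the maximum over all code
#' pairs.  Either set empty gives `NA`.
#'
#' @param codes_a,codes_b character vectors of 7-character ATC codes
#'   (pattern: letter, 2 digits, letter, letter, 2 digits).
#' @return a score in \{0, .2, .4, .6, .8, 1\}, or `NA`.
#' @export
atc_similarity <- function(codes_a, codes_b) {
  if (length(codes_a) == 0L || length(codes_b) == 0L) return(NA_real_)
  ok <- grepl("^[A-Za-z][0-9]{2}[A-Za-z]{2}[0-9]{2}$", c(codes_a, codes_b))
  if (!all(ok))
    stop("invalid ATC code(s): ",
         paste(c(codes_a, codes_b)[!ok], collapse = ", "))
  best <- 0L
  for (a in codes_a) {
    la <- atc_levels(a)
    for (b in codes_b) {
      lb <- atc_levels(b)
      m <- match(FALSE, la == lb, nomatch = 6L) - 1L  # leading matches
      if (m > best) best <- m
      if (best == 5L) return(1)
    }
  }
  best / 5
}

#' Expression-signature similarity
#'
#' Pearson correlation of two per-gene drug-response signatures, rescaled
#' from \[-1, 1\] into \[0, 1\] as \eqn{(r + 1)/2}.  Constant vectors have
#' undefined correlation and return `NA`.
#'
#' @param sig_a,sig_b real vectors of equal length (>= 3).
#' @return a score in \[0, 1\], or `NA`.
#' @export
expression_similarity <- function(sig_a, sig_b) {
  if (length(sig_a) != length(sig_b)) stop("signatures must have equal length")
  if (length(sig_a) < 3L) stop("signatures must have length >= 3")
  if (stats::sd(sig_a) == 0 || stats::sd(sig_b) == 0) return(NA_real_)
  (stats::cor(sig_a, sig_b) + 1) / 2
}

# BLOSUM62 loaded once per session from Biostrings.
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

sw_score <- function(a, b, gap_open = 10, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

#' Normalized Smith-Waterman sequence similarity
#'
#' \eqn{SW(a,b) / \sqrt{SW(a,a)\,SW(b,b)}} with local alignment under
#' BLOSUM62, gap opening 10, gap extension 1.  Self-similarity is exactly 1;
#' sequence pairs with no positive-scoring local alignment score 0.
#' Empty sequences give `NA`.
#'
#' @param seq_a,seq_b amino-acid strings (20-letter alphabet plus X).
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return a score in \[0, 1\], or `NA`.
#' @export
sequence_similarity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 1) {
  if (is.na(seq_a) || is.na(seq_b) || nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    return(NA_real_)
  saa <- sw_score(seq_a, seq_a, gap_open, gap_extend)
  sbb <- sw_score(seq_b, seq_b, gap_open, gap_extend)
  if (saa <= 0 || sbb <= 0) return(NA_real_)  # degenerate self-alignment
  sab <- sw_score(seq_a, seq_b, gap_open, gap_extend)
  max(0, min(1, sab / sqrt(saa * sbb)))
}

#' Protein-interaction-network closeness
#'
#' \eqn{decay^d} for unweighted shortest-path distance \eqn{d} between two
#' proteins in an undirected interaction network, with \eqn{d = 0} (self)
#' mapping to 1 and disconnected pairs to 0.
#'
#' @param prot_a,prot_b protein ids (vertex names).
#' @param ppi an undirected [igraph::igraph] with named vertices.
#' @param decay per-step decay factor in (0, 1); default 0.5.
#' @return a score in \[0, 1\], or `NA` if a protein is absent from the graph.
#' @export
network_closeness <- function(prot_a, prot_b, ppi, decay = 0.5) {
  vn <- igraph::V(ppi)$name
  if (!(prot_a %in% vn) || !(prot_b %in% vn)) return(NA_real_)
  if (prot_a == prot_b) return(1)
  d <- igraph::distances(ppi, v = prot_a, to = prot_b)[1, 1]
  if (is.infinite(d)) return(0)
  decay^d
}

#' Construct a similarity matrix container
#'
#' A `sim_matrix` is a dense symmetric numeric matrix of scores in \[0, 1\]
#' with entity ids as dimnames, `NA` marking missing entries (entity lacks
#' the source data) and a measure name attribute.
#'
#' @param values symmetric numeric matrix, scores in \[0, 1\] or `NA`.
#' @param measure measure name, e.g. `"fp2"` or `"sequence"`.
#' @param entity_ids optional ids; defaults to `rownames(values)`.
#' @return a `sim_matrix` object.
#' @export
sim_matrix <- function(values, measure, entity_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(entity_ids)) stop("entity ids required")
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  dimnames(values) <- list(entity_ids, entity_ids)
  fin <- values[!is.na(values)]
  if (length(fin) && (min(fin) < -1e-9 || max(fin) > 1 + 1e-9))
    stop("similarity values must lie in [0, 1] (measure ", measure, ")")
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE,
                        tolerance = 1e-8)))
    stop("similarity matrix must be symmetric (measure ", measure, ")")
  structure(values, measure = attr_chr(measure), class = c("sim_matrix", "matrix"))
}

attr_chr <- function(x) as.character(x)[1]

#' @export
print.sim_matrix <- function(x, ...) {
  cat("<sim_matrix> measure=", attr(x, "measure"), ", ", nrow(x),
      " entities, ", sum(is.na(x)), " missing entries\n", sep = "")
  invisible(x)
}

# Look up sim(id_a, id_b) in a sim_matrix; NA when either id is absent.
sim_lookup <- function(sm, ids_a, ids_b) {
  ia <- match(ids_a, rownames(sm)); ib <- match(ids_b, rownames(sm))
  out <- rep(NA_real_, length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- sm[cbind(ia[ok], ib[ok])]
  out
}

# Build a sim_matrix by applying a pairwise function over records.
pairwise_sim_matrix <- function(ids, fun, measure) {
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- suppressWarnings(fun(i, j))
      m[i, j] <- v; m[j, i] <- v
    }
  }
  sim_matrix(m, measure)
}

#' Compute drug-drug similarity matrices from compound records
#'
#' Computes the structure (FP2 Tanimoto and functional-group weighted
#' Tanimoto), side-effect (Jaccard), ATC (level-prefix), and expression
#' (rescaled Pearson) measures from raw per-compound data.  Text-mining
#' similarity is ingestion-only (see [read_sim_matrix()] and
#' [rescale_text_mining()]) because it is distributed precomputed.
#'
#' @param records a list of compound records as built by [compound_record()].
#' @param measures subset of the computable drug measures.
#' @return named list of [sim_matrix] objects.
#' @export
compute_drug_similarities <- function(records,
                                      measures = setdiff(DRUG_MEASURES,
                                                         "text_mining")) {
  ids <- vapply(records, `[[`, "", "compound_id")
  if (anyDuplicated(ids)) stop("duplicate compound ids")
  measures <- match.arg(measures, setdiff(DRUG_MEASURES, "text_mining"),
                        several.ok = TRUE)
  out <- list()
  has <- function(field) vapply(records, function(r) isTRUE(r$availability[[field]]),
                                logical(1))
  if ("fp2" %in% measures) {
    av <- has("fingerprint")
    out$fp2 <- pairwise_sim_matrix(ids, function(i, j) {
      if (!av[i] || !av[j]) return(NA_real_)
      tanimoto_similarity(records[[i]]$fingerprint, records[[j]]$fingerprint)
    }, "fp2")
  }
  if ("functional_group" %in% measures) {
    av <- has("functional_groups")
    out$functional_group <- pairwise_sim_matrix(ids, function(i, j) {
      if (!av[i] || !av[j]) return(NA_real_)
      functional_group_similarity(records[[i]]$functional_groups,
                                  records[[j]]$functional_groups)
    }, "functional_group")
  }
  if ("side_effect" %in% measures) {
    av <- has("side_effects")
    out$side_effect <- pairwise_sim_matrix(ids, function(i, j) {
      if (!av[i] || !av[j]) return(NA_real_)
      set_similarity(records[[i]]$side_effects, records[[j]]$side_effects)
    }, "side_effect")
  }
  if ("atc" %in% measures) {
    av <- has("atc_codes")
    out$atc <- pairwise_sim_matrix(ids, function(i, j) {
      if (!av[i] || !av[j]) return(NA_real_)
      atc_similarity(records[[i]]$atc_codes, records[[j]]$atc_codes)
    }, "atc")
  }
  if ("expression" %in% measures) {
    av <- has("expression_signature")
    out$expression <- pairwise_sim_matrix(ids, function(i, j) {
      if (!av[i] || !av[j]) return(NA_real_)
      expression_similarity(records[[i]]$expression_signature,
                            records[[j]]$expression_signature)
    }, "expression")
  }
  out
}

#' Compute protein-protein similarity matrices from protein records
#'
#' @param records list of protein records from [protein_record()].
#' @param ppi optional undirected igraph for the closeness measure.
#' @param measures subset of `c("sequence", "closeness", "go")`.
#' @param decay closeness decay per network step.
#' @return named list of [sim_matrix] objects.
#' @export
compute_protein_similarities <- function(records, ppi = NULL,
                                         measures = PROTEIN_MEASURES,
                                         decay = 0.5) {
  ids <- vapply(records, `[[`, "", "protein_id")
  if (anyDuplicated(ids)) stop("duplicate protein ids")
  measures <- match.arg(measures, PROTEIN_MEASURES, several.ok = TRUE)
  out <- list()
  if ("sequence" %in% measures) {
    out$sequence <- pairwise_sim_matrix(ids, function(i, j) {
      sequence_similarity(records[[i]]$sequence %||% NA_character_,
                          records[[j]]$sequence %||% NA_character_)
    }, "sequence")
  }
  if ("closeness" %in% measures) {
    if (is.null(ppi)) stop("closeness measure requires a PPI graph")
    # one distance matrix call instead of per-pair BFS
    vn <- intersect(ids, igraph::V(ppi)$name)
    dmat <- if (length(vn)) igraph::distances(ppi, v = vn, to = vn) else
      matrix(0, 0, 0)
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    if (length(vn)) {
      s <- decay^dmat
      s[is.infinite(dmat)] <- 0
      diag(s) <- 1
      m[vn, vn] <- s
    }
    out$closeness <- sim_matrix(m, "closeness")
  }
  if ("go" %in% measures) {
    ann <- lapply(records, `[[`, "go_terms")
    out$go <- pairwise_sim_matrix(ids, function(i, j) {
      if (length(ann[[i]]) == 0L || length(ann[[j]]) == 0L) return(NA_real_)
      set_similarity(ann[[i]], ann[[j]])
    }, "go")
  }
  out
}

#' Rescale a precomputed text-mining association matrix into \[0, 1\]
#'
#' Text-mining (literature co-occurrence) chemical-chemical association
#' scores arrive precomputed on an arbitrary positive scale; they are
#' normalized by the matrix maximum, with the diagonal forced to 1 for
#' entities having any data.
#'
#' @param values square numeric matrix with dimnames (raw scores >= 0).
#' @return a [sim_matrix] with measure `"text_mining"`.
#' @export
rescale_text_mining <- function(values) {
  values <- as.matrix(values)
  mx <- max(values, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("text-mining matrix has no positive score")
  v <- values / mx
  diag(v)[!is.na(diag(v))] <- 1
  sim_matrix(v, "text_mining")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
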