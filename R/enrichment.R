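# Hypergeometric enrichment of target sets, BH correction, and the
# reverse (term -> formulas) index.

#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for the number of successes when drawing `n` items
#' without replacement from a universe of `N` items of which `K` belong to
#' the term.  Evaluated in log space for numerical stability.
#'
#' @param k observed overlap (targets mapped to the term).
#' @param K term size.
#' @param n target-set size (within the universe).
#' @param N universe size.
#' @return the p-value \eqn{P(X \ge k)} in (0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(is.na(c(k, K, n, N))) || k < 0 || K < 0 || n < 0 || N < 0 ||
      k > min(n, K) || K > N || n > N)
    stop("invalid hypergeometric parameters: k=", k, " K=", K, " n=", n,
         " N=", N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p ascending, takes \eqn{\tilde p_{(i)} = \min_{j \ge i}
#' p_{(j)} m / j} capped at 1, and returns the values in input order.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  adj <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Construct a gene-set collection
#'
#' @param sets named list: term id -> character vector of member genes.
#' @param category one of pathway, go_bp, go_mf, go_cc, disease.
#' @param names optional named character vector of term descriptions.
#' @param universe background gene universe; default: the union of all
#'   member sets (self-consistent, download-free).
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category = c("pathway", "go_bp",
                                                   "go_mf", "go_cc",
                                                   "disease"),
                                names = NULL, universe = NULL) {
  category <- match.arg(category)
  if (!length(sets) || is.null(base::names(sets)))
    stop("sets must be a non-empty named list")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(!lengths(sets))) stop("member sets must be non-empty")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  universe <- unique(as.character(universe))
  outside <- setdiff(unlist(sets), universe)
  if (length(outside))
    stop("term members outside the supplied universe: ",
         paste(head(outside, 5), collapse = ", "))
  structure(list(category = category, sets = sets,
                 names = names %||%
                   setNames(base::names(sets), base::names(sets)),
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> category=", x$category, ", ", length(x$sets),
      " terms, universe of ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Hypergeometric enrichment of a target set
#'
#' Tests every term with at least one mapped target against the
#' collection's background universe, applies Benjamini-Hochberg across the
#' tested terms of this category, and sorts by adjusted p then term id.
#' Targets are de-duplicated and intersected with the universe first.
#'
#' @param targets character vector of target gene ids.
#' @param collection a [gene_set_collection()].
#' @param p_adj_cutoff significance flag threshold on the adjusted p
#'   (user-adjustable; default 0.05).
#' @return data frame with columns `term_id`, `term_name`, `category`,
#'   `k`, `K`, `n`, `N`, `p_raw`, `p_adjusted`, `significant`,
#'   `mapped_targets` (comma-joined gene list).
#' @export
enrich <- function(targets, collection, p_adj_cutoff = 0.05) {
  targets <- unique(as.character(targets))
  targets <- intersect(targets, collection$universe)
  if (!length(targets))
    stop("no target maps into the ", collection$category,
         " universe: id-space mismatch?")
  N <- length(collection$universe)
  n <- length(targets)
  rows <- lapply(base::names(collection$sets), function(tid) {
    members <- collection$sets[[tid]]
    mapped <- sort(intersect(targets, members))
    k <- length(mapped)
    if (k == 0L) return(NULL)  # untested: does not inflate m
    data.frame(term_id = tid,
               term_name = unname(collection$names[tid]),
               category = collection$category,
               k = k, K = length(members), n = n, N = N,
               p_raw = hypergeom_upper_tail(k, length(members), n, N),
               mapped_targets = paste(mapped, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(structure(data.frame(term_id = character(0),
                                term_name = character(0),
                                category = character(0), k = integer(0),
                                K = integer(0), n = integer(0),
                                N = integer(0), p_raw = numeric(0),
                                p_adjusted = numeric(0),
                                significant = logical(0),
                                mapped_targets = character(0)),
                     p_adj_cutoff = p_adj_cutoff))
  rows$p_adjusted <- bh_adjust(rows$p_raw)
  rows$significant <- rows$p_adjusted <= p_adj_cutoff
  rows <- rows[order(rows$p_adjusted, rows$term_id), ]
  rownames(rows) <- NULL
  rows <- rows[, c("term_id", "term_name", "category", "k", "K", "n", "N",
                   "p_raw", "p_adjusted", "significant", "mapped_targets")]
  structure(rows, p_adj_cutoff = p_adj_cutoff)
}

#' Reverse index: enriched term -> formulas/herbs
#'
#' Inverts a named list of enrichment outputs (one per formula/herb/TCM
#' query) into a map from term id to the queries for which the term passed
#' that analysis's significance cutoff, best adjusted p first.
#'
#' @param analyses named list of [enrich()] outputs; names are the
#'   formula/herb identifiers (must be unique).
#' @return named list: term id -> data frame (`tcm`, `p_adjusted`,
#'   `term_name`, `category`).
#' @export
function2tcm_index <- function(analyses) {
  if (!length(analyses)) stop("need at least one analysis")
  nms <- base::names(analyses)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop("analyses must have unique non-empty names (they are index keys)")
  entries <- do.call(rbind, lapply(nms, function(nm) {
    df <- as.data.frame(analyses[[nm]])
    df <- df[df$significant, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    data.frame(term_id = df$term_id, term_name = df$term_name,
               category = df$category, tcm = nm,
               p_adjusted = df$p_adjusted, stringsAsFactors = FALSE)
  }))
  if (is.null(entries)) return(structure(list(), names = character(0)))
  out <- lapply(split(entries, entries$term_id), function(g) {
    g <- g[order(g$p_adjusted, g$tcm), c("tcm", "p_adjusted", "term_name",
                                         "category")]
    rownames(g) <- NULL
    g
  })
  out[order(base::names(out))]
}
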