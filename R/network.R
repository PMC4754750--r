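# Ingredient-target-pathway/disease association network assembly, the
# paper-style filters (min linking compounds, simplified view), exports,
# and multi-cluster Venn comparison.

#' Assemble the association network
#'
#' Builds a typed graph with ingredient, target, pathway and disease nodes.
#' Edges: ingredient-target (from the per-ingredient potential-target
#' lists), target-pathway and target-disease (from enrichment results'
#' mapped targets).  Targets with `min_compounds_M` or fewer linking
#' compounds are removed (strictly "more than M" are kept); in the
#' simplified view only pathway/disease terms with adjusted p at or below
#' `p_adj_cutoff` appear.  Degrees (target: number of compounds acting on
#' it; pathway/disease: number of targets mapped to it) are recomputed
#' after filtering, and pathway/disease nodes with no remaining target are
#' dropped, so no orphans remain.  Node ordering is deterministic
#' (type, then id).
#'
#' @param ingredient_targets named list: ingredient id -> character vector
#'   of its potential targets (output of [apply_cutoff()]).
#' @param enrichments list of [enrich()] outputs (pathway and/or disease
#'   categories; GO categories are accepted and typed as pathway nodes).
#' @param min_compounds_M keep only targets with more than M linking
#'   compounds (default 0 = keep all).
#' @param simplified restrict pathway/disease nodes to significant terms.
#' @param p_adj_cutoff cutoff used by the simplified view.
#' @param clusters optional named list: cluster name -> ingredient ids,
#'   recorded as a categorical `clusters` node attribute.
#' @return an [igraph::igraph] with vertex attributes `type`, `degree`,
#'   `clusters`, `p_adjusted` (terms only) and edge attribute `edge_type`.
#' @export
assemble_network <- function(ingredient_targets, enrichments = list(),
                             min_compounds_M = 0L, simplified = FALSE,
                             p_adj_cutoff = 0.05, clusters = NULL) {
  if (min_compounds_M < 0) stop("min_compounds_M must be >= 0")
  if (!length(ingredient_targets)) stop("no ingredient target lists supplied")
  # an ingredient listed in several clusters contributes one merged node
  nm <- names(ingredient_targets)
  ingredient_targets <- lapply(split(seq_along(nm), nm), function(ix)
    unique(unlist(ingredient_targets[ix], use.names = FALSE)))
  it <- do.call(rbind, lapply(names(ingredient_targets), function(i) {
    tg <- unique(as.character(ingredient_targets[[i]]))
    if (!length(tg)) return(NULL)
    data.frame(from = i, to = tg, stringsAsFactors = FALSE)
  }))
  if (is.null(it)) it <- data.frame(from = character(0), to = character(0))
  # target filter: strictly more than M linking compounds
  n_comp <- tapply(it$from, it$to, function(x) length(unique(x)))
  keep_targets <- names(n_comp)[n_comp > min_compounds_M]
  it <- it[it$to %in% keep_targets, , drop = FALSE]

  term_rows <- do.call(rbind, lapply(enrichments, function(e) {
    df <- as.data.frame(e)
    if (!nrow(df)) return(NULL)
    if (simplified) df <- df[df$p_adjusted <= p_adj_cutoff, , drop = FALSE]
    df
  }))
  te <- NULL
  term_attr <- NULL
  if (!is.null(term_rows) && nrow(term_rows)) {
    term_rows$node_type <- ifelse(term_rows$category == "disease",
                                  "disease", "pathway")
    te <- do.call(rbind, lapply(seq_len(nrow(term_rows)), function(r) {
      mapped <- strsplit(term_rows$mapped_targets[r], ",", fixed = TRUE)[[1]]
      mapped <- intersect(mapped, keep_targets)
      if (!length(mapped)) return(NULL)
      data.frame(from = mapped, to = term_rows$term_id[r],
                 edge_type = paste0("target-", term_rows$node_type[r]),
                 stringsAsFactors = FALSE)
    }))
    term_attr <- unique(term_rows[, c("term_id", "node_type", "p_adjusted")])
  }

  edges <- rbind(
    if (nrow(it)) data.frame(from = it$from, to = it$to,
                             edge_type = "ingredient-target",
                             stringsAsFactors = FALSE),
    te)
  ing_ids <- sort(names(ingredient_targets))
  tgt_ids <- sort(unique(it$to))
  term_ids <- if (is.null(te)) character(0) else sort(unique(te$to))
  vtype <- c(setNames(rep("ingredient", length(ing_ids)), ing_ids),
             setNames(rep("target", length(tgt_ids)), tgt_ids),
             if (length(term_ids))
               setNames(term_attr$node_type[match(term_ids,
                                                  term_attr$term_id)],
                        term_ids))
  vids <- names(vtype)
  ord <- order(match(vtype, c("ingredient", "target", "pathway", "disease")),
               vids)
  vids <- vids[ord]; vtype <- vtype[ord]
  g <- igraph::make_empty_graph(n = length(vids), directed = FALSE)
  igraph::V(g)$name <- vids
  igraph::V(g)$type <- unname(vtype)
  if (!is.null(edges) && nrow(edges)) {
    edges <- edges[order(edges$edge_type, edges$from, edges$to), ]
    g <- igraph::add_edges(g, rbind(match(edges$from, vids),
                                    match(edges$to, vids)))
    igraph::E(g)$edge_type <- edges$edge_type
  }
  # degree of the defining kind, computed on the filtered graph
  deg <- integer(length(vids))
  for (i in seq_along(vids)) {
    v <- vids[i]
    deg[i] <- switch(vtype[i],
      ingredient = if (nrow(it)) length(unique(it$to[it$from == v])) else 0L,
      target = if (nrow(it)) length(unique(it$from[it$to == v])) else 0L,
      length(unique(te$from[te$to == v])))
  }
  igraph::V(g)$degree <- deg
  pa <- rep(NA_real_, length(vids))
  if (length(term_ids)) {
    idx <- match(term_attr$term_id, vids)  # NA for orphaned (dropped) terms
    pa[idx[!is.na(idx)]] <- term_attr$p_adjusted[!is.na(idx)]
  }
  igraph::V(g)$p_adjusted <- pa
  cl <- rep("", length(vids))
  if (!is.null(clusters)) {
    for (i in seq_along(vids)) {
      if (vtype[i] == "ingredient") {
        hit <- names(clusters)[vapply(clusters, function(m) vids[i] %in% m,
                                      logical(1))]
      } else if (vtype[i] == "target") {
        hit <- names(clusters)[vapply(names(clusters), function(cn) {
          any(vids[i] %in% unlist(ingredient_targets[
            intersect(clusters[[cn]], names(ingredient_targets))]))
        }, logical(1))]
      } else hit <- character(0)
      cl[i] <- paste(sort(hit), collapse = ",")
    }
  }
  igraph::V(g)$clusters <- cl
  g
}

#' Compare target sets of multiple clusters (Venn partition)
#'
#' Produces the full \eqn{2^c - 1} region partition of 2-5 cluster target
#' sets: for every non-empty cluster subset, the targets belonging to
#' exactly those clusters.
#'
#' @param cluster_targets named list (2-5 entries): cluster name ->
#'   character vector of target ids.
#' @return a `cluster_comparison`: data frame with columns `region`
#'   (cluster names joined by `&`), `n_clusters`, `size`, `members`
#'   (comma-joined ids).
#' @export
compare_clusters <- function(cluster_targets) {
  cn <- names(cluster_targets)
  if (length(cluster_targets) < 2L || is.null(cn) || anyDuplicated(cn))
    stop("need 2 or more uniquely named clusters")
  if (length(cluster_targets) > 5L)
    stop("more than 5 clusters: the full Venn partition is intractable; ",
         "compare pairwise instead")
  sets <- lapply(cluster_targets, function(x) unique(as.character(x)))
  all_ids <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_ids %in% s,
                       logical(length(all_ids)))
  if (length(all_ids) == 1L) membership <- matrix(membership, nrow = 1L)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(cn)))[-1, ,
                                                                drop = FALSE]
  rows <- lapply(seq_len(nrow(subsets)), function(r) {
    mask <- as.logical(subsets[r, ])
    in_region <- if (length(all_ids))
      apply(membership, 1, function(m) all(m == mask)) else logical(0)
    ids <- all_ids[in_region]
    data.frame(region = paste(cn[mask], collapse = "&"),
               n_clusters = sum(mask), size = length(ids),
               members = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_clusters, out$region), ]
  rownames(out) <- NULL
  structure(out, class = c("cluster_comparison", "data.frame"))
}

#' Export an association network
#'
#' Writes the graph losslessly (nodes, types, attributes) with stable
#' element ordering so outputs are diffable.  Formats: `"graphml"`
#' (igraph), `"node-link-json"` (a JSON document with `nodes` and `links`
#' arrays), `"edge-tsv"` (source, target, edge type, source/target types).
#'
#' @param net an [assemble_network()] result.
#' @param path output file path.
#' @param format one of `"graphml"`, `"node-link-json"`, `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "node-link-json",
                                                 "edge-tsv")) {
  if (!format[1] %in% c("graphml", "node-link-json", "edge-tsv"))
    stop("unknown format '", format[1],
         "'; supported: graphml, node-link-json, edge-tsv")
  format <- match.arg(format)
  el <- igraph::as_data_frame(net, what = "edges")
  vt <- igraph::as_data_frame(net, what = "vertices")
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else if (format == "node-link-json") {
    jsonlite::write_json(
      list(directed = FALSE, nodes = vt,
           links = el[, c("from", "to",
                          setdiff(names(el), c("from", "to")))]),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  } else {
    tt <- setNames(vt$type, vt$name)
    out <- data.frame(source = el$from, target = el$to,
                      edge_type = if (nrow(el)) el$edge_type else character(0),
                      source_type = unname(tt[el$from]),
                      target_type = unname(tt[el$to]),
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a GraphML network (round trip of [export_network()])
#'
#' @param path a GraphML file.
#' @return an igraph.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
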