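# Readers/writers for the plain-text interchange formats: similarity-matrix
# TSV, interaction TSV, GMT gene sets, PPI edge lists, FASTA, fingerprint
# and term-membership tables.

#' Read / write a similarity matrix TSV
#'
#' Format: header row of entity ids, first column of entity ids, numeric
#' cells with `NA` for missing entries.
#'
#' @param path file path.
#' @param measure measure name attached to the matrix.
#' @return `read_sim_matrix` returns a [sim_matrix()].
#' @export
read_sim_matrix <- function(path, measure) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  storage.mode(m) <- "double"
  sim_matrix(m, measure)
}

#' @rdname read_sim_matrix
#' @param sm a [sim_matrix()].
#' @export
write_sim_matrix <- function(sm, path) {
  df <- data.frame(id = rownames(sm), unclass(sm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write an interaction table (TSV: compound_id, protein_id)
#'
#' @param path file path.
#' @param role interaction-set role.
#' @return an [interaction_set()].
#' @export
read_interactions <- function(path, role = "GSP") {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character")
  interaction_set(df, role = role)
}

#' @rdname read_interactions
#' @param iset an [interaction_set()].
#' @export
write_interactions <- function(iset, path) {
  write.table(as.data.frame(iset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a known-target table (TSV: compound_id, protein_id, source)
#'
#' @param path file path.
#' @return data frame with the three columns (source optional).
#' @export
read_known_targets <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound_id", "protein_id") %in% names(df)))
    stop("known-target table needs compound_id and protein_id columns: ",
         path)
  if (is.null(df$source)) df$source <- NA_character_
  df
}

#' Read / write gene sets in GMT format
#'
#' One term per line: term id, TAB, description, TAB, member genes
#' (tab-separated).
#'
#' @param path file path.
#' @param category collection category.
#' @param universe optional background universe (default: union of members).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, category = "pathway", universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         " (need id, description, >=1 member)")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in ", path)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  descs <- setNames(vapply(parts, `[[`, "", 2L), ids)
  gene_set_collection(sets, category = category, names = descs,
                      universe = universe)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(tid) {
    paste(c(tid, unname(collection$names[tid]), collection$sets[[tid]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected PPI edge list (TSV, two id columns)
#'
#' Duplicate edges and self-loops are dropped.
#'
#' @param path file path (header optional; first two columns used).
#' @return an undirected [igraph::igraph] with named vertices.
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("protein|source|node|from", tolower(first))
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, colClasses = "character")
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences (names = ids up
#'   to the first whitespace).
#' @export
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read compound fingerprints (TSV: compound_id, fingerprint)
#'
#' Fingerprints are either one-bit-per-character 0/1 strings or hex strings
#' (4 bits per character, most significant bit first).
#'
#' @param path file path.
#' @return named list of 0/1 integer vectors.
#' @export
read_fingerprints <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("compound_id", "fingerprint") %in% names(df)))
    stop("fingerprint table needs compound_id and fingerprint columns")
  out <- lapply(df$fingerprint, function(s) {
    if (grepl("^[01]+$", s)) {
      as.integer(strsplit(s, "")[[1]])
    } else if (grepl("^[0-9A-Fa-f]+$", s)) {
      nib <- strtoi(strsplit(s, "")[[1]], base = 16L)
      as.integer(unlist(lapply(nib, function(x)
        as.integer(intToBits(x))[4:1])))
    } else stop("fingerprint is neither a bit string nor hex: ", s)
  })
  names(out) <- df$compound_id
  out
}

#' Read a term-membership table (TSV: entity_id, term)
#'
#' Used for side-effect, ATC-code and GO annotations.
#'
#' @param path file path.
#' @return named list: entity id -> character vector of terms.
#' @export
read_term_memberships <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character")
  lapply(split(df[[2]], df[[1]]), unique)
}

#' Read an expression-signature matrix (TSV, compounds x genes)
#'
#' First column: compound id; remaining columns: per-gene responses.
#'
#' @param path file path.
#' @return numeric matrix with compound ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Read an ingredient list (one compound id per line)
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of compound ids.
#' @export
read_ingredient_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read a formula-herb-ingredient mapping table
#'
#' TSV with columns `formula`, `herb`, `compound_id`; used to resolve a
#' formula or herb name into its flat ingredient list.
#'
#' @param path file path.
#' @return data frame with the three columns.
#' @export
read_formula_mapping <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- c("formula", "herb", "compound_id")
  if (!all(need %in% names(df)))
    stop("formula mapping needs columns: ", paste(need, collapse = ", "))
  df[, need]
}
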