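# Raw per-entity records. Availability flags are derived from the data:
# a flag is FALSE iff the corresponding field is empty/absent.

#' Construct a compound record
#'
#' Holds one compound's per-source raw descriptors.  Availability flags are
#' computed, not supplied: a source is available iff its field is non-empty.
#'
#' @param compound_id opaque id string (PubChem CID convention).
#' @param fingerprint 0/1 bit vector (FP2 convention), or `NULL`.
#' @param functional_groups non-negative count vector, or `NULL`.
#' @param side_effects character vector of side-effect term ids.
#' @param atc_codes character vector of 7-character ATC codes.
#' @param expression_signature numeric per-gene response vector, or `NULL`.
#' @return a `compound_record` list.
#' @export
compound_record <- function(compound_id, fingerprint = NULL,
                            functional_groups = NULL,
                            side_effects = character(),
                            atc_codes = character(),
                            expression_signature = NULL) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            nzchar(compound_id))
  atc_codes <- unique(as.character(atc_codes))
  if (length(atc_codes)) {
    bad <- !grepl("^[A-Za-z][0-9]{2}[A-Za-z]{2}[0-9]{2}$", atc_codes)
    if (any(bad))
      stop("compound ", compound_id, ": invalid ATC code(s): ",
           paste(atc_codes[bad], collapse = ", "))
  }
  rec <- list(
    compound_id = compound_id,
    fingerprint = fingerprint,
    functional_groups = functional_groups,
    side_effects = unique(as.character(side_effects)),
    atc_codes = atc_codes,
    expression_signature = expression_signature)
  rec$availability <- list(
    fingerprint = length(fingerprint) > 0L,
    functional_groups = length(functional_groups) > 0L,
    side_effects = length(rec$side_effects) > 0L,
    atc_codes = length(atc_codes) > 0L,
    expression_signature = length(expression_signature) >= 3L)
  structure(rec, class = "compound_record")
}

#' Construct a protein record
#'
#' @param protein_id opaque id string (gene-symbol convention).
#' @param sequence amino-acid string (20-letter alphabet plus X), or `NA`.
#' @param go_terms character vector of GO term ids (may be empty: unannotated).
#' @param in_network whether the protein occurs in the interaction network.
#' @return a `protein_record` list.
#' @export
protein_record <- function(protein_id, sequence = NA_character_,
                           go_terms = character(), in_network = FALSE) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            nzchar(protein_id))
  if (!is.na(sequence) && nchar(sequence) > 0L &&
      grepl("[^ACDEFGHIKLMNPQRSTVWYXacdefghiklmnpqrstvwyx]", sequence))
    stop("protein ", protein_id,
         ": sequence must use the 20-letter amino-acid alphabet plus X")
  structure(list(
    protein_id = protein_id,
    sequence = if (is.na(sequence) || !nzchar(sequence)) NA_character_
               else toupper(sequence),
    go_terms = unique(as.character(go_terms)),
    in_network = isTRUE(in_network)), class = "protein_record")
}

#' Construct an interaction set
#'
#' A labeled set of compound-protein pairs with a role: golden-standard
#' positive (`"GSP"`), sampled negative (`"GSN"`), or `"test"`.
#'
#' @param pairs data frame with columns `compound_id`, `protein_id` (extra
#'   columns are dropped).
#' @param role one of `"GSP"`, `"GSN"`, `"test"`.
#' @return an `interaction_set`: a data frame with attribute `role`.
#' @export
interaction_set <- function(pairs, role = c("GSP", "GSN", "test")) {
  role <- match.arg(role)
  pairs <- as.data.frame(pairs)
  if (!all(c("compound_id", "protein_id") %in% names(pairs)))
    stop("pairs need columns compound_id and protein_id")
  pairs <- unique(pairs[, c("compound_id", "protein_id")])
  pairs$compound_id <- as.character(pairs$compound_id)
  pairs$protein_id <- as.character(pairs$protein_id)
  rownames(pairs) <- NULL
  structure(pairs, role = role, class = c("interaction_set", "data.frame"))
}

pair_keys <- function(pairs) paste(pairs$compound_id, pairs$protein_id,
                                   sep = "\t")
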