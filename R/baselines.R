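# Dictionary NER baseline and adapter for external binary annotators.

#' Build an exact-match term dictionary from the ontology
#'
#' Collects every term's primary name and all synonyms as lowercased
#' surface forms. A surface form shared by several terms maps to all of
#' them. Obsolete terms contribute nothing (they are already excluded from
#' the DAG's term universe). Multi-word forms are preserved verbatim.
#'
#' @param dag An [ontology_dag()].
#' @return An object of class `term_dictionary`: list with
#'   `surface_to_terms` (named list: lowercased form -> term ids) and
#'   `terms_to_forms` (named list: term id -> lowercased forms).
#' @export
build_dictionary <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  terms_to_forms <- lapply(dag$terms, function(tm) {
    unique(tolower(c(dag$name[[tm]], dag$synonyms[[tm]])))
  })
  names(terms_to_forms) <- dag$terms

  pairs_form <- unlist(terms_to_forms, use.names = FALSE)
  pairs_term <- rep(dag$terms, lengths(terms_to_forms))
  surface_to_terms <- lapply(split(pairs_term, pairs_form), unique)

  structure(
    list(surface_to_terms = surface_to_terms,
         terms_to_forms = terms_to_forms),
    class = "term_dictionary"
  )
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("term_dictionary:", length(x$surface_to_terms), "surface forms for",
      length(x$terms_to_forms), "terms\n")
  invisible(x)
}

#' Binary dictionary-NER score for one term in a text
#'
#' Returns 1 when any surface form of the term (name or synonym) occurs in
#' the text as an exact, case-insensitive, word-boundary match; else 0.
#' Matching runs on whitespace-normalised raw text, before any token
#' filtering, because dictionary forms may be short or contain digits.
#' Word boundaries are alphanumeric boundaries, so `"brainstem"` does not
#' match `"brain"`, and exact matching is by construction not robust to
#' misspellings. Matches are not propagated up the ontology: a hit on a
#' descendant term does not set its ancestors to 1.
#'
#' @param text Raw text.
#' @param dict A [build_dictionary()] result.
#' @param term Term id.
#' @return Integer 0 or 1.
#' @export
tagger_score <- function(text, dict, term) {
  stopifnot(inherits(dict, "term_dictionary"))
  forms <- dict$terms_to_forms[[term]]
  if (is.null(forms)) stop("term '", term, "' not in dictionary")
  hay <- tolower(gsub("\\s+", " ", text, perl = TRUE))
  for (f in forms) {
    pat <- paste0("(?<![[:alnum:]])\\Q", f, "\\E(?![[:alnum:]])")
    if (grepl(pat, hay, perl = TRUE)) return(1L)
  }
  0L
}

#' Dictionary-NER scores for many texts and terms
#'
#' @param texts Named character vector of raw texts.
#' @param dict A `term_dictionary`.
#' @param terms Character vector of term ids to score.
#' @return Integer matrix (entities x terms) of 0/1 scores.
#' @export
tagger_score_matrix <- function(texts, dict, terms) {
  out <- vapply(terms, function(tm) {
    vapply(texts, tagger_score, integer(1), dict = dict, term = tm)
  }, integer(length(texts)))
  out <- matrix(out, nrow = length(texts),
                dimnames = list(names(texts), terms))
  out
}

#' Load binary annotations produced by an external annotator
#'
#' Adapter for tools (e.g. metadata-normalisation pipelines) that emit a
#' list of (entity, ontology term) hits: listed pairs score 1, all other
#' pairs over the supplied entity and term universes score 0. Rows whose
#' term is not among `terms` are skipped with a warning; duplicate rows
#' are idempotent.
#'
#' @param path TSV with header columns `entity_id`, `term_id`.
#' @param entities Character vector: full entity universe to score.
#' @param terms Character vector: selected term universe.
#' @return Integer matrix (entities x terms) of 0/1 scores.
#' @export
load_external_binary_annotations <- function(path, entities, terms) {
  df <- read_tsv_strict(path, c("entity_id", "term_id"))
  out <- matrix(0L, length(entities), length(terms),
                dimnames = list(entities, terms))
  unknown_term <- !(df$term_id %in% terms)
  if (any(unknown_term)) {
    warning("skipping ", sum(unknown_term),
            " row(s) with term id(s) outside the selected terms: ",
            paste(unique(df$term_id[unknown_term]), collapse = ", "))
  }
  df <- df[!unknown_term, , drop = FALSE]
  known_ent <- df$entity_id %in% entities
  if (any(!known_ent)) {
    warning("skipping ", sum(!known_ent), " row(s) with unknown entity id(s)")
  }
  df <- df[known_ent, , drop = FALSE]
  if (nrow(df)) out[cbind(df$entity_id, df$term_id)] <- 1L
  out
}
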