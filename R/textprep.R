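# Text preprocessing: raw metadata strings -> cleaned token bags.

#' Clean a raw metadata string into a bag of tokens
#'
#' Applies the fixed cleaning pipeline used for both sample metadata and
#' dataset description sentences:
#' characters that cannot be encoded as UTF-8 are dropped; all Unicode
#' punctuation characters are deleted (not replaced by a space, so
#' hyphenated forms collapse: `"RNA-Seq"` becomes `"rnaseq"`); whitespace
#' runs are collapsed to single spaces; the string is split on spaces;
#' tokens containing any digit, containing a URL marker (`http`, `://`,
#' `www`), or shorter than three characters are removed; survivors are
#' lowercased and lemmatized.
#'
#' The result is a multiset: repeated words are kept, so term frequencies
#' remain available to TF-IDF weighting downstream.
#'
#' @param text A character scalar (may be empty).
#' @param lemmatizer A function mapping a character vector of lowercase
#'   tokens to their root forms. Defaults to the identity; see
#'   [lemmatizer_suffix()] for a dependency-free English stemmer, or plug
#'   in a WordNet-style lemmatizer.
#' @return Character vector of cleaned tokens (possibly empty).
#' @examples
#' tokenize_and_clean("Brain cortex, 24hr; see https://x.y")
#' @export
tokenize_and_clean <- function(text, lemmatizer = lemmatizer_identity) {
  if (length(text) != 1L) stop("'text' must be a single string")
  if (is.na(text) || text == "") return(character())
  text <- iconv(text, from = "", to = "UTF-8", sub = "")
  if (is.na(text)) return(character())
  text <- gsub("\\p{P}", "", text, perl = TRUE)
  text <- gsub("\\s+", " ", text, perl = TRUE)
  toks <- strsplit(trimws(text), " ", fixed = TRUE)[[1]]
  if (!length(toks)) return(character())
  low <- tolower(toks)
  drop <- grepl("\\p{N}", toks, perl = TRUE) |
    grepl("http", low, fixed = TRUE) |
    grepl("://", low, fixed = TRUE) |
    grepl("www", low, fixed = TRUE) |
    nchar(toks) < 3L
  toks <- low[!drop]
  if (!length(toks)) return(character())
  lemmatizer(toks)
}

#' Lemmatizer plug-ins
#'
#' `lemmatizer_identity()` returns tokens unchanged (the default, so the
#' core pipeline needs no language resources). `lemmatizer_suffix()` is a
#' small rule-based English suffix stripper covering regular plurals
#' (`bodies` -> `body`, `classes` -> `class`, `genes` -> `gene`); it is
#' idempotent, which the cleaning pipeline relies on. For production-grade
#' lemmatization inject a WordNet-style lemmatizer with the same signature.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of the same length.
#' @export
lemmatizer_identity <- function(tokens) tokens

#' @rdname lemmatizer_identity
#' @export
lemmatizer_suffix <- function(tokens) {
  out <- tokens
  ies <- grepl("[a-z]ies$", out) & nchar(out) > 4L
  out[ies] <- sub("ies$", "y", out[ies])
  es <- grepl("(s|x|z|ch|sh)es$", out) & nchar(out) > 4L
  out[es] <- sub("es$", "", out[es])
  s <- grepl("[a-rt-z]s$", out) & !grepl("(ss|us|is)$", out) & nchar(out) > 3L
  out[s] <- sub("s$", "", out[s])
  out
}

#' Split free text into sentences
#'
#' Deterministic rule-based segmentation: a sentence boundary is a run of
#' terminal punctuation (`.`, `!`, `?`) followed by whitespace and an
#' uppercase letter. Common lowercase abbreviations (`e.g.`, `vs.`) do not
#' trigger a split because the next character is lowercase. Text with no
#' terminal punctuation is a single sentence; empty input yields zero
#' sentences.
#'
#' @param text A character scalar.
#' @return Character vector of sentences (trimmed, empty segments dropped).
#' @export
split_sentences <- function(text) {
  if (length(text) != 1L) stop("'text' must be a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  parts <- strsplit(text, "(?<=[.!?])\\s+(?=[A-Z])", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Write token bags as TSV
#'
#' Two-column TSV: `entity_id` and the space-joined token bag.
#'
#' @param bags Named list of character vectors (token bags).
#' @param path Output path.
#' @return `path`, invisibly (`write_token_bags`); a named list of
#'   character vectors (`read_token_bags`).
#' @export
write_token_bags <- function(bags, path) {
  df <- data.frame(
    entity_id = names(bags),
    tokens = vapply(bags, paste, character(1), collapse = " "),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' @rdname write_token_bags
#' @export
read_token_bags <- function(path) {
  df <- read_tsv_strict(path, c("entity_id", "tokens"))
  bags <- lapply(df$tokens, function(x) {
    if (is.na(x) || x == "") character() else strsplit(x, " ", fixed = TRUE)[[1]]
  })
  stats::setNames(bags, df$entity_id)
}
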