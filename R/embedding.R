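# Word weights (IDF), word-vector backends, and pooled entity embeddings.

#' Compute inverse document frequencies over a corpus
#'
#' For each word \eqn{t} seen in the corpus, the weight is
#' \eqn{\mathrm{IDF}(t, D) = \log(N / |\{d \in D : t \in d\}|)} with the
#' natural logarithm, where \eqn{N} is the number of documents. A document
#' contributes its *unique* words only, so repetition inside a document
#' does not change its document count. The log base only rescales all
#' weights by a constant, which cancels in the weighted mean used for
#' pooling.
#'
#' @param corpus Either a character vector of raw documents (each is
#'   tokenized with `tokenizer`) or a list of pre-tokenized character
#'   vectors.
#' @param tokenizer Function turning a raw document into tokens; defaults
#'   to [tokenize_and_clean()].
#' @return An object of class `idf_table`: list with `weight` (named
#'   numeric, one entry per word), `n_docs`, and `doc_count` (named
#'   integer).
#' @examples
#' idf <- compute_idf(c("liver sample", "brain sample"))
#' idf$weight
#' @export
compute_idf <- function(corpus, tokenizer = tokenize_and_clean) {
  if (length(corpus) == 0L) stop("corpus is empty")
  docs <- if (is.list(corpus)) {
    lapply(corpus, as.character)
  } else {
    lapply(corpus, tokenizer)
  }
  n_docs <- length(docs)
  counts <- table(unlist(lapply(docs, unique), use.names = FALSE))
  if (length(counts) == 0L) stop("corpus contains no tokens")
  doc_count <- stats::setNames(as.integer(counts), names(counts))
  weight <- log(n_docs / doc_count)
  structure(
    list(weight = weight, n_docs = n_docs, doc_count = doc_count),
    class = "idf_table"
  )
}

#' @export
print.idf_table <- function(x, ...) {
  cat("idf_table:", length(x$weight), "words over", x$n_docs, "documents\n")
  invisible(x)
}

#' Write / read an IDF table as two-column TSV
#'
#' @param idf An `idf_table` (only weights are serialized).
#' @param path File path.
#' @return `path` invisibly; `read_idf` returns an `idf_table` whose
#'   `n_docs`/`doc_count` are `NA` (weights only).
#' @export
write_idf <- function(idf, path) {
  write_tsv(data.frame(word = names(idf$weight),
                       weight = unname(idf$weight),
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_idf
#' @export
read_idf <- function(path) {
  df <- read_tsv_strict(path, c("word", "weight"))
  structure(
    list(weight = stats::setNames(df$weight, df$word),
         n_docs = NA_integer_, doc_count = NULL),
    class = "idf_table"
  )
}

#' Deterministic hashed word-embedding backend
#'
#' A lightweight embedding backend satisfying the backend contract: every
#' string maps to a fixed unit-norm vector, identically across calls, runs
#' and platforms. Each word's vector is drawn from a Gaussian seeded by a
#' stable 31-bit hash of the word's characters combined with `seed`, then
#' normalised. Distinct words receive near-orthogonal vectors at moderate
#' dimensionality, which is what pooled bag-of-words embeddings need for
#' benchmarking; contextual neural backends plug in through the same
#' interface.
#'
#' The global RNG state of the caller is saved and restored, so embedding
#' words does not perturb user-level randomness.
#'
#' @param dim Vector dimensionality (>= 1).
#' @param seed Integer seed folded into every word hash.
#' @return An object of class `embedding_backend` with fields `dim`, `id`
#'   and function `embed_word(word)`.
#' @export
hashed_backend <- function(dim, seed = 0L) {
  stopifnot(dim >= 1L)
  dim <- as.integer(dim)
  seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())
  embed_word <- function(word) {
    key <- paste0("w:", word)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    h <- string_hash31(word, seed = seed)
    v <- with_seed(h, stats::rnorm(dim))
    v <- v / sqrt(sum(v * v))
    cache[[key]] <- v
    v
  }
  structure(
    list(dim = dim, seed = seed,
         id = sprintf("hashed-d%d-s%d", dim, seed),
         embed_word = embed_word),
    class = "embedding_backend"
  )
}

#' Construct an embedding backend from a word-vector table
#'
#' Wraps a precomputed embedding matrix (words x dim) as a backend.
#' Out-of-vocabulary words fall back to a hashed vector so the backend
#' stays total, mirroring character-level models that can embed any
#' string.
#'
#' @param vectors Numeric matrix with one row per word; rownames are the
#'   vocabulary.
#' @param id Identifier recorded in model fingerprints.
#' @return An `embedding_backend`.
#' @export
table_backend <- function(vectors, id = "table") {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  dim <- ncol(vectors)
  oov <- hashed_backend(dim, seed = 104729L)
  embed_word <- function(word) {
    if (word %in% rownames(vectors)) as.numeric(vectors[word, ]) else
      oov$embed_word(word)
  }
  structure(list(dim = dim, id = id, embed_word = embed_word),
            class = "embedding_backend")
}

# words x dim matrix for a token vector (with repeats)
embed_words <- function(backend, words) {
  if (!length(words)) {
    return(matrix(numeric(), 0L, backend$dim))
  }
  mat <- t(vapply(words, backend$embed_word, numeric(backend$dim)))
  rownames(mat) <- words
  mat
}

#' Pool word embeddings into an entity embedding
#'
#' The entity vector is the element-wise weighted average of its token
#' vectors, summed over the token multiset:
#' \eqn{v = \sum_i w_i e(t_i) / \sum_i w_i}. Weights come from the chosen
#' scheme: `"idf"` uses the IDF table; `"tfidf"` multiplies each word's IDF
#' by a supplied per-class term frequency; `"uniform"` sets every weight
#' to 1. A token with no stored weight (misspellings, concatenated words)
#' receives the mean weight of the other tokens in the same bag that do
#' have one. If no token has a stored weight the pooling falls back to
#' uniform with a warning. An empty bag yields the zero vector with
#' attribute `empty = TRUE`.
#'
#' @param bag Character vector of tokens (multiset; repeats count).
#' @param backend An `embedding_backend`.
#' @param weights An `idf_table`, required for schemes `"idf"`/`"tfidf"`.
#' @param scheme Weighting scheme.
#' @param tf Named numeric of per-class term frequencies (scheme
#'   `"tfidf"` only); words absent from `tf` fall under the missing-weight
#'   rule.
#' @return Numeric vector of length `backend$dim`.
#' @export
embed_entity <- function(bag, backend, weights = NULL,
                         scheme = c("idf", "tfidf", "uniform"), tf = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(backend, "embedding_backend"))
  bag <- as.character(bag)
  if (!length(bag)) {
    return(structure(numeric(backend$dim), empty = TRUE))
  }
  w <- token_weights(bag, weights, scheme, tf)
  E <- embed_words(backend, bag)
  v <- colSums(E * w) / sum(w)
  as.numeric(v)
}

# per-token weights with the mean-of-known fallback
token_weights <- function(bag, weights, scheme, tf) {
  n <- length(bag)
  if (scheme == "uniform") return(rep(1, n))
  if (is.null(weights) || !inherits(weights, "idf_table")) {
    stop("scheme '", scheme, "' needs an idf_table in 'weights'")
  }
  w <- unname(weights$weight[bag])
  if (scheme == "tfidf") {
    if (is.null(tf)) stop("scheme 'tfidf' needs per-class frequencies 'tf'")
    w <- w * unname(tf[bag])
  }
  known <- !is.na(w)
  if (!any(known)) {
    warning("no token has a stored weight; falling back to uniform pooling")
    return(rep(1, n))
  }
  if (any(!known)) w[!known] <- mean(w[known])
  if (sum(w) <= 0) {
    warning("token weights sum to zero; falling back to uniform pooling")
    return(rep(1, n))
  }
  w
}

#' Per-class term frequencies for TF-IDF pooling
#'
#' Relative frequency of each word across the token bags of the supplied
#' (training-positive) entities. Computed from training data only so that
#' evaluation folds never leak into the weights.
#'
#' @param bags Named list of token bags.
#' @param entity_ids Entities (e.g. training positives for one term) whose
#'   bags are pooled.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
class_term_frequencies <- function(bags, entity_ids) {
  toks <- unlist(bags[entity_ids], use.names = FALSE)
  if (!length(toks)) return(stats::setNames(numeric(), character()))
  tab <- table(toks)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Embed a multi-sentence dataset description
#'
#' Splits the description into sentences, cleans each, and pools each
#' sentence independently, giving a matrix with one row per non-empty
#' sentence. Datasets whose sentences all clean to empty bags yield a
#' 0-row matrix with attribute `empty = TRUE`.
#'
#' @param description Raw description string.
#' @inheritParams embed_entity
#' @param lemmatizer Passed to [tokenize_and_clean()].
#' @return Numeric matrix (sentences x dim).
#' @export
embed_dataset <- function(description, backend, weights = NULL,
                          scheme = c("idf", "tfidf", "uniform"), tf = NULL,
                          lemmatizer = lemmatizer_identity) {
  scheme <- match.arg(scheme)
  sents <- split_sentences(description)
  bags <- lapply(sents, tokenize_and_clean, lemmatizer = lemmatizer)
  bags <- bags[lengths(bags) > 0]
  if (!length(bags)) {
    out <- matrix(numeric(), 0L, backend$dim)
    attr(out, "empty") <- TRUE
    return(out)
  }
  rows <- lapply(bags, embed_entity, backend = backend, weights = weights,
                 scheme = scheme, tf = tf)
  do.call(rbind, rows)
}

#' Embed a set of sample texts
#'
#' Convenience wrapper: cleans each text and pools it, returning the
#' entity embedding matrix used as the feature matrix for model training.
#'
#' @param texts Named character vector of raw texts (names are entity ids).
#' @inheritParams embed_dataset
#' @return Numeric matrix (entities x dim) with an attribute `empty_ids`
#'   listing entities whose bags cleaned to empty (their rows are zero).
#' @export
embed_samples <- function(texts, backend, weights = NULL,
                          scheme = c("idf", "tfidf", "uniform"), tf = NULL,
                          lemmatizer = lemmatizer_identity) {
  scheme <- match.arg(scheme)
  bags <- lapply(texts, tokenize_and_clean, lemmatizer = lemmatizer)
  rows <- lapply(bags, embed_entity, backend = backend, weights = weights,
                 scheme = scheme, tf = tf)
  out <- do.call(rbind, rows)
  rownames(out) <- names(texts)
  attr(out, "empty_ids") <- names(texts)[lengths(bags) == 0]
  out
}

#' Write / read an embedding matrix as TSV
#'
#' Dense TSV with an `entity_id` column followed by `d1..dK` columns; the
#' dimensionality is recoverable from the header.
#'
#' @param mat Numeric matrix with entity rownames.
#' @param path File path.
#' @return `path` invisibly; `read_embeddings` returns the matrix.
#' @export
write_embeddings <- function(mat, path) {
  df <- data.frame(entity_id = rownames(mat), mat,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("entity_id", paste0("d", seq_len(ncol(mat))))
  write_tsv(df, path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- read_tsv_strict(path, "entity_id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$entity_id
  storage.mode(mat) <- "double"
  mat
}
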