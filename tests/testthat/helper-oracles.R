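# Independent oracles and fixture builders shared across tests.

# Boolean transitive closure by repeated matrix multiplication.
# Returns a terms x terms logical matrix: closure[i, j] iff j is a strict
# ancestor of i (reachable via parent edges).
closure_oracle <- function(terms, parents) {
  n <- length(terms)
  M <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  for (child in names(parents)) {
    for (p in parents[[child]]) M[child, p] <- TRUE
  }
  repeat {
    M2 <- M | ((M %*% M) > 0)
    if (identical(M2, M)) break
    M <- M2
  }
  M
}

# Brute-force label propagation using the explicit closure matrix.
brute_labels <- function(terms, parents, direct, term) {
  M <- closure_oracle(terms, parents)
  desc <- terms[M[, term]]          # terms having `term` as ancestor
  anc <- terms[M[term, ]]
  pos_set <- c(term, desc)
  vapply(direct, function(d) {
    if (any(d %in% pos_set)) "pos"
    else if (any(d %in% anc)) "ignore"
    else "neg"
  }, character(1))
}

# Random DAG: term i may take parents only among earlier terms, so the
# graph is acyclic by construction.
random_dag_fixture <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(n_terms))
  parents <- list()
  for (i in seq(2L, n_terms)) {
    k <- sample(0:2, 1L)
    if (k > 0) {
      parents[[terms[i]]] <- sample(terms[seq_len(i - 1L)],
                                    min(k, i - 1L))
    }
  }
  list(terms = terms, parents = parents,
       dag = ontology_dag(terms, parents = parents))
}

# Random direct annotations over a term universe.
random_annotations <- function(terms, n_samples, seed) {
  set.seed(seed)
  direct <- lapply(seq_len(n_samples), function(i) {
    sample(terms, sample(1:3, 1L))
  })
  names(direct) <- sprintf("S%02d", seq_len(n_samples))
  direct
}

# Wrap bare direct annotations as an annotation_table-alike (one dataset).
as_annotation <- function(direct, dataset_of = NULL) {
  if (is.null(dataset_of)) {
    dataset_of <- stats::setNames(rep("D1", length(direct)), names(direct))
  }
  structure(list(direct = direct, dataset_of = dataset_of, seed = 1L),
            class = "annotation_table")
}

# Hand-built chain ontology A <- B <- C plus an unrelated term D.
chain_dag <- function() {
  ontology_dag(
    terms = c("A", "B", "C", "D"),
    parents = list(B = "A", C = "B")
  )
}

# Classical average precision: mean over positives of precision at each
# positive's rank. Valid only for tie-free scores.
ap_by_positive_ranks <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels[ord] == "pos")
  tp <- cumsum(y)
  prec_at <- tp / seq_along(y)
  mean(prec_at[y == 1L])
}

# Manually assembled logistic model (no fitting), for contract tests.
manual_model <- function(beta, intercept, term = "T") {
  structure(
    list(term = term, coefficients = beta, intercept = intercept,
         C = 1, penalty = "l1", dim = length(beta), fingerprint = NULL),
    class = "term_model"
  )
}

# Small OBO file on disk; returns the path.
write_fixture_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}
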