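# Per-term one-vs-rest classifiers on entity embeddings.

#' Train an L1-regularised logistic model for one ontology term
#'
#' Fits a sparse logistic regression separating positively from negatively
#' labelled entities for a term; ignored entities are excluded from
#' training. Regularisation follows the common inverse-strength
#' parameterisation `C` (default 1): the glmnet penalty is
#' `lambda = 1/(C * n)` with `alpha = 1` and no internal standardisation,
#' so the optimised objective is the familiar
#' \eqn{\|\beta\|_1 + C \sum_i \ell_i} up to a constant factor. The fit is
#' deterministic given the data order.
#'
#' The trainer is feature-agnostic: any numeric entity-by-feature matrix
#' works (text embeddings, expression profiles, ...).
#'
#' @param features Numeric matrix (entities x features) with rownames.
#' @param labels Named character vector over (at least) the feature rows
#'   with values `"pos"`, `"neg"`, `"ignore"`.
#' @param term Term id, recorded on the model.
#' @param C Inverse regularisation strength (default 1).
#' @param fingerprint Optional list describing the feature space (e.g.
#'   `list(dim =, backend =, scheme =)`); checked at prediction time when
#'   present.
#' @return An object of class `term_model` with `term`, `coefficients`,
#'   `intercept`, `C`, `penalty = "l1"`, `dim`, `fingerprint`.
#' @export
train_term_model <- function(features, labels, term, C = 1,
                             fingerprint = NULL) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  labels <- labels[rownames(features)]
  keep <- !is.na(labels) & labels %in% c("pos", "neg")
  y <- as.integer(labels[keep] == "pos")
  if (length(unique(y)) < 2L) {
    stop("term '", term, "' has a single class after excluding ignored ",
         "entities; cannot train")
  }
  x <- features[keep, , drop = FALSE]
  n <- nrow(x)
  # decreasing lambda path ending at the target: warm starts keep the
  # coordinate descent fast and deterministic at small penalties
  target <- 1 / (C * n)
  path <- exp(seq(log(max(1, target * 100)), log(target), length.out = 25L))
  fit <- glmnet::glmnet(
    x, factor(y, levels = c(0L, 1L)), family = "binomial",
    alpha = 1, lambda = path, standardize = FALSE
  )
  last <- ncol(fit$beta)
  structure(
    list(
      term = term,
      coefficients = as.numeric(fit$beta[, last]),
      intercept = as.numeric(fit$a0[[last]]),
      C = C,
      penalty = "l1",
      dim = ncol(x),
      fingerprint = fingerprint
    ),
    class = "term_model"
  )
}

#' @export
print.term_model <- function(x, ...) {
  cat("term_model for '", x$term, "': ", sum(x$coefficients != 0), "/",
      x$dim, " nonzero coefficients\n", sep = "")
  invisible(x)
}

#' Score entities with a trained term model
#'
#' Returns the logistic probability \eqn{\sigma(x\beta + \beta_0)} per
#' entity, a calibrated score in (0, 1).
#'
#' @param model A [train_term_model()] fit.
#' @param features Numeric matrix (entities x features); feature count must
#'   match the model.
#' @return Named numeric vector of probabilities.
#' @export
predict_entities <- function(model, features) {
  stopifnot(inherits(model, "term_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$dim) {
    stop("feature dimensionality ", ncol(features),
         " does not match model dimensionality ", model$dim)
  }
  eta <- drop(features %*% model$coefficients) + model$intercept
  stats::setNames(stats::plogis(eta), rownames(features))
}

#' Score a multi-sentence dataset description
#'
#' A dataset's score for a term is the maximum model probability over its
#' sentence embeddings — a dataset is about a tissue if any sentence is.
#' An empty sentence matrix yields `NA` (a missing score, not 0).
#'
#' @param model A `term_model`.
#' @param dataset_matrix Numeric matrix (sentences x dim) from
#'   [embed_dataset()].
#' @return A single probability, or `NA_real_` for an empty matrix.
#' @export
predict_dataset <- function(model, dataset_matrix) {
  stopifnot(inherits(model, "term_model"))
  if (is.null(dataset_matrix) || nrow(dataset_matrix) == 0L) {
    return(NA_real_)
  }
  max(predict_entities(model, dataset_matrix))
}

#' Embed arbitrary text and score it against a set of term models
#'
#' Cleans and pools any text snippet — unlabeled sample metadata, an
#' ontology term's name-plus-definition, a disease description — and
#' scores it with every supplied model. Text cleaning to an empty bag
#' yields `NA` scores for all terms.
#'
#' @param text Raw text.
#' @param models List of `term_model` objects (equal dimensionality).
#' @param backend,weights,scheme,tf,lemmatizer Passed to [embed_entity()].
#' @return Named numeric vector of probabilities, one per model term.
#' @export
embed_and_predict_text <- function(text, models, backend, weights = NULL,
                                   scheme = c("idf", "tfidf", "uniform"),
                                   tf = NULL,
                                   lemmatizer = lemmatizer_identity) {
  scheme <- match.arg(scheme)
  terms <- vapply(models, function(m) m$term, character(1))
  bag <- tokenize_and_clean(text, lemmatizer = lemmatizer)
  if (!length(bag)) {
    return(stats::setNames(rep(NA_real_, length(models)), terms))
  }
  check_fingerprints(models, backend, scheme)
  v <- embed_entity(bag, backend, weights, scheme = scheme, tf = tf)
  scores <- vapply(models, function(m) {
    unname(predict_entities(m, matrix(v, nrow = 1L)))
  }, numeric(1))
  stats::setNames(scores, terms)
}

check_fingerprints <- function(models, backend, scheme) {
  for (m in models) {
    fp <- m$fingerprint
    if (is.null(fp)) next
    if (!is.null(fp$dim) && fp$dim != backend$dim) {
      stop("model '", m$term, "' was trained at dim ", fp$dim,
           " but backend has dim ", backend$dim)
    }
    if (!is.null(fp$backend) && fp$backend != backend$id) {
      stop("model '", m$term, "' was trained with backend '", fp$backend,
           "' but scoring backend is '", backend$id, "'")
    }
    if (!is.null(fp$scheme) && fp$scheme != scheme) {
      stop("model '", m$term, "' was trained with weighting scheme '",
           fp$scheme, "' but scoring uses '", scheme, "'")
    }
  }
  invisible(TRUE)
}

#' Cosine similarity between standardized model coefficient vectors
#'
#' Stacks the coefficient vectors of several term models, z-scores each
#' feature across models (features with zero variance are set to 0), and
#' returns the cosine similarity matrix between the standardized vectors.
#' Related terms trained on shared vocabulary produce similar coefficient
#' profiles, so this matrix recovers anatomical structure from the models
#' alone. A model whose standardized vector is all zero gets similarity 0
#' to every other model (diagonal stays 1) and is listed in the
#' `degenerate` attribute.
#'
#' @param models List of >= 2 `term_model` objects with equal `dim`.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = term
#'   ids.
#' @export
coefficient_similarity <- function(models) {
  if (length(models) < 2L) stop("need at least two models")
  dims <- vapply(models, function(m) m$dim, numeric(1))
  if (length(unique(dims)) != 1L) {
    stop("models have differing dimensionality")
  }
  terms <- vapply(models, function(m) m$term, character(1))
  B <- do.call(rbind, lapply(models, function(m) m$coefficients))
  rownames(B) <- terms

  # all-zero coefficient vectors (fully shrunk fits) carry no signature;
  # they are excluded from standardization and pinned to similarity 0
  zero_row <- rowSums(B != 0) == 0
  Z <- matrix(0, nrow(B), ncol(B), dimnames = dimnames(B))
  if (sum(!zero_row) >= 2L) {
    Zs <- scale(B[!zero_row, , drop = FALSE])  # z-score per feature
    Zs[, attr(Zs, "scaled:scale") == 0] <- 0
    Z[!zero_row, ] <- Zs
  }

  norms <- sqrt(rowSums(Z * Z))
  bad <- zero_row | norms == 0
  safe <- ifelse(bad, 1, norms)
  sim <- (Z %*% t(Z)) / outer(safe, safe)
  sim[bad, ] <- 0
  sim[, bad] <- 0
  diag(sim) <- 1
  attr(sim, "degenerate") <- terms[zero_row]
  sim
}

#' Serialize / restore term models as JSON
#'
#' Plain-text JSON serialization carrying the coefficients, intercept and
#' the feature-space fingerprint, so models cannot silently be applied to
#' embeddings from a different backend.
#'
#' @param models List of `term_model` objects.
#' @param path File path.
#' @return `path` invisibly; `read_models` returns a named list of
#'   `term_model` objects.
#' @export
write_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(term = m$term, coefficients = m$coefficients,
         intercept = m$intercept, C = m$C, penalty = m$penalty,
         dim = m$dim, fingerprint = m$fingerprint)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  models <- lapply(payload, function(p) {
    structure(
      list(term = p$term, coefficients = as.numeric(p$coefficients),
           intercept = as.numeric(p$intercept), C = p$C,
           penalty = p$penalty, dim = as.integer(p$dim),
           fingerprint = p$fingerprint),
      class = "term_model"
    )
  })
  stats::setNames(models, vapply(models, function(m) m$term, character(1)))
}
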