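# Dataset-stratified cross-validation and precision-recall evaluation.

#' Plan dataset-stratified cross-validation folds for one term
#'
#' Datasets — never individual samples — are assigned to folds, so all
#' samples of a dataset stay together and models are always evaluated on
#' unseen datasets. The fold count follows data availability: 3 folds for
#' terms with exactly three positive datasets, 4 for four, 5 for five or
#' more. Positive datasets are spread as evenly as possible (seeded
#' shuffle, round-robin), guaranteeing at least one positive dataset per
#' fold; negative datasets are assigned by seeded round-robin after
#' shuffling. Ignored datasets are excluded entirely.
#'
#' @param dataset_labels Named character vector (dataset -> `"pos"`,
#'   `"neg"`, `"ignore"`) from [label_datasets()].
#' @param seed Integer seed for the shuffles.
#' @param term Optional term id recorded on the plan.
#' @return An object of class `fold_plan`: list with `term`, `k`, and
#'   `fold_of` (named integer vector over non-ignored datasets).
#' @export
plan_dataset_folds <- function(dataset_labels, seed = 1L, term = NULL) {
  pos <- names(dataset_labels)[dataset_labels == "pos"]
  neg <- names(dataset_labels)[dataset_labels == "neg"]
  n_pos <- length(pos)
  if (n_pos < 3L) {
    stop("term ", if (!is.null(term)) paste0("'", term, "' "),
         "has only ", n_pos, " positive dataset(s); at least 3 are ",
         "required (such terms should have been filtered out)")
  }
  k <- if (n_pos == 3L) 3L else if (n_pos == 4L) 4L else 5L
  fold_of <- with_seed(seed, {
    p <- sample(pos)
    n <- sample(neg)
    c(stats::setNames(rep_len(seq_len(k), length(p)), p),
      stats::setNames(rep_len(seq_len(k), length(n)), n))
  })
  structure(list(term = term, k = k, fold_of = fold_of),
            class = "fold_plan")
}

#' Check that a fold plan respects dataset integrity
#'
#' Verifies that every evaluated sample's dataset has exactly one fold and
#' that no dataset could appear on both sides of a split. Called
#' automatically by [run_cv()]; exported so pipelines can hard-fail early
#' on externally supplied plans.
#'
#' @param plan A `fold_plan`.
#' @param dataset_of Named character vector (sample -> dataset).
#' @return `TRUE` invisibly; errors on violation.
#' @export
check_fold_integrity <- function(plan, dataset_of) {
  stopifnot(inherits(plan, "fold_plan"))
  if (anyDuplicated(names(plan$fold_of))) {
    stop("fold plan assigns a dataset to more than one fold")
  }
  if (!all(plan$fold_of %in% seq_len(plan$k))) {
    stop("fold plan contains fold indices outside 1..k")
  }
  invisible(TRUE)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computes average precision over the ranked entity list:
#' scores are ranked in decreasing order and the precision-recall curve is
#' evaluated at each distinct score value, with
#' \eqn{AP = \sum_k (R_k - R_{k-1}) P_k}. Tied scores are handled as a
#' block at their common threshold — for tie-free scores this equals the
#' classical mean of precision at each positive's rank, and a constant
#' scorer yields exactly the positive fraction (the prior). No trapezoidal
#' interpolation is applied.
#'
#' @param scores Named numeric vector of entity scores.
#' @param labels Named character vector over the same entities with values
#'   `"pos"`/`"neg"` (ignored entities must be excluded upstream).
#' @return Average precision in `[0, 1]`, or `NA_real_` when there are no
#'   positives.
#' @examples
#' auprc(c(a = .9, b = .8, c = .1),
#'       c(a = "pos", b = "neg", c = "pos"))  # (1 + 2/3) / 2
#' @export
auprc <- function(scores, labels) {
  labels <- labels[names(scores)]
  if (anyNA(labels)) stop("every scored entity needs a pos/neg label")
  if (any(!labels %in% c("pos", "neg"))) {
    stop("labels must be 'pos' or 'neg'; exclude ignored entities upstream")
  }
  y <- as.integer(labels == "pos")
  n_pos <- sum(y)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  block_end <- c(which(diff(s) != 0), length(s)) # last index per distinct score
  prec <- tp[block_end] / (tp[block_end] + fp[block_end])
  rec <- tp[block_end] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Log2 enrichment of auPRC over the prior
#'
#' \eqn{\log_2(\mathrm{auPRC} / \mathrm{prior})}: 0 means performance at
#' the level of a random ranking, each unit doubles over it. An auPRC of
#' zero has no finite enrichment and returns `NA`.
#'
#' @param auprc Average precision value (> 0 for a finite result).
#' @param prior Positive fraction among evaluated entities, in (0, 1].
#' @return Numeric scalar or `NA_real_`.
#' @export
log2_enrichment <- function(auprc, prior) {
  stopifnot(prior > 0, prior <= 1)
  if (is.na(auprc) || auprc == 0) return(NA_real_)
  log2(auprc / prior)
}

#' Run dataset-stratified cross-validation for one term
#'
#' For each fold, entities whose dataset lies in the fold form the test
#' set and all other (non-ignored) entities form the training set; the
#' scoring method is fitted on the training samples and evaluated by
#' average precision on the held-out samples only. Dataset integrity is
#' asserted on every fold: no dataset ever contributes to both sides.
#' Folds without a positive test sample are skipped with a warning and the
#' mean is taken over the remaining folds.
#'
#' The `method` callable owns all modelling detail (including any weight
#' estimation such as per-class TF tables), and receives only training
#' ids, so fold leakage is structurally impossible for conforming methods.
#'
#' @param method Function `(train_ids, test_ids) -> named numeric scores`
#'   for the test ids. See [lr_method()].
#' @param fold_plan A [plan_dataset_folds()] result.
#' @param sample_labels Named character vector (sample -> `"pos"`,
#'   `"neg"`, `"ignore"`).
#' @param dataset_of Named character vector (sample -> dataset).
#' @return An object of class `eval_result`: list with `term`, `k`,
#'   `per_fold_auprc`, `mean_auprc`, `prior` (positive fraction among
#'   evaluated samples), and `log2_enrichment`.
#' @export
run_cv <- function(method, fold_plan, sample_labels, dataset_of) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  check_fold_integrity(fold_plan, dataset_of)

  samples <- names(sample_labels)
  ds <- dataset_of[samples]
  in_plan <- ds %in% names(fold_plan$fold_of)
  evaluated <- samples[in_plan & sample_labels != "ignore"]
  ds <- dataset_of[evaluated]
  fold <- fold_plan$fold_of[ds]

  per_fold <- rep(NA_real_, fold_plan$k)
  for (f in seq_len(fold_plan$k)) {
    test_ids <- evaluated[fold == f]
    train_ids <- evaluated[fold != f]
    if (length(intersect(dataset_of[test_ids], dataset_of[train_ids]))) {
      stop("dataset integrity violated in fold ", f)
    }
    if (!any(sample_labels[test_ids] == "pos")) {
      warning("fold ", f, " has no positive test sample; skipping")
      next
    }
    scores <- method(train_ids, test_ids)
    per_fold[f] <- auprc(scores[test_ids], sample_labels[test_ids])
  }

  prior <- mean(sample_labels[evaluated] == "pos")
  mean_auprc <- mean(per_fold, na.rm = TRUE)
  structure(
    list(term = fold_plan$term, k = fold_plan$k,
         per_fold_auprc = per_fold, mean_auprc = mean_auprc,
         prior = prior,
         log2_enrichment = log2_enrichment(mean_auprc, prior)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result%s: k=%d mean auPRC=%.3f prior=%.3f log2(auPRC/prior)=%.2f\n",
              if (is.null(x$term)) "" else paste0(" [", x$term, "]"),
              x$k, x$mean_auprc, x$prior, x$log2_enrichment))
  invisible(x)
}

#' Standard embedding + logistic-regression CV method
#'
#' Builds the `(train_ids, test_ids)` callable used by [run_cv()] for the
#' core pipeline: fit [train_term_model()] on the training rows of a fixed
#' feature matrix and score the test rows. For TF-IDF pooling pass `bags`
#' plus `backend`/`weights`; the per-class term-frequency table and the
#' resulting embeddings are then recomputed inside each training fold from
#' training positives only, so held-out datasets never inform the weights.
#'
#' @param features Numeric matrix (entities x features); ignored when
#'   `bags` is given.
#' @param labels Named character vector of sample labels.
#' @param term Term id for the fitted models.
#' @param C Inverse regularisation strength.
#' @param bags,backend,weights Optional token bags, embedding backend and
#'   IDF table enabling fold-local TF-IDF embedding.
#' @return A function `(train_ids, test_ids) -> named numeric`.
#' @export
lr_method <- function(features = NULL, labels, term, C = 1,
                      bags = NULL, backend = NULL, weights = NULL) {
  if (is.null(bags)) {
    stopifnot(is.matrix(features))
    function(train_ids, test_ids) {
      m <- train_term_model(features[train_ids, , drop = FALSE],
                            labels, term, C = C)
      predict_entities(m, features[test_ids, , drop = FALSE])
    }
  } else {
    stopifnot(!is.null(backend), !is.null(weights))
    function(train_ids, test_ids) {
      tr_pos <- train_ids[labels[train_ids] == "pos"]
      tf <- class_term_frequencies(bags, tr_pos)
      emb <- function(ids) {
        rows <- lapply(bags[ids], embed_entity, backend = backend,
                       weights = weights, scheme = "tfidf", tf = tf)
        out <- do.call(rbind, rows)
        rownames(out) <- ids
        out
      }
      m <- train_term_model(emb(train_ids), labels, term, C = C)
      predict_entities(m, emb(test_ids))
    }
  }
}

#' Paired Wilcoxon comparison of per-term performance
#'
#' Convenience wrapper for comparing two methods across terms: a paired
#' two-sided (by default) Wilcoxon signed-rank test, exact for fewer than
#' 25 pairs.
#'
#' @param a,b Numeric vectors of per-term metric values, paired by term.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return An `htest` object.
#' @export
wilcoxon_compare <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) == length(b))
  stats::wilcox.test(a, b, paired = TRUE, alternative = alternative,
                     exact = length(a) < 25)
}

#' Summarise evaluation results as a report table
#'
#' @param results List of `eval_result` objects.
#' @param n_pos_datasets Optional named integer (term -> count of positive
#'   datasets).
#' @param systems Optional named list (term -> anatomical system labels)
#'   from [assign_anatomical_systems()].
#' @return A data frame with one row per term: `term`, `k`, `n_pos`,
#'   `mean_auprc`, `prior`, `log2_enrichment`, `system`.
#' @export
eval_report <- function(results, n_pos_datasets = NULL, systems = NULL) {
  terms <- vapply(results, function(r) r$term %||% NA_character_,
                  character(1))
  data.frame(
    term = terms,
    k = vapply(results, function(r) r$k, integer(1)),
    n_pos = if (is.null(n_pos_datasets)) NA_integer_ else
      as.integer(n_pos_datasets[terms]),
    mean_auprc = vapply(results, function(r) r$mean_auprc, numeric(1)),
    prior = vapply(results, function(r) r$prior, numeric(1)),
    log2_enrichment = vapply(results, function(r) r$log2_enrichment,
                             numeric(1)),
    system = if (is.null(systems)) NA_character_ else
      vapply(terms, function(tm) {
        paste(systems[[tm]], collapse = ";")
      }, character(1)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
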