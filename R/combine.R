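# Combining predictions across methods and across granularities.

#' F1 score of thresholded predictions
#'
#' Harmonic mean of precision and recall after thresholding scores at
#' `threshold`. When no entity is predicted positive the F1 is defined as
#' 0 (reported via `message()` since it usually signals a miscalibrated
#' method).
#'
#' @param scores Named numeric vector.
#' @param labels Named character vector (`"pos"`/`"neg"`) over the same
#'   entities.
#' @param threshold Decision threshold (default 0.5; scores `>= threshold`
#'   are predicted positive).
#' @return F1 in `[0, 1]`.
#' @export
f1_from_predictions <- function(scores, labels, threshold = 0.5) {
  labels <- labels[names(scores)]
  if (!any(labels == "pos")) stop("labels contain no positive entity")
  pred <- scores >= threshold
  tp <- sum(pred & labels == "pos")
  fp <- sum(pred & labels == "neg")
  fn <- sum(!pred & labels == "pos")
  if (tp + fp == 0L) {
    message("no predicted positives at threshold ", threshold,
            "; F1 set to 0")
    return(0)
  }
  if (tp == 0L) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' F1-weighted average of per-method prediction scores
#'
#' Combines several methods' probabilities for the same entities using
#' each method's F1 score as its weight:
#' \eqn{p = \sum_m F1_m \, p_m / \sum_m F1_m}. Binary annotators enter
#' with their 0/1 scores directly. If every weight is zero the combination
#' degrades to the unweighted mean with a warning.
#'
#' @param per_method_scores Named list (method -> named numeric vector);
#'   all vectors must cover the same entities.
#' @param per_method_f1 Named numeric vector of non-negative weights,
#'   aligned with `per_method_scores` by name.
#' @return Named numeric vector of combined scores.
#' @export
combine_weighted <- function(per_method_scores, per_method_f1) {
  methods <- names(per_method_scores)
  if (length(methods) < 2L) stop("need at least two methods to combine")
  if (is.null(methods) || !all(methods %in% names(per_method_f1))) {
    stop("every method needs a weight in 'per_method_f1'")
  }
  w <- per_method_f1[methods]
  if (any(w < 0)) stop("weights must be non-negative")
  ents <- names(per_method_scores[[1L]])
  for (m in methods[-1L]) {
    if (!identical(sort(names(per_method_scores[[m]])), sort(ents))) {
      stop("method '", m, "' scores a different entity set")
    }
  }
  if (all(w == 0)) {
    warning("all combination weights are zero; using unweighted mean")
    w[] <- 1
  }
  num <- Reduce(`+`, Map(function(m, wt) wt * per_method_scores[[m]][ents],
                         methods, w))
  stats::setNames(as.numeric(num / sum(w)), ents)
}

#' Combine a sample-level and a dataset-level prediction
#'
#' `mode = "add"` simply adds the sample's own probability and its parent
#' dataset's probability, yielding a ranking score in `[0, 2]` (not a
#' probability); `mode = "max"` takes the larger of the two. A missing
#' dataset score leaves the sample score unchanged; two missing scores
#' yield `NA`.
#'
#' @param p_sample,p_dataset Numeric vectors (recycled) of probabilities
#'   in `[0, 1]`, `NA` for missing.
#' @param mode `"add"` or `"max"`.
#' @return Numeric vector of combined scores.
#' @export
combine_sample_dataset <- function(p_sample, p_dataset,
                                   mode = c("add", "max")) {
  mode <- match.arg(mode)
  n <- max(length(p_sample), length(p_dataset))
  ps <- rep_len(p_sample, n)
  pd <- rep_len(p_dataset, n)
  out <- ifelse(
    is.na(ps) & is.na(pd), NA_real_,
    ifelse(is.na(pd), ps,
           ifelse(is.na(ps), pd,
                  if (mode == "add") ps + pd else pmax(ps, pd)))
  )
  if (!is.null(names(p_sample)) && length(p_sample) == n) {
    names(out) <- names(p_sample)
  } else if (!is.null(names(p_dataset)) && length(p_dataset) == n) {
    names(out) <- names(p_dataset)
  }
  out
}
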