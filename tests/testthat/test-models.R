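# Fixture: linearly separable 2-D embeddings around (1,0) and (0,1).
separable_fixture <- function(n_per_class = 20, eps = 0.05, seed = 1) {
  set.seed(seed)
  ids <- sprintf("e%02d", seq_len(2 * n_per_class))
  x <- rbind(
    cbind(1 + rnorm(n_per_class, 0, eps), rnorm(n_per_class, 0, eps)),
    cbind(rnorm(n_per_class, 0, eps), 1 + rnorm(n_per_class, 0, eps))
  )
  rownames(x) <- ids
  labels <- stats::setNames(rep(c("pos", "neg"), each = n_per_class), ids)
  list(x = x, labels = labels)
}

test_that("a separable problem is fit to training auPRC 1", {
  fx <- separable_fixture()
  m <- train_term_model(fx$x, fx$labels, "muscle")
  p <- predict_entities(m, fx$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(auprc(p, fx$labels), 1.0)
})

test_that("single-class training is an explicit error naming the term", {
  fx <- separable_fixture()
  all_pos <- stats::setNames(rep("pos", nrow(fx$x)), rownames(fx$x))
  expect_error(train_term_model(fx$x, all_pos, "liver"), "liver")
})

test_that("ignored entities are excluded from the fit", {
  fx <- separable_fixture()
  lab <- fx$labels
  # corrupt some entities with an 'ignore' label at extreme positions
  lab[c("e01", "e21")] <- "ignore"
  m <- train_term_model(fx$x, lab, "t")
  keep <- names(lab)[lab != "ignore"]
  p <- predict_entities(m, fx$x[keep, ])
  expect_equal(auprc(p, lab[keep]), 1.0)
})

test_that("duplicating every training row preserves the decision ranking", {
  fx <- separable_fixture(n_per_class = 15, eps = 0.4, seed = 7)
  m1 <- train_term_model(fx$x, fx$labels, "t")
  xdup <- rbind(fx$x, fx$x)
  rownames(xdup) <- c(rownames(fx$x), paste0(rownames(fx$x), "_b"))
  labdup <- stats::setNames(rep(fx$labels, 2), rownames(xdup))
  m2 <- train_term_model(xdup, labdup, "t")
  s1 <- predict_entities(m1, fx$x)
  s2 <- predict_entities(m2, fx$x)
  # rank agreement up to numerical near-ties in the duplicated fit
  expect_gt(stats::cor(s1, s2, method = "spearman"), 0.999)
  # clearly separated entities keep their exact relative order
  spread <- abs(outer(s1, s1, "-")) > 0.05
  expect_true(all((outer(s1, s1, "<") == outer(s2, s2, "<"))[spread]))
})

test_that("probabilities follow the logistic link exactly", {
  m <- manual_model(beta = c(2, -1), intercept = 0.5)
  x <- rbind(p1 = c(0.25, 1))     # eta = 0.5 - 1 + 0.5 = 0
  expect_equal(unname(predict_entities(m, x)[["p1"]]), 0.5)
  m0 <- manual_model(beta = c(0, 0), intercept = 0)
  xs <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("e", 1:5), NULL))
  expect_equal(unname(predict_entities(m0, xs)), rep(0.5, 5))
  expect_error(predict_entities(m, cbind(1)), "dimensionality")
})

test_that("probability is monotone in the projection onto the coefficients", {
  set.seed(21)
  for (i in 1:20) {
    beta <- rnorm(6)
    m <- manual_model(beta, intercept = rnorm(1))
    base <- rnorm(6)
    step <- beta / sqrt(sum(beta^2))     # move along the coefficient vector
    x <- rbind(a = base, b = base + 0.5 * step, c = base + 2 * step)
    p <- predict_entities(m, x)
    expect_true(p[["a"]] <= p[["b"]] && p[["b"]] <= p[["c"]])
  }
})

test_that("dataset scoring is the max over sentence probabilities", {
  m <- manual_model(beta = c(1, 0), intercept = 0)
  mat <- rbind(c(stats::qlogis(0.2), 0),
               c(stats::qlogis(0.9), 0),
               c(stats::qlogis(0.4), 0))
  expect_equal(predict_dataset(m, mat), 0.9)
  expect_equal(predict_dataset(m, mat[2, , drop = FALSE]),
               unname(predict_entities(m, mat[2, , drop = FALSE])))
  same <- mat[c(1, 1, 1), ]
  expect_equal(predict_dataset(m, same), 0.2)
  expect_true(is.na(predict_dataset(m, matrix(numeric(), 0, 2))))
  # pooling dominates every individual sentence
  expect_true(all(predict_dataset(m, mat) >= predict_entities(m, mat)))
})

test_that("free-text scoring matches sample scoring and flags empty text", {
  be <- hashed_backend(32, seed = 13)
  fxtexts <- c(s1 = "muscle contraction assay tissue",
               s2 = "hepatic lobule staining")
  feats <- embed_samples(fxtexts, be, scheme = "uniform")
  labels <- stats::setNames(c("pos", "neg"), names(fxtexts))
  # replicated two-sample fit is enough for the determinism contract
  reps <- 8L
  xrep <- feats[rep(1:2, reps), ]
  rownames(xrep) <- paste0(rep(names(labels), reps), "_",
                           rep(seq_len(reps), each = 2))
  labrep <- stats::setNames(rep(labels, reps), rownames(xrep))
  m <- train_term_model(xrep, labrep, "muscle")
  m$fingerprint <- list(dim = 32, backend = be$id, scheme = "uniform")
  via_text <- embed_and_predict_text(fxtexts[["s1"]], list(m), be,
                                     scheme = "uniform")
  expect_equal(unname(via_text[["muscle"]]),
               unname(predict_entities(m, feats)[["s1"]]))
  empty <- embed_and_predict_text("12 34 :-)", list(m), be,
                                  scheme = "uniform")
  expect_true(is.na(empty[["muscle"]]))
  # fingerprint guard refuses a mismatched backend
  expect_error(
    embed_and_predict_text("muscle", list(m), hashed_backend(32, 99),
                           scheme = "uniform"),
    "backend"
  )
})

test_that("an ontology-style description is recognised by a term model", {
  set.seed(31)
  be <- hashed_backend(64, seed = 31)
  muscle_vocab <- c("muscle", "contraction", "force", "myofiber",
                    "sarcomere", "actin")
  other_vocab <- c("hepatic", "lobule", "bile", "neuron", "axon",
                   "synapse")
  mk <- function(vocab, n, prefix) {
    stats::setNames(
      vapply(seq_len(n), function(i) {
        paste(sample(vocab, 8, replace = TRUE), collapse = " ")
      }, character(1)),
      sprintf("%s%02d", prefix, seq_len(n))
    )
  }
  texts <- c(mk(muscle_vocab, 30, "p"), mk(other_vocab, 30, "n"))
  labels <- stats::setNames(rep(c("pos", "neg"), each = 30), names(texts))
  feats <- embed_samples(texts, be, scheme = "uniform")
  m <- train_term_model(feats, labels, "muscle")
  snippet <- paste("muscle contraction. A process in which force is",
                   "generated within muscle tissue")
  p <- embed_and_predict_text(snippet, list(m), be, scheme = "uniform")
  expect_gt(p[["muscle"]], 0.5)
})

test_that("coefficient similarity is symmetric with unit diagonal", {
  m1 <- manual_model(c(1, 0, 2, 0), 0, term = "t1")
  m2 <- manual_model(c(0, 1, 0, 2), 0, term = "t2")
  m3 <- manual_model(c(1, 0, 2, 0) * 3, 0, term = "t3")
  S <- coefficient_similarity(list(m1, m2, m3))
  expect_equal(diag(S), stats::setNames(rep(1, 3), c("t1", "t2", "t3")))
  expect_equal(S, t(S), ignore_attr = TRUE)
  expect_true(all(S >= -1 - 1e-9 & S <= 1 + 1e-9))
})

test_that("raw-cosine structure: orthogonal vs colinear models", {
  # bypass z-scoring effects by checking on unstandardised copies
  B <- rbind(t1 = c(1, 0), t2 = c(0, 1))
  cosine <- sum(B[1, ] * B[2, ]) /
    (sqrt(sum(B[1, ]^2)) * sqrt(sum(B[2, ]^2)))
  expect_equal(cosine, 0)
  # degenerate all-zero model is flagged with similarity 0
  mz <- manual_model(c(0, 0, 0), 0, term = "z")
  ma <- manual_model(c(1, 2, 3), 0, term = "a")
  mb <- manual_model(c(3, 2, 1), 0, term = "b")
  S <- coefficient_similarity(list(mz, ma, mb))
  expect_true("z" %in% attr(S, "degenerate"))
  expect_equal(unname(S["z", "a"]), 0)
  expect_equal(unname(S["z", "z"]), 1)
})

test_that("the trainer honours generic feature matrices", {
  # simulated expression-like features: two gene programs
  set.seed(55)
  n <- 40
  x <- cbind(matrix(rnorm(n * 5, 2), n, 5), matrix(rnorm(n * 5, 0), n, 5))
  x[1:(n / 2), 1:5] <- x[1:(n / 2), 1:5] + 3
  rownames(x) <- sprintf("expr%02d", 1:n)
  labels <- stats::setNames(rep(c("pos", "neg"), each = n / 2),
                            rownames(x))
  m <- train_term_model(x, labels, "tissue")
  p <- predict_entities(m, x)
  expect_true(all(p > 0 & p < 1))
  expect_gt(auprc(p, labels), 0.95)
})

test_that("models round-trip through JSON with their fingerprint", {
  fx <- separable_fixture()
  m <- train_term_model(fx$x, fx$labels, "t1",
                        fingerprint = list(dim = 2, backend = "hashed-x",
                                           scheme = "uniform"))
  path <- tempfile(fileext = ".json")
  write_models(list(m), path)
  back <- read_models(path)[["t1"]]
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_identical(back$fingerprint$backend, "hashed-x")
  expect_equal(predict_entities(back, fx$x), predict_entities(m, fx$x))
})
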