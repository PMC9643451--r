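test_that("parse_obo loads chain ontologies and computes closures", {
  path <- write_fixture_obo(c(
    "[Term]", "id: A", "name: organ a", "",
    "[Term]", "id: B", "name: organ b", "is_a: A ! organ a", "",
    "[Term]", "id: C", "name: organ c", "is_a: B", ""
  ))
  dag <- parse_obo(path)
  expect_setequal(dag$terms, c("A", "B", "C"))
  expect_setequal(ancestors(dag, "C"), c("A", "B"))
  expect_setequal(descendants(dag, "A"), c("B", "C"))
})

test_that("part_of edges participate in the closure when requested", {
  path <- write_fixture_obo(c(
    "[Term]", "id: A", "name: a", "",
    "[Term]", "id: B", "name: b", "is_a: A", "",
    "[Term]", "id: C", "name: c", "relationship: part_of B", ""
  ))
  dag <- parse_obo(path, edge_types = c("is_a", "part_of"))
  # oracle: DFS transitive closure on the retained edges
  M <- closure_oracle(c("A", "B", "C"), list(B = "A", C = "B"))
  expect_setequal(ancestors(dag, "C"), c("A", "B")[M["C", c("A", "B")]])

  dag_isa <- parse_obo(path, edge_types = "is_a")
  expect_identical(ancestors(dag_isa, "C"), character(0))
})

test_that("cycles are a structural error naming a participant", {
  path <- write_fixture_obo(c(
    "[Term]", "id: A", "name: a", "is_a: B", "",
    "[Term]", "id: B", "name: b", "is_a: A", ""
  ))
  expect_error(parse_obo(path), "cycle involving term '(A|B)'")
})

test_that("dangling edges drop with a warning; obsolete terms are skipped", {
  path <- write_fixture_obo(c(
    "[Term]", "id: A", "name: a", "is_a: ZZZ", "",
    "[Term]", "id: B", "name: b", "is_obsolete: true", "",
    "[Term]", "id: C", "name: c",
    "synonym: \"old c\" EXACT []", "is_a: A", ""
  ))
  expect_warning(expect_warning(dag <- parse_obo(path), "obsolete"),
                 "undeclared")
  expect_setequal(dag$terms, c("A", "C"))
  expect_identical(dag$obsolete, "B")
  expect_identical(dag$synonyms[["C"]], "old c")
  expect_identical(ancestors(dag, "C"), "A")
})

test_that("sample label propagation follows the descendant/ancestor rule", {
  dag <- chain_dag()
  ann <- as_annotation(list(s1 = "C", s2 = "A", s3 = "D",
                            s4 = c("A", "C")))
  # positives flow up from descendants
  expect_identical(propagate_sample_labels(dag, ann, "A")[["s1"]], "pos")
  # ancestor-annotated samples are ambiguous -> ignored
  expect_identical(propagate_sample_labels(dag, ann, "C")[["s2"]], "ignore")
  # unrelated -> negative
  expect_identical(propagate_sample_labels(dag, ann, "C")[["s3"]], "neg")
  # positive beats ignore when both trigger
  expect_identical(propagate_sample_labels(dag, ann, "C")[["s4"]], "pos")
  expect_error(propagate_sample_labels(dag, ann, "Z"), "not in ontology")
})

test_that("propagation matches the brute-force closure oracle", {
  for (rep in 1:25) {
    fx <- random_dag_fixture(n_terms = sample(5:20, 1L), seed = 500 + rep)
    direct <- random_annotations(fx$terms, n_samples = sample(3:8, 1L),
                                 seed = 900 + rep)
    ann <- as_annotation(direct)
    for (tm in fx$terms) {
      expect_identical(
        propagate_sample_labels(fx$dag, ann, tm),
        brute_labels(fx$terms, fx$parents, direct, tm),
        info = paste("seed", rep, "term", tm)
      )
    }
  }
})

test_that("propagation respects the true-path rule and is exhaustive", {
  for (rep in 1:10) {
    fx <- random_dag_fixture(12, seed = 40 + rep)
    ann <- as_annotation(random_annotations(fx$terms, 6, seed = 70 + rep))
    cols <- propagate_labels(fx$dag, ann)
    expect_true(all(cols %in% c("pos", "neg", "ignore")))
    for (tm in fx$terms) {
      pos_t <- rownames(cols)[cols[, tm] == "pos"]
      for (a in ancestors(fx$dag, tm)) {
        expect_true(all(pos_t %in% rownames(cols)[cols[, a] == "pos"]))
      }
    }
  }
})

test_that("dataset labels follow the strict-majority cascade", {
  dag <- chain_dag()
  lab5 <- stats::setNames(c("pos", "pos", "pos", "neg", "ignore"),
                          sprintf("s%d", 1:5))
  ann5 <- as_annotation(stats::setNames(as.list(rep("A", 5)), names(lab5)))
  expect_identical(label_datasets(lab5, ann5)[["D1"]], "pos")

  lab4 <- stats::setNames(c("ignore", "ignore", "ignore", "neg"),
                          sprintf("s%d", 1:4))
  ann4 <- as_annotation(stats::setNames(as.list(rep("A", 4)), names(lab4)))
  expect_identical(label_datasets(lab4, ann4)[["D1"]], "ignore")

  # exact tie: neither strict majority -> negative
  labt <- stats::setNames(c("pos", "pos", "neg", "neg"),
                          sprintf("s%d", 1:4))
  annt <- as_annotation(stats::setNames(as.list(rep("A", 4)), names(labt)))
  expect_identical(label_datasets(labt, annt)[["D1"]], "neg")
})

test_that("dataset labels are invariant under sample order permutation", {
  set.seed(11)
  labs <- stats::setNames(sample(c("pos", "neg", "ignore"), 9, TRUE),
                          sprintf("s%d", 1:9))
  ds <- stats::setNames(rep(c("D1", "D2", "D3"), each = 3), names(labs))
  ann <- as_annotation(stats::setNames(as.list(rep("A", 9)), names(labs)),
                       dataset_of = ds)
  ref <- label_datasets(labs, ann)
  for (i in 1:5) {
    perm <- sample(names(labs))
    expect_identical(label_datasets(labs[perm], ann)[names(ref)], ref)
  }
})

test_that("trainable-term selection counts positive datasets", {
  m <- cbind(
    t1 = c("pos", "pos", "pos", "neg"),
    t2 = c("pos", "pos", "neg", "neg"),
    t3 = c("pos", "neg", "neg", "neg")
  )
  rownames(m) <- sprintf("D%d", 1:4)
  expect_identical(select_trainable_terms(m), "t1")
  expect_setequal(select_trainable_terms(m, min_pos_datasets = 1),
                  c("t1", "t2", "t3"))
})

test_that("samples in several datasets are assigned to exactly one", {
  dag <- chain_dag()
  df <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    dataset_id = c("D1", "D2", "D1"),
    term_id = c("C", "C", "A")
  )
  ann1 <- annotation_table(df, dag, seed = 5)
  ann2 <- annotation_table(df, dag, seed = 5)
  expect_identical(ann1$dataset_of, ann2$dataset_of)   # seeded determinism
  expect_length(ann1$dataset_of[["s1"]], 1L)
  expect_true(ann1$dataset_of[["s1"]] %in% c("D1", "D2"))
  expect_error(annotation_table(
    data.frame(sample_id = "s", dataset_id = "D", term_id = "NOPE"),
    dag), "absent from ontology")
})

test_that("anatomical-system assignment maps via ancestors and dissolves
           sparse systems", {
  # two system roots; sys1 has 9 model terms below it, sys2 has exactly 8
  terms <- c("root", "sys1", "sys2", sprintf("a%d", 1:9),
             sprintf("b%d", 1:8), "orphan")
  parents <- c(
    list(sys1 = "root", sys2 = "root"),
    stats::setNames(as.list(rep("sys1", 9)), sprintf("a%d", 1:9)),
    stats::setNames(as.list(rep("sys2", 8)), sprintf("b%d", 1:8))
  )
  dag <- ontology_dag(terms, parents = parents)
  model_terms <- c(sprintf("a%d", 1:9), sprintf("b%d", 1:8), "orphan")
  sys <- assign_anatomical_systems(dag, c("sys1", "sys2"), model_terms)
  expect_identical(sys[["a1"]], "sys1")          # 9 > 8 members survives
  expect_identical(sys[["b1"]], NA_character_)   # exactly 8 -> dissolved
  expect_identical(sys[["orphan"]], NA_character_)
})

test_that("label matrices round-trip through TSV", {
  m <- cbind(t1 = c("pos", "neg"), t2 = c("ignore", "pos"))
  rownames(m) <- c("e1", "e2")
  path <- tempfile(fileext = ".tsv")
  write_labels(m, path)
  expect_identical(read_labels(path)[rownames(m), colnames(m)], m)
})
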