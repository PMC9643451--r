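# Ontology DAG: OBO parsing, transitive closures, and gold-standard labels.

#' Construct an ontology DAG
#'
#' Builds the directed acyclic graph of ontology terms used throughout the
#' package. Edges point from child to parent (`t` is_a/part_of `p`), and
#' ancestor/descendant transitive closures are precomputed. Validation
#' enforces that every edge endpoint is a declared term and that the graph
#' restricted to the retained edge types is acyclic.
#'
#' @param terms Character vector of term ids.
#' @param names Named character vector mapping term id to its primary name.
#' @param synonyms Named list mapping term id to a character vector of
#'   synonym strings (may be empty).
#' @param parents Named list mapping term id to a character vector of parent
#'   term ids (already restricted to the edge types of interest).
#' @param edge_types Named list mapping term id to the relation name of each
#'   parent edge, parallel to `parents` (recorded for provenance).
#' @param obsolete Character vector of term ids that were declared obsolete
#'   and are excluded from the term universe.
#' @return An object of class `ontology_dag` with elements `terms`, `name`,
#'   `synonyms`, `parents`, `edge_types`, `obsolete`, and precomputed
#'   closures `anc` and `desc` (named lists of character vectors; strict,
#'   i.e. a term is not its own ancestor).
#' @export
ontology_dag <- function(terms, names = NULL, synonyms = NULL,
                         parents = NULL, edge_types = NULL,
                         obsolete = character()) {
  terms <- unique(as.character(terms))
  if (is.null(names)) names <- stats::setNames(terms, terms)
  if (is.null(synonyms)) synonyms <- stats::setNames(
    rep(list(character()), length(terms)), terms)
  if (is.null(parents)) parents <- list()
  parents <- parents[lengths(parents) > 0]

  for (child in names(parents)) {
    if (!child %in% terms) {
      stop("edge child '", child, "' is not a declared term")
    }
    bad <- setdiff(parents[[child]], terms)
    if (length(bad)) {
      stop("edge target(s) not declared: ", paste(bad, collapse = ", "))
    }
  }

  edges <- NULL
  if (length(parents)) {
    edges <- data.frame(
      from = rep(names(parents), lengths(parents)),
      to = unlist(parents, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }

  closures <- compute_closures(terms, edges)

  structure(
    list(
      terms = terms,
      name = names,
      synonyms = synonyms,
      parents = parents,
      edge_types = edge_types,
      obsolete = unique(as.character(obsolete)),
      anc = closures$anc,
      desc = closures$desc
    ),
    class = "ontology_dag"
  )
}

# Reachability closures over the child->parent edge list. Errors on cycles,
# naming one term that participates.
compute_closures <- function(terms, edges) {
  empty <- stats::setNames(rep(list(character()), length(terms)), terms)
  if (is.null(edges) || nrow(edges) == 0) {
    return(list(anc = empty, desc = empty))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    in_cycle <- names(comp$membership)[comp$membership %in%
                                         which(comp$csize > 1)]
    if (!length(in_cycle)) {  # pure self-loop
      in_cycle <- unique(edges$from[edges$from == edges$to])
    }
    stop("ontology edges contain a cycle involving term '",
         in_cycle[[1]], "'")
  }
  anc <- empty
  desc <- empty
  up <- igraph::ego(g, order = igraph::vcount(g), mode = "out", mindist = 1)
  down <- igraph::ego(g, order = igraph::vcount(g), mode = "in", mindist = 1)
  vnames <- igraph::V(g)$name
  for (i in seq_along(vnames)) {
    anc[[vnames[i]]] <- names(up[[i]])
    desc[[vnames[i]]] <- names(down[[i]])
  }
  list(anc = anc, desc = desc)
}

#' Ancestors / descendants of a term
#'
#' Strict transitive closure lookups on an [ontology_dag()]: a term is not
#' reported as its own ancestor or descendant.
#'
#' @param dag An `ontology_dag`.
#' @param term A term id present in the DAG.
#' @return Character vector of term ids.
#' @export
ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms) stop("term '", term, "' not in ontology")
  dag$anc[[term]]
}

#' @rdname ancestors
#' @export
descendants <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$terms) stop("term '", term, "' not in ontology")
  dag$desc[[term]]
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat("ontology_dag:", length(x$terms), "terms,", n_edges, "edges,",
      length(x$obsolete), "obsolete\n")
  invisible(x)
}

#' Parse an OBO-format ontology file
#'
#' Reads the subset of the OBO dialect used by anatomy/cell-type ontologies:
#' `[Term]` stanzas with `id:`, `name:`, `synonym: "..."` (scope ignored),
#' `is_a:`, `relationship: <type> <id>`, and `is_obsolete:` tags. All other
#' stanzas and tags are ignored. Only edges whose relation is listed in
#' `edge_types` are retained; the default `is_a` + `part_of` set mirrors the
#' extended anatomy/cell-ontology graphs commonly used for sample
#' annotation. Obsolete terms are skipped with a warning, and edges whose
#' target is not a loaded term are dropped with a warning.
#'
#' @param path Path to an OBO file.
#' @param edge_types Character vector of relation names to keep as parent
#'   edges. `is_a` is always expressed as relation name `"is_a"`.
#' @return An [ontology_dag()].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: A", "name: organ a",
#'              "[Term]", "id: B", "name: organ b", "is_a: A"), obo)
#' dag <- parse_obo(obo)
#' ancestors(dag, "B")
#' @export
parse_obo <- function(path, edge_types = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)

  terms <- character()
  nm <- character()
  syn <- list()
  par <- list()
  par_rel <- list()
  obsolete <- character()

  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (is.null(cur) || is.na(cur$id)) return()
    if (isTRUE(cur$obsolete)) {
      obsolete[[length(obsolete) + 1L]] <<- cur$id
      return()
    }
    terms[[length(terms) + 1L]] <<- cur$id
    nm[[cur$id]] <<- if (is.na(cur$name)) cur$id else cur$name
    syn[[cur$id]] <<- cur$synonyms
    par[[cur$id]] <<- cur$parents
    par_rel[[cur$id]] <<- cur$rels
  }
  new_term <- function() list(id = NA_character_, name = NA_character_,
                              synonyms = character(), parents = character(),
                              rels = character(), obsolete = FALSE)

  for (ln in lines) {
    if (ln == "[Term]") {
      flush(); cur <- new_term(); in_term <- TRUE; next
    }
    if (grepl("^\\[", ln)) {  # other stanza type
      flush(); cur <- NULL; in_term <- FALSE; next
    }
    if (!in_term || ln == "") next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "synonym:")) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) {
        cur$synonyms <- c(cur$synonyms, substr(m, 2L, nchar(m) - 1L))
      }
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
      cur$rels <- c(cur$rels, "is_a")
    } else if (startsWith(ln, "relationship:")) {
      body <- trimws(sub("!.*$", "", sub("^relationship:", "", ln)))
      parts <- strsplit(body, "\\s+")[[1]]
      if (length(parts) >= 2) {
        cur$parents <- c(cur$parents, parts[[2]])
        cur$rels <- c(cur$rels, parts[[1]])
      }
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  flush()

  if (length(obsolete)) {
    warning("skipped ", length(obsolete), " obsolete term(s)")
  }

  # restrict to requested edge types, then drop dangling targets
  dropped <- character()
  for (id in names(par)) {
    keep <- par_rel[[id]] %in% edge_types
    p <- par[[id]][keep]
    r <- par_rel[[id]][keep]
    known <- p %in% terms
    if (any(!known)) dropped <- c(dropped, p[!known])
    par[[id]] <- p[known]
    par_rel[[id]] <- r[known]
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " edge(s) to undeclared term(s): ",
            paste(unique(dropped), collapse = ", "))
  }

  ontology_dag(terms = terms, names = nm, synonyms = syn, parents = par,
               edge_types = par_rel, obsolete = obsolete)
}

#' Build an annotation table
#'
#' Holds direct sample-to-term annotations and the sample-to-dataset map.
#' Every annotated term must exist in the DAG. A sample listed under more
#' than one dataset is assigned to a single dataset by a seeded random
#' draw, so downstream dataset-stratified evaluation sees each sample
#' exactly once; the seed is recorded on the object.
#'
#' @param df Data frame with columns `sample_id`, `dataset_id`, `term_id`
#'   (one row per direct annotation).
#' @param dag An [ontology_dag()] used to validate term ids.
#' @param seed Integer seed for resolving samples that appear in several
#'   datasets.
#' @return An object of class `annotation_table`: list with `direct` (named
#'   list sample id -> character vector of term ids), `dataset_of` (named
#'   character vector sample id -> dataset id) and `seed`.
#' @export
annotation_table <- function(df, dag, seed = 1L) {
  stopifnot(inherits(dag, "ontology_dag"))
  needed <- c("sample_id", "dataset_id", "term_id")
  if (!all(needed %in% names(df))) {
    stop("annotation data frame needs columns: ",
         paste(needed, collapse = ", "))
  }
  bad <- setdiff(unique(df$term_id), dag$terms)
  if (length(bad)) {
    stop("annotated term(s) absent from ontology: ",
         paste(bad, collapse = ", "))
  }

  direct <- split(as.character(df$term_id), as.character(df$sample_id))
  direct <- lapply(direct, unique)

  ds_by_sample <- split(as.character(df$dataset_id),
                        as.character(df$sample_id))
  ds_by_sample <- lapply(ds_by_sample, unique)
  dataset_of <- with_seed(seed, {
    vapply(ds_by_sample, function(ds) {
      if (length(ds) == 1L) ds else sample(ds, 1L)
    }, character(1))
  })

  structure(
    list(direct = direct, dataset_of = dataset_of, seed = as.integer(seed)),
    class = "annotation_table"
  )
}

#' Read an annotation TSV
#'
#' @param path TSV with header columns `sample_id`, `dataset_id`, `term_id`.
#' @inheritParams annotation_table
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, dag, seed = 1L) {
  df <- read_tsv_strict(path, c("sample_id", "dataset_id", "term_id"))
  annotation_table(df, dag, seed = seed)
}

#' Propagate direct annotations into sample labels for one term
#'
#' Implements the ontology-aware labelling rule used to build the gold
#' standard: a sample is positive for a term if any of its direct
#' annotations is the term itself or one of its descendants; otherwise it
#' is ignored (removed from training and testing) if any direct annotation
#' is a strict ancestor of the term, because such a sample is ambiguous;
#' all remaining samples are negatives. Positivity takes precedence over
#' the ignore rule.
#'
#' @param dag An [ontology_dag()].
#' @param ann An [annotation_table()].
#' @param term Term id to label.
#' @return Named character vector over samples with values `"pos"`,
#'   `"neg"`, `"ignore"`.
#' @export
propagate_sample_labels <- function(dag, ann, term) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(ann, "annotation_table"))
  if (!term %in% dag$terms) stop("term '", term, "' not in ontology")
  pos_set <- c(term, dag$desc[[term]])
  anc_set <- dag$anc[[term]]
  vapply(ann$direct, function(d) {
    if (any(d %in% pos_set)) "pos"
    else if (any(d %in% anc_set)) "ignore"
    else "neg"
  }, character(1))
}

#' Aggregate sample labels into dataset labels for one term
#'
#' A dataset is positive when a strict majority of its samples are positive
#' for the term; failing that it is ignored when a strict majority of its
#' samples are ignored; otherwise (including exact ties) it is negative.
#'
#' @param sample_labels Named character vector from
#'   [propagate_sample_labels()].
#' @param ann An [annotation_table()] supplying the sample -> dataset map.
#' @return Named character vector over datasets with values `"pos"`,
#'   `"neg"`, `"ignore"`.
#' @export
label_datasets <- function(sample_labels, ann) {
  stopifnot(inherits(ann, "annotation_table"))
  samples <- names(sample_labels)
  ds <- ann$dataset_of[samples]
  if (anyNA(ds)) {
    stop("sample(s) without a dataset: ",
         paste(samples[is.na(ds)], collapse = ", "))
  }
  groups <- split(unname(sample_labels), unname(ds))
  vapply(groups, function(lab) {
    n <- length(lab)
    if (n == 0L) stop("empty dataset encountered")
    if (sum(lab == "pos") > n / 2) "pos"
    else if (sum(lab == "ignore") > n / 2) "ignore"
    else "neg"
  }, character(1))
}

#' Label every candidate term at sample or dataset granularity
#'
#' Convenience wrapper building the full label matrix (entities x terms)
#' by applying [propagate_sample_labels()] (and [label_datasets()] when
#' `granularity = "dataset"`) to each term.
#'
#' @inheritParams propagate_sample_labels
#' @param terms Character vector of term ids; defaults to all DAG terms.
#' @param granularity `"sample"` or `"dataset"`.
#' @return Character matrix with entity rows and term columns; values in
#'   `"pos"`, `"neg"`, `"ignore"`.
#' @export
propagate_labels <- function(dag, ann, terms = NULL,
                             granularity = c("sample", "dataset")) {
  granularity <- match.arg(granularity)
  if (is.null(terms)) terms <- dag$terms
  cols <- lapply(terms, function(tm) {
    sl <- propagate_sample_labels(dag, ann, tm)
    if (granularity == "dataset") label_datasets(sl, ann) else sl
  })
  out <- do.call(cbind, cols)
  colnames(out) <- terms
  out
}

#' Select terms with enough positively labelled datasets to train on
#'
#' Robust training and dataset-stratified evaluation require positives from
#' several independent datasets; terms below the threshold are dropped.
#'
#' @param dataset_labels Character matrix (datasets x terms) from
#'   [propagate_labels()] at dataset granularity, or a named list of
#'   dataset-label vectors per term.
#' @param min_pos_datasets Minimum count of positive datasets (default 3).
#' @return Character vector of retained term ids.
#' @export
select_trainable_terms <- function(dataset_labels, min_pos_datasets = 3L) {
  if (is.list(dataset_labels)) {
    counts <- vapply(dataset_labels, function(v) sum(v == "pos"), numeric(1))
  } else {
    counts <- apply(dataset_labels, 2L, function(v) sum(v == "pos"))
  }
  names(counts)[counts >= min_pos_datasets]
}

#' Map model terms to high-level anatomical systems
#'
#' Each model term is assigned to every system root found among its
#' ancestors (or itself, when the term is a root). Systems whose membership
#' does not exceed `min_models_per_system` are dissolved and their members
#' fall back to their remaining systems, or to `NA` when none survive.
#' Terms with no system-root ancestor are `NA` from the start.
#'
#' @param dag An [ontology_dag()].
#' @param system_roots Character vector of high-level term ids (e.g. the
#'   nervous-system or cardiovascular-system roots).
#' @param model_terms Character vector of terms that have trained models.
#' @param min_models_per_system Systems with member count strictly greater
#'   than this survive (default 8).
#' @return Named list over `model_terms`; each element a character vector
#'   of system root ids, or `NA_character_` for unassigned terms.
#' @export
assign_anatomical_systems <- function(dag, system_roots, model_terms,
                                      min_models_per_system = 8L) {
  stopifnot(inherits(dag, "ontology_dag"))
  bad <- setdiff(system_roots, dag$terms)
  if (length(bad)) {
    stop("system root(s) not in ontology: ", paste(bad, collapse = ", "))
  }
  raw <- lapply(model_terms, function(tm) {
    intersect(system_roots, c(tm, dag$anc[[tm]]))
  })
  names(raw) <- model_terms
  counts <- table(unlist(raw, use.names = FALSE))
  keep <- names(counts)[counts > min_models_per_system]
  out <- lapply(raw, function(s) {
    s <- intersect(s, keep)
    if (length(s)) s else NA_character_
  })
  names(out) <- model_terms
  out
}

#' Write / read label columns as TSV
#'
#' Serialises a label matrix in long form with columns `entity_id`,
#' `term_id`, `label` (values `pos`, `neg`, `ignore`).
#'
#' @param labels Character matrix (entities x terms).
#' @param path Output TSV path.
#' @return `path`, invisibly (`write_labels`); a character matrix
#'   (`read_labels`).
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(
    entity_id = rep(rownames(labels), times = ncol(labels)),
    term_id = rep(colnames(labels), each = nrow(labels)),
    label = as.vector(labels),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read_tsv_strict(path, c("entity_id", "term_id", "label"))
  ents <- unique(df$entity_id)
  terms <- unique(df$term_id)
  out <- matrix(NA_character_, length(ents), length(terms),
                dimnames = list(ents, terms))
  out[cbind(df$entity_id, df$term_id)] <- df$label
  out
}
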