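# Seeded synthetic ontology + metadata corpus generator.
#
# Emits the exact OBO/TSV dialects the rest of the package consumes, with
# controllable tissue signal, so the full pipeline is benchmarkable with
# no external data.

#' Generate a toy anatomy-style ontology
#'
#' Builds a forest of `is_a` trees: one shared root, `n_systems` system
#' roots beneath it, and `terms_per_system` tissue terms under each system
#' arranged so the tree reaches the requested depth (the first `depth`
#' terms of a system form a chain; remaining terms attach to a seeded
#' random earlier term of admissible level). Every term gets a synthetic
#' name and one synonym, so dictionary baselines have surface forms to
#' match. Total term count is `n_systems * terms_per_system + n_systems +
#' 1`.
#'
#' @param n_systems Number of system roots (>= 1).
#' @param terms_per_system Tissue terms under each system (>= 1).
#' @param depth Maximum chain length below a system root (>= 1).
#' @param seed Integer seed.
#' @return List with `dag` (an [ontology_dag()]), `root`, `system_roots`,
#'   `terms_by_system` (named list), and `leaves` (terms without
#'   children).
#' @export
generate_toy_ontology <- function(n_systems = 2L, terms_per_system = 6L,
                                  depth = 3L, seed = 1L) {
  stopifnot(n_systems >= 1L, terms_per_system >= 1L, depth >= 1L)
  root <- "TS:0000000"
  systems <- sprintf("TS:%07d", seq_len(n_systems))
  next_id <- n_systems

  ids <- root
  nm <- stats::setNames("anatomical root", root)
  syn <- stats::setNames(list(character()), root)
  par <- list()

  for (s in seq_len(n_systems)) {
    ids <- c(ids, systems[s])
    nm[systems[s]] <- paste("system", s)
    syn[[systems[s]]] <- paste0("organ system ", s)
    par[[systems[s]]] <- root
  }

  with_seed(seed, {
    for (s in seq_len(n_systems)) {
      level <- integer()        # level below system root, system = 0
      sys_terms <- character()
      for (j in seq_len(terms_per_system)) {
        next_id <- next_id + 1L
        id <- sprintf("TS:%07d", next_id)
        if (j <= depth) {
          parent <- if (j == 1L) systems[s] else sys_terms[j - 1L]
          lev <- j
        } else {
          cand <- c(systems[s], sys_terms)[c(0L, level) < depth]
          parent <- if (length(cand) == 1L) cand else sample(cand, 1L)
          lev <- c(0L, level)[match(parent, c(systems[s], sys_terms))] + 1L
        }
        ids <- c(ids, id)
        nm[id] <- sprintf("tissue %d.%d", s, j)
        syn[[id]] <- sprintf("tissue synonym %d.%d", s, j)
        par[[id]] <- parent
        sys_terms <- c(sys_terms, id)
        level <- c(level, lev)
      }
    }
  })

  dag <- ontology_dag(terms = ids, names = nm, synonyms = syn,
                      parents = par)
  all_parents <- unique(unlist(par, use.names = FALSE))
  tissue_terms <- setdiff(ids, c(root, systems))
  structure(list(
    dag = dag,
    root = root,
    system_roots = systems,
    terms_by_system = stats::setNames(
      lapply(systems, function(sr) intersect(tissue_terms,
                                             dag$desc[[sr]])),
      systems),
    leaves = setdiff(tissue_terms, all_parents)
  ), class = "toy_ontology")
}

#' Serialize an ontology DAG to OBO text
#'
#' Writes `[Term]` stanzas with `id`, `name`, `synonym` (EXACT scope) and
#' `is_a` lines, round-trippable through [parse_obo()].
#'
#' @param dag An [ontology_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (tm in dag$terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", tm), con)
    writeLines(paste0("name: ", dag$name[[tm]]), con)
    for (s in dag$synonyms[[tm]]) {
      writeLines(sprintf("synonym: \"%s\" EXACT []", s), con)
    }
    for (p in dag$parents[[tm]]) {
      writeLines(paste0("is_a: ", p, " ! ", dag$name[[p]]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Specification of a synthetic metadata corpus
#'
#' Defaults emulate the shape of curated expression-sample metadata
#' collections: 16 samples per dataset, free-text descriptions of about 30
#' words, several independent datasets per tissue term, and realistic
#' noise (numeric tokens, URLs, very short tokens) that the cleaning
#' pipeline must remove. `signal` is the fraction of a sample's content
#' words drawn from its term's signature vocabulary (the rest come from a
#' shared background vocabulary); `inherit_frac` is the fraction of each
#' ancestor's signature a term inherits, which makes sibling terms share
#' vocabulary the way related tissues share descriptive language.
#'
#' @param n_datasets_per_term,samples_per_dataset,tokens_per_sample
#'   Corpus shape (tokens per sample is a Poisson mean).
#' @param signature_vocab_size Words in each term's own signature.
#' @param background_vocab_size Words in the shared background vocabulary.
#' @param signal Fraction in `[0, 1]` of signature-drawn content words.
#' @param inherit_frac Fraction of each ancestor signature inherited.
#' @param url_rate,number_rate,short_rate Expected noise tokens per sample.
#' @param sentences_per_dataset Sentences in each dataset description.
#' @param seed Integer seed; identical specs generate identical corpora.
#' @return An object of class `corpus_spec` (a validated list).
#' @export
corpus_spec <- function(n_datasets_per_term = 4L, samples_per_dataset = 16L,
                        tokens_per_sample = 30, signature_vocab_size = 20L,
                        background_vocab_size = 200L, signal = 0.8,
                        inherit_frac = 0.25, url_rate = 0.5,
                        number_rate = 1, short_rate = 0.5,
                        sentences_per_dataset = 3L, seed = 1L) {
  stopifnot(signal >= 0, signal <= 1, n_datasets_per_term >= 1L,
            samples_per_dataset >= 1L)
  structure(as.list(environment()), class = "corpus_spec")
}

# pool of unique pronounceable-ish letter words, 5-8 chars
random_words <- function(n) {
  words <- character(0)
  while (length(words) < n) {
    need <- n - length(words)
    lens <- sample(5:8, 2L * need, replace = TRUE)
    more <- vapply(lens, function(L) {
      paste(sample(letters, L, replace = TRUE), collapse = "")
    }, character(1))
    words <- unique(c(words, more))
  }
  words[seq_len(n)]
}

#' Generate a synthetic metadata corpus over a toy ontology
#'
#' For each annotated term (the ontology's leaves), generates
#' `n_datasets_per_term` datasets of `samples_per_dataset` samples. Each
#' sample's raw text mixes words from the term's effective signature
#' vocabulary (its own signature plus inherited fractions of each
#' ancestor's, so siblings share words) with background words, at the
#' spec's `signal` fraction, and injects URL / numeric / short-token noise
#' that the cleaning pipeline removes. Dataset descriptions are
#' multi-sentence summaries drawn from the member samples' vocabulary.
#' Every sample is directly annotated to exactly one leaf term.
#'
#' @param spec A [corpus_spec()].
#' @param onto A [generate_toy_ontology()] result.
#' @return List with `samples` (data frame `sample_id`, `dataset_id`,
#'   `text`), `datasets` (data frame `dataset_id`, `description`),
#'   `annotations` (data frame `sample_id`, `dataset_id`, `term_id`),
#'   `vocab` (list with `signature`, `effective`, `background`), and
#'   `terms` (the annotated leaf terms).
#' @export
generate_corpus <- function(spec, onto) {
  stopifnot(inherits(spec, "corpus_spec"), inherits(onto, "toy_ontology"))
  dag <- onto$dag
  terms <- onto$leaves
  non_root <- setdiff(dag$terms, onto$root)

  with_seed(spec$seed, {
    pool <- random_words(length(non_root) * spec$signature_vocab_size +
                           spec$background_vocab_size)
    background <- pool[seq_len(spec$background_vocab_size)]
    rest <- pool[-seq_len(spec$background_vocab_size)]
    signature <- stats::setNames(
      split(rest, rep(seq_along(non_root),
                      each = spec$signature_vocab_size)),
      non_root)

    # effective vocabulary: own signature + an inherited slice of every
    # ancestor's signature. The slice is the same for all children, so
    # sibling terms provably share vocabulary (as related tissues share
    # descriptive language) while cross-system terms share none.
    n_inherit <- max(1L, round(spec$inherit_frac *
                                 spec$signature_vocab_size))
    effective <- stats::setNames(lapply(terms, function(tm) {
      up <- intersect(dag$anc[[tm]], non_root)
      inherited <- unlist(lapply(up, function(a) {
        signature[[a]][seq_len(min(n_inherit, length(signature[[a]])))]
      }), use.names = FALSE)
      unique(c(signature[[tm]], inherited))
    }), terms)

    sample_rows <- list()
    dataset_rows <- list()
    ann_rows <- list()
    ds_i <- 0L

    for (tm in terms) {
      for (d in seq_len(spec$n_datasets_per_term)) {
        ds_i <- ds_i + 1L
        ds_id <- sprintf("DS%04d", ds_i)
        member_texts <- character(spec$samples_per_dataset)
        for (s in seq_len(spec$samples_per_dataset)) {
          sm_id <- sprintf("%s.S%02d", ds_id, s)
          n_tok <- max(5L, stats::rpois(1L, spec$tokens_per_sample))
          from_sig <- stats::runif(n_tok) < spec$signal
          toks <- ifelse(
            from_sig,
            sample(effective[[tm]], n_tok, replace = TRUE),
            sample(background, n_tok, replace = TRUE)
          )
          toks <- inject_noise(toks, spec)
          txt <- paste0(paste(toks, collapse = " "), ".")
          member_texts[s] <- txt
          sample_rows[[length(sample_rows) + 1L]] <-
            data.frame(sample_id = sm_id, dataset_id = ds_id, text = txt,
                       stringsAsFactors = FALSE)
          ann_rows[[length(ann_rows) + 1L]] <-
            data.frame(sample_id = sm_id, dataset_id = ds_id, term_id = tm,
                       stringsAsFactors = FALSE)
        }
        sents <- vapply(seq_len(spec$sentences_per_dataset), function(i) {
          n_tok <- max(4L, stats::rpois(1L, spec$tokens_per_sample / 3))
          from_sig <- stats::runif(n_tok) < spec$signal
          toks <- ifelse(from_sig,
                         sample(effective[[tm]], n_tok, replace = TRUE),
                         sample(background, n_tok, replace = TRUE))
          first <- paste0(toupper(substr(toks[1L], 1L, 1L)),
                          substr(toks[1L], 2L, nchar(toks[1L])))
          paste0(paste(c(first, toks[-1L]), collapse = " "), ".")
        }, character(1))
        dataset_rows[[length(dataset_rows) + 1L]] <-
          data.frame(dataset_id = ds_id,
                     description = paste(sents, collapse = " "),
                     stringsAsFactors = FALSE)
      }
    }

    list(
      samples = do.call(rbind, sample_rows),
      datasets = do.call(rbind, dataset_rows),
      annotations = do.call(rbind, ann_rows),
      vocab = list(signature = signature, effective = effective,
                   background = background),
      terms = terms
    )
  })
}

# append URL / numeric / short-token noise; counts ~ Poisson(rate)
inject_noise <- function(toks, spec) {
  n_url <- stats::rpois(1L, spec$url_rate)
  n_num <- stats::rpois(1L, spec$number_rate)
  n_short <- stats::rpois(1L, spec$short_rate)
  noise <- c(
    if (n_url) sprintf("https://repo.example/run%d",
                       sample.int(999L, n_url, replace = TRUE)),
    if (n_num) sprintf("%dhr", sample.int(96L, n_num, replace = TRUE)),
    if (n_short) sample(c("at", "of", "in", "ab"), n_short, replace = TRUE)
  )
  if (!length(noise)) return(toks)
  sample(c(toks, noise))
}
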