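# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed` and
#' restores the caller's state afterwards, so seeded internals (fold
#' planning, synthetic data, hashed embeddings) never perturb user code.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Stable 31-bit string hash (polynomial rolling hash); platform-independent.
string_hash31 <- function(x, seed = 0L) {
  m <- 2147483647  # 2^31 - 1, fits in double arithmetic exactly
  h <- (as.numeric(seed) * 1103515245) %% m
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# read/write helpers for the package's TSV dialects
read_tsv_strict <- function(path, required_cols) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
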