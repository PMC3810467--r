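#' Distance weight for a token pair within a 5-gram
#'
#' Co-occurrence counts are weighted by proximity: adjacent words (distance 1)
#' get weight 4, and the weight falls by one per extra word of separation down
#' to weight 1 at the maximal distance of 4, i.e. `weight = 5 - d`.
#'
#' @param d Integer token distance(s) within a 5-gram; each must be in 1..4.
#' @return Integer weight(s), `5 - d`.
#' @export
#' @examples
#' distance_weight(1:4)
distance_weight <- function(d) {
  if (length(d) == 0 || any(!is.finite(d)) || any(d != as.integer(d)) ||
      any(d < 1) || any(d > 4)) {
    abort("`d` must be integer token distance(s) in 1..4")
  }
  as.integer(5 - d)
}

#' Build a vocabulary from an n-gram table
#'
#' Orders words by descending corpus frequency (total 5-gram count mass over
#' all occurrences) and retains the `row_size` most frequent as row words and
#' the `col_size` most frequent as context (column) words. Ties are broken
#' alphabetically for determinism.
#'
#' @param ngrams Data frame with columns `w1`..`w5` and `count`.
#' @param row_size,col_size Number of row / context words to keep; default all
#'   words seen. `col_size` must not exceed `row_size`, so the context words
#'   are a subset of the row words.
#' @return A `memscale_vocabulary`: list with `row_words`, `col_words`, and the
#'   frequency table `freq`.
#' @export
build_vocabulary <- function(ngrams, row_size = NULL, col_size = NULL) {
  check_columns(ngrams, c(paste0("w", 1:5), "count"), "`ngrams`")
  if (nrow(ngrams) == 0) abort("`ngrams` is empty")
  long <- tidyr::pivot_longer(
    ngrams[, c(paste0("w", 1:5), "count")],
    cols = dplyr::all_of(paste0("w", 1:5)),
    values_to = "word"
  )
  freq <- long %>%
    group_by(.data$word) %>%
    summarise(freq = sum(.data$count), .groups = "drop")
  ord <- order(-freq$freq, freq$word, method = "radix")
  freq <- freq[ord, ]
  n_words <- nrow(freq)
  row_size <- min(row_size %||% n_words, n_words)
  col_size <- min(col_size %||% row_size, n_words)
  if (col_size > row_size) {
    abort("`col_size` must not exceed `row_size`: context words are a subset of row words")
  }
  structure(
    list(
      row_words = freq$word[seq_len(row_size)],
      col_words = freq$word[seq_len(col_size)],
      freq = freq
    ),
    class = "memscale_vocabulary"
  )
}

#' @export
print.memscale_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<memscale_vocabulary> %d row words, %d context words (of %d seen)\n",
    length(x$row_words), length(x$col_words), nrow(x$freq)
  ))
  invisible(x)
}

#' Count distance-weighted co-occurrences from 5-grams
#'
#' Every ordered position pair (i, j), i != j, within each 5-gram contributes
#' `distance_weight(|i - j|) * count` to the cell indexed by (row word at i,
#' context word at j). Tokens outside the respective vocabulary contribute
#' nothing.
#'
#' @param ngrams Data frame with columns `w1`..`w5` and `count` (each
#'   `count >= 1`).
#' @param vocab A [build_vocabulary()] result.
#' @return A `cooc_matrix`: sparse non-negative matrix (rows = row words,
#'   columns = context words) with a `log_normalized` flag set to `FALSE`.
#' @export
count_cooccurrences <- function(ngrams, vocab) {
  if (!inherits(vocab, "memscale_vocabulary")) {
    abort("`vocab` must come from build_vocabulary()")
  }
  check_columns(ngrams, c(paste0("w", 1:5), "count"), "`ngrams`")
  if (nrow(ngrams) == 0) abort("`ngrams` is empty: cannot build a co-occurrence matrix")
  if (any(!is.finite(ngrams$count)) || any(ngrams$count < 1)) {
    bad <- which(!is.finite(ngrams$count) | ngrams$count < 1)[1]
    abort(sprintf("record %d has an invalid count (must be >= 1)", bad))
  }
  tok <- lapply(paste0("w", 1:5), function(cn) as.character(ngrams[[cn]]))
  row_idx <- lapply(tok, match, table = vocab$row_words)
  col_idx <- lapply(tok, match, table = vocab$col_words)
  ii <- jj <- xx <- vector("list", 20L)
  slot <- 0L
  for (i in 1:5) {
    for (j in 1:5) {
      if (i == j) next
      slot <- slot + 1L
      ri <- row_idx[[i]]
      cj <- col_idx[[j]]
      keep <- !is.na(ri) & !is.na(cj)
      ii[[slot]] <- ri[keep]
      jj[[slot]] <- cj[keep]
      xx[[slot]] <- distance_weight(abs(i - j)) * ngrams$count[keep]
    }
  }
  m <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(length(vocab$row_words), length(vocab$col_words)),
    dimnames = list(vocab$row_words, vocab$col_words)
  )
  structure(
    list(matrix = m, log_normalized = FALSE),
    class = "cooc_matrix"
  )
}

#' Log-scale a co-occurrence matrix
#'
#' Replaces every cell by `log(cell + 1)` (natural log; zero cells stay zero).
#' Applying the transform twice is an error.
#'
#' @param cooc A `cooc_matrix` from [count_cooccurrences()].
#' @return The matrix with all cells log-scaled and `log_normalized = TRUE`.
#' @export
log_normalize <- function(cooc) {
  if (!inherits(cooc, "cooc_matrix")) abort("`cooc` must be a cooc_matrix")
  if (isTRUE(cooc$log_normalized)) {
    abort("matrix is already log-normalized; refusing to apply log(x + 1) twice")
  }
  m <- cooc$matrix
  if (methods::is(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- log1p(m@x)
  } else {
    m <- log1p(m)
  }
  structure(list(matrix = m, log_normalized = TRUE), class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf(
    "<cooc_matrix> %d x %d, %s, %d nonzero cells\n",
    nrow(x$matrix), ncol(x$matrix),
    if (x$log_normalized) "log-normalized" else "raw weighted counts",
    Matrix::nnzero(x$matrix)
  ))
  invisible(x)
}
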