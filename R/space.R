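#' Build a semantic space by singular value decomposition
#'
#' Decomposes a log-normalized co-occurrence matrix as `M = U S V'` and
#' represents each row word by the first `k` coordinates of `U S` (left
#' singular vectors scaled by their singular values, in descending
#' singular-value order), normalized to unit length. This projection preserves
#' the row geometry of `M`: at full rank, pairwise cosines of the unnormalized
#' projections equal pairwise cosines of the raw rows. Rows whose k-dimensional
#' projection is (numerically) the zero vector are dropped from the space and
#' recorded in the `dropped` field.
#'
#' @param cooc A log-normalized `cooc_matrix` (see [log_normalize()]).
#' @param k Target dimensionality, `1 <= k <= rank(M)`.
#' @return A `semantic_space`: list with `vectors` (words x k unit-row matrix),
#'   `k`, `dropped` (words excluded for zero projection), and `selection`
#'   (populated when the space comes from [select_dimensionality()]).
#' @export
build_space <- function(cooc, k) {
  if (!inherits(cooc, "cooc_matrix")) abort("`cooc` must be a cooc_matrix")
  if (!isTRUE(cooc$log_normalized)) {
    abort("co-occurrence matrix must be log-normalized before SVD (see log_normalize())")
  }
  sv <- svd(as.matrix(cooc$matrix))
  space_from_svd(sv, k, rownames(cooc$matrix))
}

# Shared by build_space() and select_dimensionality(): turn a precomputed SVD
# into a unit-vector space at dimensionality k.
space_from_svd <- function(sv, k, words) {
  rank_m <- sum(sv$d > length(sv$d) * .Machine$double.eps * sv$d[1])
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
    abort("`k` must be a single positive integer")
  }
  if (k > rank_m) {
    abort(sprintf("`k` = %d exceeds the attained matrix rank %d", k, rank_m))
  }
  proj <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], nrow = k)
  rownames(proj) <- words
  un <- unit_rows(proj)
  dropped <- words[un$dropped]
  if (length(dropped) > 0) {
    inform(sprintf(
      "dropping %d word(s) with zero projection at k = %d: %s",
      length(dropped), k, paste(head(dropped, 10), collapse = ", ")
    ))
  }
  structure(
    list(vectors = un$vectors, k = as.integer(k), dropped = dropped,
         selection = NULL),
    class = "semantic_space"
  )
}

#' Construct a semantic space from a matrix of word vectors
#'
#' Low-level constructor, mainly for tests and for loading externally built
#' spaces: rows are words (rownames required) and are unit-normalized; zero
#' rows are dropped.
#'
#' @param vectors Numeric matrix with one row per word; rownames are the words.
#' @return A `semantic_space`.
#' @export
as_semantic_space <- function(vectors) {
  if (!is.matrix(vectors) || is.null(rownames(vectors))) {
    abort("`vectors` must be a numeric matrix with words as rownames")
  }
  un <- unit_rows(vectors)
  structure(
    list(vectors = un$vectors, k = ncol(vectors),
         dropped = rownames(vectors)[un$dropped], selection = NULL),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf(
    "<semantic_space> %d words x %d dimensions (unit vectors)%s\n",
    nrow(x$vectors), x$k,
    if (length(x$dropped) > 0) sprintf(", %d dropped", length(x$dropped)) else ""
  ))
  if (!is.null(x$selection)) {
    cat(sprintf("  dimensionality selected by synonym test (score %.3f)\n",
                x$selection$results$score[x$selection$results$k == x$k]))
  }
  invisible(x)
}

#' Words present in a semantic space
#' @param space A `semantic_space`.
#' @return Character vector of words.
#' @export
space_words <- function(space) {
  rownames(space$vectors)
}

#' Cosine similarity between two words
#'
#' Since all word vectors are unit length the cosine is the plain dot product;
#' it is symmetric and bounded in \[-1, 1\].
#'
#' @param space A `semantic_space`.
#' @param w1,w2 Words, both present in the space.
#' @return Cosine of the angle between the two word vectors.
#' @export
cosine_similarity <- function(space, w1, w2) {
  for (w in c(w1, w2)) {
    if (!w %in% rownames(space$vectors)) {
      abort(sprintf("word not in space: \"%s\"", w))
    }
  }
  sum(space$vectors[w1, ] * space$vectors[w2, ])
}
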