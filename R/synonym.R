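#' Synonym percentile test of a semantic space
#'
#' Scores a space by how highly synonym pairs rank among random word pairs:
#' for each synonym pair the cosine similarity is compared with `n_random`
#' seeded random in-space word pairs, and its percentile rank is the percentage
#' of random pairs with a strictly greater cosine (ties count one half). The
#' score is the median percentile across synonym pairs — low is good (0 means
#' every synonym pair beats all its random pairs; 50 is chance level).
#'
#' Random pairs are drawn with replacement from the in-space words, excluding
#' self-pairs. Synonym pairs with either word missing from the space are
#' dropped with a warning.
#'
#' @param space A `semantic_space`.
#' @param pairs Data frame whose first two columns hold the synonym pairs.
#' @param n_random Number of random pairs per synonym pair (at least 100).
#' @param seed Integer seed for the random-pair draws (mandatory).
#' @return Median percentile score in \[0, 100\].
#' @export
synonym_test <- function(space, pairs, n_random = 1000, seed) {
  if (missing(seed)) abort("`seed` is mandatory for the synonym test")
  if (n_random < 100) abort("`n_random` must be at least 100")
  pairs <- as.data.frame(pairs)[, 1:2]
  names(pairs) <- c("word1", "word2")
  words <- rownames(space$vectors)
  if (length(words) < 2) abort("space has fewer than 2 words")
  usable <- pairs$word1 %in% words & pairs$word2 %in% words
  if (!any(usable)) {
    abort(sprintf(
      "no synonym pair has both words in the space; dropped pairs: %s",
      paste(sprintf("%s/%s", pairs$word1, pairs$word2), collapse = ", ")
    ))
  }
  if (any(!usable)) {
    warn(sprintf(
      "dropping %d synonym pair(s) with out-of-space words: %s",
      sum(!usable),
      paste(sprintf("%s/%s", pairs$word1[!usable], pairs$word2[!usable]),
            collapse = ", ")
    ))
  }
  pairs <- pairs[usable, , drop = FALSE]
  V <- space$vectors
  n_words <- nrow(V)
  withr::with_seed(seed, {
    scores <- vapply(seq_len(nrow(pairs)), function(p) {
      syn_cos <- sum(V[pairs$word1[p], ] * V[pairs$word2[p], ])
      i <- sample.int(n_words, n_random, replace = TRUE)
      j <- sample.int(n_words, n_random, replace = TRUE)
      while (any(self <- i == j)) {
        j[self] <- sample.int(n_words, sum(self), replace = TRUE)
      }
      rand_cos <- rowSums(V[i, , drop = FALSE] * V[j, , drop = FALSE])
      100 * (sum(rand_cos > syn_cos) + 0.5 * sum(rand_cos == syn_cos)) / n_random
    }, numeric(1))
  })
  stats::median(scores)
}

#' Select space dimensionality by the synonym test
#'
#' Builds one space per candidate dimensionality (by default the doubling grid
#' 1, 2, 4, 8, ... up to the matrix rank), scores each with [synonym_test()]
#' under a common seed, and selects the dimensionality with the lowest (best)
#' median percentile score; ties go to the smallest `k`. The SVD is computed
#' once and reused across candidates.
#'
#' @param cooc A log-normalized `cooc_matrix`.
#' @param pairs Synonym pairs as in [synonym_test()].
#' @param k_grid Candidate dimensionalities; default doubling grid up to rank.
#' @param n_random,seed Passed to [synonym_test()].
#' @return A `synonym_selection`: list with `results` (tibble of `k`, `score`),
#'   `chosen_k`, `n_random` and `seed`. Use [build_selected_space()] to
#'   materialize the winning space.
#' @export
select_dimensionality <- function(cooc, pairs, k_grid = NULL, n_random = 1000,
                                  seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (!inherits(cooc, "cooc_matrix") || !isTRUE(cooc$log_normalized)) {
    abort("`cooc` must be a log-normalized cooc_matrix")
  }
  sv <- svd(as.matrix(cooc$matrix))
  rank_m <- sum(sv$d > length(sv$d) * .Machine$double.eps * sv$d[1])
  if (is.null(k_grid)) {
    k_grid <- 2^(0:floor(log2(rank_m)))
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0) abort("`k_grid` is empty")
  if (any(k_grid > rank_m)) {
    abort(sprintf(
      "k_grid values %s exceed the attained matrix rank %d",
      paste(k_grid[k_grid > rank_m], collapse = ", "), rank_m
    ))
  }
  words <- rownames(cooc$matrix)
  scores <- vapply(k_grid, function(k) {
    space_k <- withCallingHandlers(
      space_from_svd(sv, k, words),
      message = function(m) invokeRestart("muffleMessage")
    )
    tryCatch(
      synonym_test(space_k, pairs, n_random = n_random, seed = seed),
      error = function(e) abort(sprintf("synonym test failed at k = %d: %s",
                                        k, conditionMessage(e)))
    )
  }, numeric(1))
  results <- tibble(k = k_grid, score = scores)
  chosen <- results$k[order(results$score, results$k)][1]
  structure(
    list(results = results, chosen_k = as.integer(chosen),
         n_random = n_random, seed = seed, svd = sv, words = words),
    class = "synonym_selection"
  )
}

#' Build the space at the selected dimensionality
#'
#' @param selection A `synonym_selection` from [select_dimensionality()].
#' @param k Dimensionality to build; defaults to the chosen one.
#' @return A `semantic_space` carrying the selection record.
#' @export
build_selected_space <- function(selection, k = selection$chosen_k) {
  if (!inherits(selection, "synonym_selection")) {
    abort("`selection` must come from select_dimensionality()")
  }
  space <- space_from_svd(selection$svd, k, selection$words)
  space$selection <- list(
    results = selection$results, chosen_k = selection$chosen_k,
    n_random = selection$n_random, seed = selection$seed
  )
  space
}

#' @export
print.synonym_selection <- function(x, ...) {
  cat(sprintf(
    "<synonym_selection> chosen k = %d (median synonym percentile %.2f)\n",
    x$chosen_k, min(x$results$score)
  ))
  print(x$results, n = nrow(x$results))
  invisible(x)
}

#' @rdname select_dimensionality
#' @param x A `synonym_selection`.
#' @param ... Unused.
#' @export
tidy.synonym_selection <- function(x, ...) {
  mutate(x$results, chosen = .data$k == x$chosen_k)
}

#' @rdname select_dimensionality
#' @export
glance.synonym_selection <- function(x, ...) {
  tibble(
    chosen_k = x$chosen_k,
    best_score = min(x$results$score),
    n_candidates = nrow(x$results),
    n_random = x$n_random,
    seed = x$seed
  )
}

#' @rdname select_dimensionality
#' @param object A `synonym_selection`.
#' @export
autoplot.synonym_selection <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(
      x = "dimensions (log2 grid)",
      y = "median synonym percentile (lower is better)",
      title = "Synonym-test dimensionality selection"
    ) +
    ggplot2::theme_minimal()
}
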