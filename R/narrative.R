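#' Tokenize narrative text
#'
#' Lowercases and splits on whitespace; punctuation marks are emitted as
#' separate tokens (they carry the `interpunction` word class). Deterministic;
#' empty text yields an empty token vector.
#'
#' @param text Character vector of narrative texts.
#' @return A list with one character vector of tokens per input element.
#' @export
#' @examples
#' tokenize("Jag minns havet.")
tokenize <- function(text) {
  stringr::str_extract_all(
    stringr::str_to_lower(text),
    "[\\p{L}\\p{N}]+|[\\p{P}\\p{S}]"
  )
}

#' Tag tokens with word classes
#'
#' @param tokens Character vector of tokens.
#' @param lexicon Data frame with columns `word` and `word_class`; classes must
#'   be drawn from [word_classes()].
#' @return Tibble with columns `token` and `word_class`; tokens absent from the
#'   lexicon get the `"untagged"` sentinel. Token order is preserved.
#' @export
tag_word_classes <- function(tokens, lexicon) {
  validate_lexicon(lexicon)
  cls <- lexicon$word_class[match(tokens, lexicon$word)]
  cls[is.na(cls)] <- "untagged"
  tibble(token = tokens, word_class = cls)
}

validate_lexicon <- function(lexicon) {
  check_columns(lexicon, c("word", "word_class"), "`lexicon`")
  bad <- setdiff(unique(lexicon$word_class), word_classes())
  if (length(bad) > 0) {
    abort(sprintf("lexicon contains unknown word class(es): %s",
                  paste(bad, collapse = ", ")))
  }
  invisible(lexicon)
}

#' Aggregate narratives into participant vectors
#'
#' Summarizes each participant's narratives in the semantic space by summing
#' the word vector of every in-space token occurrence (each token weighted
#' equally, repeats counted repeatedly) and normalizing the sum to unit length.
#' With `by_class = TRUE` the aggregation is done separately within each word
#' class (untagged tokens belong to the all-words scope only).
#'
#' A participant whose scope contains no in-space token — or whose token
#' vectors cancel to the zero vector — has no representation: the row is kept
#' with a `NULL` entry in the `vector` list-column rather than a zero vector.
#'
#' @param narratives Data frame with columns `participant_id`, `condition`,
#'   `cue_id`, `text`; all narratives of a participant must share one
#'   condition.
#' @param space A `semantic_space`.
#' @param lexicon Word-class lexicon (required when `by_class = TRUE`).
#' @param by_class Aggregate per word class instead of over all words.
#' @return Tibble with columns `participant_id`, `condition`, `scope`
#'   (`"all"` or a word class), `n_tokens_used`, `n_tokens_oov`,
#'   `vector_norm` (Euclidean norm of the pre-normalization token-vector sum),
#'   and `vector` (list-column of unit k-vectors, `NULL` when absent).
#' @export
aggregate_participants <- function(narratives, space, lexicon = NULL,
                                   by_class = FALSE) {
  check_columns(narratives, c("participant_id", "condition", "cue_id", "text"),
                "`narratives`")
  check_conditions(narratives$condition)
  cond_per_p <- distinct(narratives, .data$participant_id, .data$condition)
  if (anyDuplicated(cond_per_p$participant_id) > 0) {
    abort("each participant must appear under a single condition")
  }
  toks <- tokenize(narratives$text)
  long <- tibble(
    participant_id = rep(narratives$participant_id, lengths(toks)),
    token = unlist(toks, use.names = FALSE)
  )
  if (by_class) {
    if (is.null(lexicon)) abort("`lexicon` is required when by_class = TRUE")
    tagged <- tag_word_classes(long$token, lexicon)
    long$scope <- tagged$word_class
    long <- filter(long, .data$scope != "untagged")
  } else {
    long$scope <- "all"
  }
  V <- space$vectors
  long$word_idx <- match(long$token, rownames(V))
  scopes <- if (by_class) word_classes() else "all"
  grid <- tidyr::expand_grid(
    participant_id = cond_per_p$participant_id,
    scope = scopes
  )
  tallies <- long %>%
    group_by(.data$participant_id, .data$scope) %>%
    summarise(
      n_tokens_used = sum(!is.na(.data$word_idx)),
      n_tokens_oov = sum(is.na(.data$word_idx)),
      .groups = "drop"
    )
  used <- filter(long, !is.na(.data$word_idx))
  key <- paste(used$participant_id, used$scope, sep = "\r")
  sums <- rowsum(V[used$word_idx, , drop = FALSE], group = key)
  norms <- sqrt(rowSums(sums^2))
  out <- grid %>%
    left_join(cond_per_p, by = "participant_id") %>%
    left_join(tallies, by = c("participant_id", "scope")) %>%
    mutate(
      n_tokens_used = dplyr::coalesce(.data$n_tokens_used, 0L),
      n_tokens_oov = dplyr::coalesce(.data$n_tokens_oov, 0L)
    )
  out_key <- paste(out$participant_id, out$scope, sep = "\r")
  pos <- match(out_key, rownames(sums))
  out$vector_norm <- ifelse(is.na(pos), 0, norms[pos])
  out$vector <- lapply(seq_len(nrow(out)), function(r) {
    i <- pos[r]
    if (is.na(i) || norms[i] <= 1e-12) NULL else sums[i, ] / norms[i]
  })
  select(out, "participant_id", "condition", "scope",
         "n_tokens_used", "n_tokens_oov", "vector_norm", "vector")
}

#' Representation matrix for one scope
#'
#' Extracts the participants that have a representation in the given scope as
#' a numeric matrix (one unit row vector per participant), with the matching
#' condition labels attached.
#'
#' @param representations Output of [aggregate_participants()].
#' @param scope Which scope to extract (default `"all"`).
#' @return Matrix with participant ids as rownames and attribute `conditions`.
#' @export
representation_matrix <- function(representations, scope = "all") {
  rows <- filter(representations, .data$scope == !!scope,
                 !vapply(.data$vector, is.null, logical(1)))
  if (nrow(rows) == 0) {
    abort(sprintf("no participant has a representation in scope \"%s\"", scope))
  }
  X <- do.call(rbind, rows$vector)
  rownames(X) <- rows$participant_id
  attr(X, "conditions") <- rows$condition
  X
}
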