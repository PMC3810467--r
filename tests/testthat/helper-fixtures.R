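# Shared fixtures, built lazily and cached for the whole test run.
# The default bundle/space reflect the study conditions the generator encodes:
# 80 participants (20 per condition), 15 cues, ~2/3 retrieval success, a
# 120-word 8-topic corpus with 2 planted synonym pairs per topic.

fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

default_config <- function(...) {
  generator_config(seed = 42, ...)
}

default_bundle <- function() {
  memoize("bundle", simulate_bundle(default_config()))
}

default_space <- function() {
  memoize("space", {
    b <- default_bundle()
    vocab <- build_vocabulary(b$ngrams, col_size = 60)
    cooc <- log_normalize(count_cooccurrences(b$ngrams, vocab))
    sel <- select_dimensionality(cooc, b$synonyms, seed = 4242)
    suppressMessages(build_selected_space(sel))
  })
}

# A tiny deterministic space with hand-controllable vectors.
toy_space <- function(vectors) {
  as_semantic_space(vectors)
}

# Brute-force co-occurrence oracle: enumerate every record and every ordered
# position pair; dense accumulation. Independent of count_cooccurrences().
brute_cooc <- function(ngrams, row_words, col_words) {
  m <- matrix(0, length(row_words), length(col_words),
              dimnames = list(row_words, col_words))
  for (r in seq_len(nrow(ngrams))) {
    toks <- as.character(unlist(ngrams[r, paste0("w", 1:5)]))
    for (i in 1:5) {
      for (j in 1:5) {
        if (i == j) next
        if (toks[i] %in% row_words && toks[j] %in% col_words) {
          m[toks[i], toks[j]] <- m[toks[i], toks[j]] +
            (5 - abs(i - j)) * ngrams$count[r]
        }
      }
    }
  }
  m
}

# Build a scale matrix from freshly generated narratives in the default space.
scale_matrix_for <- function(cfg, rep_seed, scope = "all") {
  narr <- generate_narratives(cfg, seed = rep_seed)
  reps <- aggregate_participants(narr$narratives, default_space(),
                                 lexicon = narr$lexicon,
                                 by_class = scope == "classes")
  suppressMessages(semantic_scale_matrix(reps, scope = scope))
}

# Random small n-gram table over a given alphabet (deterministic via seed).
random_ngrams <- function(n, alphabet, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      w1 = sample(alphabet, n, TRUE), w2 = sample(alphabet, n, TRUE),
      w3 = sample(alphabet, n, TRUE), w4 = sample(alphabet, n, TRUE),
      w5 = sample(alphabet, n, TRUE), count = sample(1:5, n, TRUE)
    )
  })
}
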