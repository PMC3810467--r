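#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic study: a topic-structured 5-gram corpus with planted
#' synonym pairs, a word-class lexicon, and condition-labelled participant
#' narratives. Words are partitioned into latent topics; each unimodal cue
#' condition draws its narrative tokens from a topic mixture that leans
#' towards that condition's signature topic by `effect_size`, and the
#' multimodal condition mixes the three unimodal distributions with
#' `multimodal_weights`, optionally blended with a fresh "supra-additive"
#' topic of its own (`supra_weight > 0`), the geometric signature of
#' supra-additive multimodal retrieval.
#'
#' The default study shape mirrors the design the pipeline targets: 80
#' participants, 20 per condition, 15 cues each, with retrieval succeeding at
#' rate 798/1200 so roughly 800 narratives result.
#'
#' @param seed Integer seed (mandatory); drives the deterministic topic /
#'   lexicon structure and the default corpus and narrative draws.
#' @param vocab_size Number of corpus words (partitioned evenly into topics).
#' @param n_topics Number of latent topics (at most `vocab_size / 2`).
#' @param synonym_pairs_per_topic Planted synonym pairs per topic; the two
#'   words of a pair share an identical emission probability.
#' @param n_ngrams Number of 5-gram draws for the corpus.
#' @param epsilon Per-token cross-topic leak probability in corpus generation.
#' @param n_participants Total participants.
#' @param condition_n Named participant counts per condition (must sum to
#'   `n_participants`).
#' @param cues_per_participant Retrieval cues presented per participant.
#' @param retrieval_success Probability a cue yields a narrative.
#' @param tokens_mean,tokens_dispersion Negative-binomial narrative length
#'   (mean and size); a floor of 5 tokens is applied.
#' @param effect_size Mixture weight on the signature topic, in \[0, 1):
#'   0 means all conditions share the uniform topic mixture (null data). The
#'   default 0.015 is calibrated (via [calibrate_effect_size()]) so that the
#'   population standardized difference between a unimodal condition and the
#'   pooled rest along its signal axis is about 0.8 under the default study
#'   shape — a large effect of the order the modality-comparison literature
#'   reports.
#' @param condition_effects Named per-unimodal-condition multipliers on
#'   `effect_size` (default 1 for each); set e.g. `c(visual = 1, auditory = 0,
#'   olfactory = 0)` to plant a visual-only signal.
#' @param signature_topics Named topic indices for the three unimodal
#'   conditions.
#' @param supra_topic Topic index reserved for the supra-additive component.
#' @param multimodal_weights Named convex weights over the unimodal mixtures.
#' @param supra_weight Weight of the supra-additive topic in the multimodal
#'   mixture, in \[0, 1\].
#' @param class_proportions Named proportions over the 14 word classes used to
#'   assign lexicon classes; the `interpunction` share is emitted as "."
#'   tokens.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             vocab_size = 120,
                             n_topics = 8,
                             synonym_pairs_per_topic = 2,
                             n_ngrams = 30000,
                             epsilon = 0.05,
                             n_participants = 80,
                             condition_n = c(visual = 20, auditory = 20,
                                             olfactory = 20, multimodal = 20),
                             cues_per_participant = 15,
                             retrieval_success = 798 / 1200,
                             tokens_mean = 40,
                             tokens_dispersion = 10,
                             effect_size = 0.015,
                             condition_effects = c(visual = 1, auditory = 1,
                                                   olfactory = 1),
                             signature_topics = c(visual = 1, auditory = 2,
                                                  olfactory = 3),
                             supra_topic = 4,
                             multimodal_weights = c(visual = 1 / 3,
                                                    auditory = 1 / 3,
                                                    olfactory = 1 / 3),
                             supra_weight = 0,
                             class_proportions = default_class_proportions()) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (n_topics > vocab_size / 2) {
    abort("`n_topics` must not exceed vocab_size / 2")
  }
  if (vocab_size %% n_topics != 0) {
    abort("`vocab_size` must be divisible by `n_topics`")
  }
  words_per_topic <- vocab_size / n_topics
  if (2 * synonym_pairs_per_topic > words_per_topic) {
    abort("too many synonym pairs per topic for the topic size")
  }
  if (!setequal(names(condition_n), cue_conditions())) {
    abort("`condition_n` must name all four conditions")
  }
  if (sum(condition_n) != n_participants) {
    abort("`condition_n` must sum to `n_participants`")
  }
  if (abs(sum(multimodal_weights) - 1) > 1e-9) {
    abort("`multimodal_weights` must sum to 1")
  }
  if (!setequal(names(multimodal_weights), unimodal_conditions())) {
    abort("`multimodal_weights` must name the three unimodal conditions")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9 ||
      !setequal(names(class_proportions), word_classes())) {
    abort("`class_proportions` must be a probability vector over the 14 word classes")
  }
  if (effect_size < 0 || effect_size >= 1) abort("`effect_size` must be in [0, 1)")
  if (!setequal(names(condition_effects), unimodal_conditions()) ||
      any(condition_effects < 0) || any(condition_effects * effect_size >= 1)) {
    abort("`condition_effects` must name the unimodal conditions with nonnegative multipliers keeping each effect below 1")
  }
  if (supra_weight < 0 || supra_weight > 1) abort("`supra_weight` must be in [0, 1]")
  if (any(c(signature_topics, supra_topic) > n_topics)) {
    abort("signature/supra topic indices must not exceed `n_topics`")
  }
  structure(
    list(
      seed = as.integer(seed), vocab_size = vocab_size, n_topics = n_topics,
      words_per_topic = words_per_topic,
      synonym_pairs_per_topic = synonym_pairs_per_topic,
      n_ngrams = n_ngrams, epsilon = epsilon,
      n_participants = n_participants,
      condition_n = condition_n[cue_conditions()],
      cues_per_participant = cues_per_participant,
      retrieval_success = retrieval_success,
      tokens_mean = tokens_mean, tokens_dispersion = tokens_dispersion,
      effect_size = effect_size,
      condition_effects = condition_effects[unimodal_conditions()],
      signature_topics = signature_topics, supra_topic = supra_topic,
      multimodal_weights = multimodal_weights[unimodal_conditions()],
      supra_weight = supra_weight,
      class_proportions = class_proportions[word_classes()]
    ),
    class = "generator_config"
  )
}

#' Default word-class token proportions
#'
#' Roughly realistic running-text proportions over the 14 word classes, used
#' to assign lexicon classes to synthetic vocabulary words (the interpunction
#' share is realized as "." tokens in the narratives).
#'
#' @return Named numeric vector over [word_classes()], summing to 1.
#' @export
default_class_proportions <- function() {
  c(
    noun = 0.21, adjective = 0.07, proper_name = 0.03, verb = 0.16,
    adverb = 0.08, participle = 0.02, pronoun = 0.11, conjunction = 0.05,
    determiner = 0.06, counting_word = 0.02, particle = 0.02,
    preposition = 0.10, interpunction = 0.06, interjection = 0.01
  )
}

# Deterministic latent structure shared by the corpus and the narratives:
# topic partition of the vocabulary, within-topic Zipf emission probabilities
# (equalized within synonym pairs), synonym list, and the word-class lexicon.
# Depends only on config$seed.
topic_structure <- function(config) {
  wpt <- config$words_per_topic
  words <- sprintf("w%03d", seq_len(config$vocab_size))
  topic_of <- rep(seq_len(config$n_topics), each = wpt)
  emission <- 1 / seq_len(wpt)
  for (p in seq_len(config$synonym_pairs_per_topic)) {
    idx <- c(2 * p - 1, 2 * p)
    emission[idx] <- mean(emission[idx])
  }
  emission <- emission / sum(emission)
  synonyms <- purrr::map_dfr(seq_len(config$n_topics), function(t) {
    base <- (t - 1) * wpt
    purrr::map_dfr(seq_len(config$synonym_pairs_per_topic), function(p) {
      tibble(word1 = words[base + 2 * p - 1], word2 = words[base + 2 * p])
    })
  })
  word_cls <- setdiff(word_classes(), "interpunction")
  props <- config$class_proportions[word_cls]
  props <- props / sum(props)
  lexicon_classes <- withr::with_seed(
    config$seed,
    sample(word_cls, config$vocab_size, replace = TRUE, prob = props)
  )
  lexicon <- bind_rows(
    tibble(word = words, word_class = lexicon_classes),
    tibble(word = ".", word_class = "interpunction")
  )
  # per-topic word emission over the full vocabulary
  emis_matrix <- matrix(0, nrow = config$vocab_size, ncol = config$n_topics,
                        dimnames = list(words, NULL))
  for (t in seq_len(config$n_topics)) {
    emis_matrix[topic_of == t, t] <- emission
  }
  list(words = words, topic_of = topic_of, emission = emission,
       emission_matrix = emis_matrix, synonyms = synonyms, lexicon = lexicon)
}

# Topic mixture (over topics) per condition given the config.
condition_mixtures <- function(config) {
  k <- config$n_topics
  base <- rep(1 / k, k)
  mix <- matrix(base, nrow = k, ncol = 4,
                dimnames = list(NULL, cue_conditions()))
  for (u in unimodal_conditions()) {
    lambda <- config$effect_size * config$condition_effects[[u]]
    sig <- config$signature_topics[[u]]
    mix[, u] <- (1 - lambda) * base
    mix[sig, u] <- mix[sig, u] + lambda
  }
  mm <- as.vector(mix[, unimodal_conditions()] %*% config$multimodal_weights)
  if (config$supra_weight > 0) {
    supra <- numeric(k)
    supra[config$supra_topic] <- 1
    mm <- (1 - config$supra_weight) * mm + config$supra_weight * supra
  }
  mix[, "multimodal"] <- mm
  mix
}

#' Generate a synthetic 5-gram corpus with planted synonyms
#'
#' Draws `n_ngrams` 5-grams by sampling a topic uniformly, then 5 words from
#' that topic's Zipf-shaped word distribution; each token independently leaks
#' to a random other topic with probability `epsilon`. Identical 5-grams are
#' aggregated into counts. Synonym pairs are same-topic word pairs with
#' identical emission probabilities, so their co-occurrence profiles match.
#'
#' @param config A [generator_config()].
#' @param seed Seed for the corpus draws (default `config$seed + 1`).
#' @return List with `ngrams` (tibble `w1`..`w5`, `count`), `synonyms`,
#'   `lexicon`, `vocabulary` (words), and `ground_truth`.
#' @export
generate_corpus <- function(config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "generator_config"))
  st <- topic_structure(config)
  wpt <- config$words_per_topic
  withr::with_seed(seed, {
    topics <- sample.int(config$n_topics, config$n_ngrams, replace = TRUE)
    slots <- matrix("", nrow = config$n_ngrams, ncol = 5)
    for (s in 1:5) {
      slot_topic <- topics
      leak <- runif(config$n_ngrams) < config$epsilon
      if (any(leak)) {
        slot_topic[leak] <- sample.int(config$n_topics, sum(leak), replace = TRUE)
      }
      within_rank <- sample.int(wpt, config$n_ngrams, replace = TRUE,
                                prob = st$emission)
      slots[, s] <- st$words[(slot_topic - 1) * wpt + within_rank]
    }
  })
  ngrams <- as_tibble(slots, .name_repair = ~paste0("w", 1:5)) %>%
    count(dplyr::across(dplyr::everything()), name = "count") %>%
    ungroup()
  list(
    ngrams = ngrams,
    synonyms = st$synonyms,
    lexicon = st$lexicon,
    vocabulary = st$words,
    ground_truth = list(
      topic_of = stats::setNames(st$topic_of, st$words),
      emission = st$emission,
      seed = seed
    )
  )
}

#' Generate condition-labelled synthetic narratives
#'
#' Assigns participants to conditions, samples which cues yield a narrative
#' (retrieval succeeds with `retrieval_success`), draws narrative lengths from
#' a negative binomial, and emits each token from the participant condition's
#' word distribution (the topic mixture of [generator_config()] pushed through
#' the per-topic emissions). The interpunction share of `class_proportions` is
#' emitted as "." tokens.
#'
#' @param config A [generator_config()].
#' @param seed Seed for the narrative draws (default `config$seed + 2`).
#' @return List with `narratives` (tibble `participant_id`, `condition`,
#'   `cue_id`, `text`), `lexicon`, and `ground_truth` (condition mixtures and
#'   word distributions, the multimodal rule, topic assignments).
#' @export
generate_narratives <- function(config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "generator_config"))
  st <- topic_structure(config)
  mix <- condition_mixtures(config)
  word_dist <- st$emission_matrix %*% mix  # vocab x condition
  p_dot <- config$class_proportions[["interpunction"]]
  participants <- tibble(
    participant_id = sprintf("p%03d", seq_len(config$n_participants)),
    condition = rep(cue_conditions(), times = config$condition_n)
  )
  withr::with_seed(seed, {
    cue_grid <- tidyr::expand_grid(
      participant_id = participants$participant_id,
      cue_id = sprintf("cue%02d", seq_len(config$cues_per_participant))
    ) %>%
      left_join(participants, by = "participant_id")
    retrieved <- runif(nrow(cue_grid)) < config$retrieval_success
    cue_grid <- cue_grid[retrieved, ]
    len <- 5 + rnbinom(nrow(cue_grid),
                       mu = max(config$tokens_mean - 5, 1),
                       size = config$tokens_dispersion)
    texts <- character(nrow(cue_grid))
    for (cond in cue_conditions()) {
      rows <- which(cue_grid$condition == cond)
      if (length(rows) == 0) next
      total <- sum(len[rows])
      is_dot <- runif(total) < p_dot
      toks <- character(total)
      toks[is_dot] <- "."
      n_words <- sum(!is_dot)
      toks[!is_dot] <- st$words[sample.int(config$vocab_size, n_words,
                                           replace = TRUE,
                                           prob = word_dist[, cond])]
      texts[rows] <- vapply(
        split(toks, rep(seq_along(rows), times = len[rows])),
        paste, character(1), collapse = " "
      )
    }
  })
  narratives <- tibble(
    participant_id = cue_grid$participant_id,
    condition = cue_grid$condition,
    cue_id = cue_grid$cue_id,
    text = texts
  )
  list(
    narratives = narratives,
    lexicon = st$lexicon,
    ground_truth = list(
      condition_mixtures = mix,
      condition_word_dist = word_dist,
      multimodal_weights = config$multimodal_weights,
      supra_weight = config$supra_weight,
      effect_size = config$effect_size,
      signature_topics = config$signature_topics,
      topic_of = stats::setNames(st$topic_of, st$words),
      seed = seed
    )
  )
}

#' Generate the full synthetic input bundle
#'
#' Runs [generate_corpus()] and [generate_narratives()] with seeds derived
#' from the config seed and optionally writes the four input files plus a
#' `ground_truth.json` record to `outdir`.
#'
#' @param config A [generator_config()].
#' @param outdir Optional output directory.
#' @return List with `ngrams`, `synonyms`, `narratives`, `lexicon`,
#'   `vocabulary`, `ground_truth`, and (if written) `paths`.
#' @export
simulate_bundle <- function(config, outdir = NULL) {
  corpus <- generate_corpus(config)
  narr <- generate_narratives(config)
  bundle <- list(
    ngrams = corpus$ngrams,
    synonyms = corpus$synonyms,
    narratives = narr$narratives,
    lexicon = narr$lexicon,
    vocabulary = corpus$vocabulary,
    ground_truth = utils::modifyList(
      narr$ground_truth,
      list(corpus_seed = corpus$ground_truth$seed, config_seed = config$seed)
    )
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      ngrams = file.path(outdir, "ngrams.tsv"),
      synonyms = file.path(outdir, "synonyms.tsv"),
      narratives = file.path(outdir, "narratives.tsv"),
      lexicon = file.path(outdir, "lexicon.tsv"),
      ground_truth = file.path(outdir, "ground_truth.json")
    )
    write_ngrams(bundle$ngrams, paths$ngrams)
    write_synonyms(bundle$synonyms, paths$synonyms)
    write_narratives(bundle$narratives, paths$narratives)
    write_lexicon(bundle$lexicon, paths$lexicon)
    gt <- bundle$ground_truth
    gt$condition_mixtures <- as.data.frame(gt$condition_mixtures)
    gt$condition_word_dist <- NULL  # large and reconstructible
    jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA)
    bundle$paths <- paths
  }
  bundle
}

#' Calibrate the generator effect size to a population Cohen's d
#'
#' Finds, by bisection, the `effect_size` for which the population
#' standardized mean difference between the target condition and the pooled
#' other conditions — measured along the population signal axis in the given
#' semantic space — equals `target_d`. The signal axis is the difference
#' between the expected narrative vector of the target condition and that of
#' the rest; d is estimated by simulating `n_per_condition` participants per
#' condition at each candidate effect size.
#'
#' @param config A [generator_config()]; its other fields define the study.
#' @param space The semantic space in which representations live.
#' @param target_d Desired population d (default 0.8).
#' @param target Target condition (default `"visual"`).
#' @param seed Seed for the calibration simulations (mandatory).
#' @param n_per_condition Simulated participants per condition per step.
#' @param iterations Bisection steps (default 10).
#' @return The calibrated `effect_size`.
#' @export
calibrate_effect_size <- function(config, space, target_d = 0.8,
                                  target = "visual", seed,
                                  n_per_condition = 150, iterations = 10) {
  if (missing(seed)) abort("`seed` is mandatory")
  sim_d <- function(lambda, step_seed) {
    cfg <- config
    cfg$effect_size <- lambda
    cfg$n_participants <- 4L * n_per_condition
    cfg$condition_n <- stats::setNames(rep(n_per_condition, 4), cue_conditions())
    narr <- generate_narratives(cfg, seed = step_seed)
    reps <- aggregate_participants(narr$narratives, space)
    X <- representation_matrix(reps)
    conds <- attr(X, "conditions")
    wd <- narr$ground_truth$condition_word_dist
    common <- intersect(rownames(space$vectors), rownames(wd))
    t_axis <- t(space$vectors[common, , drop = FALSE]) %*%
      (wd[common, target] - rowMeans(wd[common, setdiff(cue_conditions(), target)]))
    t_axis <- t_axis / sqrt(sum(t_axis^2))
    proj <- as.vector(X %*% t_axis)
    cohens_d(proj[conds == target], proj[conds != target])
  }
  lo <- 0.005
  hi <- 0.9
  for (it in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    d_mid <- sim_d(mid, seed + it)
    if (d_mid < target_d) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
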