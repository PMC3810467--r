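four_participants <- function() {
  tibble::tibble(
    participant_id = c("p1", "p2", "p3", "p4"),
    condition = c("visual", "auditory", "olfactory", "multimodal")
  )
}

test_that("condition coding is +1 for the target and -1 elsewhere", {
  codes <- code_conditions(four_participants(), "visual")
  expect_identical(codes$code, c(1, -1, -1, -1))
  expect_identical(attr(codes, "target"), "visual")
  expect_error(code_conditions(four_participants(), "gustatory"), "unknown")
  allv <- dplyr::mutate(four_participants(), condition = "visual")
  expect_identical(code_conditions(allv, "visual")$code, rep(1, 4))
  only3 <- dplyr::filter(four_participants(), condition != "multimodal")
  expect_error(code_conditions(only3, "multimodal"), "not present")
})

test_that("dimensions are ranked by |r| with the codes; constants sink last", {
  withr::with_seed(21, {
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- rep(c(1, -1), 10)
  })
  X[, 3] <- y                 # perfect predictor
  X[, 5] <- 2                 # zero variance
  ord <- rank_dimensions(X, y)
  expect_identical(ord[1], 3L)
  expect_identical(ord[5], 5L)
  # brute-force correlation oracle for the full ordering
  r <- vapply(1:5, function(j) {
    if (sd(X[, j]) == 0) 0 else abs(cor(X[, j], y))
  }, numeric(1))
  expect_identical(ord, order(-r, 1:5))
})

test_that("LOO scale values match a hand-rolled normal-equations oracle", {
  withr::with_seed(31, {
    X <- matrix(rnorm(4 * 2), 4, 2)
  })
  rownames(X) <- paste0("p", 1:4)
  codes <- code_conditions(four_participants(), "visual")
  sc <- loo_scale(X, codes, subset_size = 2)
  oracle <- vapply(1:4, function(i) {
    A <- cbind(1, X[-i, , drop = FALSE])
    beta <- solve(t(A) %*% A, t(A) %*% codes$code[-i])
    sum(c(1, X[i, ]) * beta)
  }, numeric(1))
  expect_equal(sc$value, oracle, tolerance = 1e-8)
  expect_identical(attr(sc, "subset_size"), 2)
  expect_equal(sc$z_value, z_transform(sc$value))
})

test_that("a held-out participant's value never uses their own code", {
  withr::with_seed(41, {
    X <- matrix(rnorm(12 * 3), 12, 3)
  })
  rownames(X) <- sprintf("q%02d", 1:12)
  participants <- tibble::tibble(
    participant_id = rownames(X),
    condition = rep(cue_conditions(), each = 3)
  )
  codes <- code_conditions(participants, "visual")
  sc <- loo_scale(X, codes)
  flipped <- codes
  flipped$code[1] <- -flipped$code[1]
  sc2 <- loo_scale(X, flipped)
  expect_equal(sc2$value[1], sc$value[1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sc2$value[-1], sc$value[-1])))
})

test_that("perfectly separable data ranks every target above every non-target", {
  withr::with_seed(51, {
    X <- matrix(rnorm(40 * 4, sd = 0.05), 40, 4)
  })
  X[1:10, 1] <- X[1:10, 1] + 5  # huge condition signal on dim 1
  rownames(X) <- sprintf("s%02d", 1:40)
  participants <- tibble::tibble(
    participant_id = rownames(X),
    condition = rep(cue_conditions(), each = 10)
  )
  codes <- code_conditions(participants, "visual")
  sc <- loo_scale(X, codes)
  expect_gt(min(sc$value[sc$code == 1]), max(sc$value[sc$code == -1]))
})

test_that("scale values are invariant to a common positive rescaling of raw vectors", {
  withr::with_seed(61, {
    X <- matrix(rnorm(16 * 3), 16, 3)
  })
  rownames(X) <- sprintf("r%02d", 1:16)
  participants <- tibble::tibble(
    participant_id = rownames(X),
    condition = rep(cue_conditions(), each = 4)
  )
  codes <- code_conditions(participants, "auditory")
  expect_equal(loo_scale(X, codes)$value, loo_scale(X * 7.3, codes)$value,
               tolerance = 1e-9)
})

test_that("the scaled z-transform matches its printed formula", {
  expect_equal(z_transform(c(0, 1)), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  x <- c(2, 2, 5, 9)
  z <- z_transform(x)
  expect_equal(z, ((x - mean(x)) / sd(x)) / sqrt(3), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(z[x == mean(x)], numeric(0))  # no value sits at the mean here
  expect_equal(z_transform(c(1, 1, 4))[1], z_transform(c(1, 1, 4))[2])
  expect_error(z_transform(c(3, 3, 3)), "zero")
  expect_error(z_transform(4), "at least 2")
})

test_that("predictive validity is the Pearson r with a one-sided p", {
  codes <- rep(c(1, -1), each = 5)
  perfect <- evaluate_scale(codes, codes)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_value, 1e-10)
  anti <- evaluate_scale(-codes, codes)
  expect_equal(anti$r, -1)
  expect_gt(anti$p_value, 0.999)
  withr::with_seed(71, {
    pred <- rnorm(10)
  })
  ev <- evaluate_scale(pred, codes)
  # brute-force covariance-formula oracle
  r_oracle <- sum((codes - mean(codes)) * (pred - mean(pred))) /
    sqrt(sum((codes - mean(codes))^2) * sum((pred - mean(pred))^2))
  expect_equal(ev$r, r_oracle, tolerance = 1e-10)
  t_oracle <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(ev$p_value, pt(t_oracle, 8, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_warning(flat <- evaluate_scale(rep(2, 10), codes), "zero-variance")
  expect_true(is.na(flat$r))
})

test_that("single-class data reduces class scales to the plain LOO scale", {
  space <- default_space()
  words <- space_words(space)[1:20]
  lex <- tibble::tibble(word = words, word_class = "noun")
  narratives <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:16),
    condition = rep(cue_conditions(), each = 4),
    cue_id = "c1",
    text = withr::with_seed(81, vapply(1:16, function(i)
      paste(sample(words, 12, TRUE), collapse = " "), character(1)))
  )
  codes <- code_conditions(narratives, "visual")
  cls_reps <- aggregate_participants(narratives, space, lexicon = lex,
                                     by_class = TRUE)
  suppressWarnings(cs <- class_scales(cls_reps, codes))
  direct <- loo_scale(cls_reps, codes, scope = "noun")
  expect_equal(cs$noun, direct$value, tolerance = 1e-12)
  expect_true(all(attr(cs, "dropped_classes") != "noun"))
})

test_that("participants missing a class get the neutral value 0", {
  space <- default_space()
  words <- space_words(space)[1:20]
  lex <- tibble::tibble(word = words,
                        word_class = rep(c("noun", "verb"), each = 10))
  texts <- withr::with_seed(91, vapply(1:12, function(i)
    paste(sample(words, 14, TRUE), collapse = " "), character(1)))
  narratives <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:12),
    condition = rep(cue_conditions(), each = 3),
    cue_id = "c1", text = texts
  )
  # strip every verb token from participant p01 so that class is absent
  verbs <- lex$word[lex$word_class == "verb"]
  t1 <- tokenize(narratives$text[1])[[1]]
  narratives$text[1] <- paste(t1[!t1 %in% verbs], collapse = " ")
  codes <- code_conditions(narratives, "visual")
  cls_reps <- aggregate_participants(narratives, space, lexicon = lex,
                                     by_class = TRUE)
  suppressMessages(suppressWarnings(cs <- class_scales(cls_reps, codes)))
  expect_equal(cs$verb[cs$participant_id == "p01"], 0)
  expect_false(all(cs$verb == 0))
})

test_that("a class scale equal to the codes makes the combined scale reproduce their signs", {
  participants <- tibble::tibble(
    participant_id = sprintf("p%d", 1:8),
    condition = rep(cue_conditions(), each = 2)
  )
  codes <- code_conditions(participants, "olfactory")
  class_values <- dplyr::mutate(codes, noun = code,
                                verb = withr::with_seed(5, rnorm(8, sd = 0.1)))
  attr(class_values, "target") <- "olfactory"
  combined <- combine_scales(class_values)
  expect_identical(sign(combined$value), sign(codes$code))
})

test_that("pure-noise class scales have low LOO validity", {
  participants <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:80),
    condition = rep(cue_conditions(), each = 20)
  )
  codes <- code_conditions(participants, "visual")
  hits <- vapply(1:60, function(r) {
    class_values <- withr::with_seed(8000 + r, {
      dplyr::mutate(codes, c1 = rnorm(80), c2 = rnorm(80), c3 = rnorm(80))
    })
    attr(class_values, "target") <- "visual"
    abs(evaluate_scale(combine_scales(class_values))$r) < 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("classes with no between-participant variation are dropped, not combined", {
  space <- default_space()
  words <- space_words(space)[1:21]
  # 20 varied nouns plus a single proper name: every participant's
  # proper_name representation is the same unit vector
  lex <- tibble::tibble(word = words,
                        word_class = c(rep("noun", 20), "proper_name"))
  texts <- withr::with_seed(95, vapply(1:16, function(i)
    paste(c(sample(words[1:20], 12, TRUE), words[21]), collapse = " "),
    character(1)))
  narratives <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:16),
    condition = rep(cue_conditions(), each = 4),
    cue_id = "c1", text = texts
  )
  codes <- code_conditions(narratives, "visual")
  cls_reps <- aggregate_participants(narratives, space, lexicon = lex,
                                     by_class = TRUE)
  warns <- capture_warnings(
    suppressMessages(cs <- class_scales(cls_reps, codes)))
  expect_true(any(grepl("no between-participant variation", warns)))
  expect_false("proper_name" %in% names(cs))
  expect_true("proper_name" %in% attr(cs, "dropped_classes"))
  expect_true("noun" %in% names(cs))
  # the combined scale cannot be a perfect reconstruction of the codes
  combined <- combine_scales(cs)
  expect_lt(abs(evaluate_scale(combined)$r), 0.999)
})
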