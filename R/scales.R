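#' Code conditions as +1 / -1 for one target
#'
#' Codes participants in the target condition as +1 and all others as -1; this
#' coding is the regressand of the semantic-scale regressions.
#'
#' @param participants Data frame with columns `participant_id`, `condition`
#'   (one condition per participant; extra rows are collapsed).
#' @param target The target condition, one of [cue_conditions()] and present
#'   in the data.
#' @return Tibble `participant_id`, `condition`, `code` with attribute
#'   `target`.
#' @export
code_conditions <- function(participants, target) {
  check_columns(participants, c("participant_id", "condition"), "`participants`")
  check_conditions(participants$condition)
  d <- distinct(participants, .data$participant_id, .data$condition)
  if (anyDuplicated(d$participant_id) > 0) {
    abort("each participant must have a single condition label")
  }
  if (!target %in% cue_conditions()) {
    abort(sprintf("unknown target condition \"%s\"", target))
  }
  if (!target %in% d$condition) {
    abort(sprintf("target condition \"%s\" not present in the data", target))
  }
  out <- mutate(d, code = ifelse(.data$condition == target, 1, -1))
  attr(out, "target") <- target
  out
}

#' Rank space dimensions by training-set predictiveness
#'
#' Orders the columns of a representation matrix by descending absolute
#' Pearson correlation with the +1/-1 codes; ties (including zero-variance
#' dimensions, which score 0) are broken by ascending column index.
#'
#' @param X Numeric matrix, participants x dimensions.
#' @param codes Numeric +1/-1 vector, one per row of `X`.
#' @return Integer vector of column indices, most predictive first.
#' @export
rank_dimensions <- function(X, codes) {
  if (nrow(X) < 2) abort("need at least 2 training points to rank dimensions")
  r <- abs_cor_with(X, codes)
  order(-r, seq_along(r))
}

# LOO predictions of `codes` from columns of X, re-selecting the top
# `subset_size` dimensions per fold; OLS with intercept, minimum-norm on
# singular folds (counted and reported via attr).
loo_predict <- function(X, codes, subset_size, rank_dims = TRUE) {
  n <- nrow(X)
  m_use <- min(subset_size, ncol(X))
  pred <- numeric(n)
  n_singular <- 0L
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- codes[-i]
    sel <- if (rank_dims && m_use < ncol(X)) {
      rank_dimensions(Xtr, ytr)[seq_len(m_use)]
    } else {
      seq_len(ncol(X))
    }
    beta <- ols_coef(Xtr[, sel, drop = FALSE], ytr)
    if (isTRUE(attr(beta, "rank_deficient"))) n_singular <- n_singular + 1L
    pred[i] <- sum(c(1, X[i, sel]) * beta)
  }
  attr(pred, "n_singular") <- n_singular
  attr(pred, "n_dims_used") <- m_use
  pred
}

#' Leave-one-subject-out semantic scale
#'
#' For each participant, an ordinary least-squares regression (with intercept)
#' of the +1/-1 condition codes on the participant representations is fitted
#' on all *other* participants, using only the `subset_size` dimensions most
#' predictive on that training fold (re-ranked per fold); the fitted function
#' applied to the held-out participant's representation is that participant's
#' scale value. Positive values indicate semantic similarity to the target
#' condition. The default subset size is half the number of predicted data
#' points, `floor(n / 2)`, an overfitting guard.
#'
#' @param representations Output of [aggregate_participants()] (one scope), or
#'   a participants x dimensions matrix with participant rownames.
#' @param codes Output of [code_conditions()].
#' @param subset_size Number of ranked dimensions used per fold; default
#'   `floor(n / 2)` where `n` is the number of predicted participants.
#' @param scope Scope label stored on the result.
#' @return A `semantic_scale` tibble: `participant_id`, `condition`, `code`,
#'   `value` (LOO prediction), `z_value` (see [z_transform()]), plus attributes
#'   `target`, `subset_size`, `n_dims_used`, `scope`, `n_singular_folds`.
#' @export
loo_scale <- function(representations, codes, subset_size = NULL,
                      scope = "all") {
  if (is.matrix(representations)) {
    X <- representations
  } else {
    X <- representation_matrix(representations, scope = scope)
  }
  check_columns(codes, c("participant_id", "code"), "`codes`")
  idx <- match(rownames(X), codes$participant_id)
  if (anyNA(idx)) {
    abort("every represented participant needs a row in `codes`")
  }
  y <- codes$code[idx]
  n <- nrow(X)
  if (n < 4) abort("need at least 4 participants with representations")
  if (length(unique(y)) < 2) {
    abort("both code levels must be present among represented participants")
  }
  subset_size <- subset_size %||% floor(n / 2)
  pred <- loo_predict(X, y, subset_size)
  if (attr(pred, "n_singular") > 0) {
    inform(sprintf("%d fold(s) had singular designs; minimum-norm solutions used",
                   attr(pred, "n_singular")))
  }
  out <- tibble(
    participant_id = rownames(X),
    condition = codes$condition[idx],
    code = y,
    value = as.numeric(pred),
    z_value = z_transform(as.numeric(pred))
  )
  structure(
    out,
    class = c("semantic_scale", class(out)),
    target = attr(codes, "target"),
    subset_size = subset_size,
    n_dims_used = attr(pred, "n_dims_used"),
    scope = scope,
    n_singular_folds = attr(pred, "n_singular")
  )
}

#' Scaled z-transform of scale values
#'
#' Standardizes by the mean and standard deviation and then divides by
#' `sqrt(n - 1)`: `z_i = ((x_i - mean) / sd) / sqrt(n - 1)`. The extra
#' `sqrt(n - 1)` shrinkage is unconventional but is the transform this
#' analysis defines; the plain standardized score is `z * sqrt(n - 1)`.
#'
#' @param x Numeric vector, `length(x) >= 2`, with positive standard
#'   deviation.
#' @return Numeric vector of transformed values (mean 0).
#' @export
z_transform <- function(x) {
  n <- length(x)
  if (n < 2) abort("need at least 2 values to z-transform")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("standard deviation is zero; z-transform undefined")
  ((x - mean(x)) / s) / sqrt(n - 1)
}

#' Predictive validity of a semantic scale
#'
#' Correlates the empirical +1/-1 codes with the LOO-predicted scale values;
#' a significantly positive Pearson correlation (one-sided test of r > 0)
#' indicates that the semantic representation predicts the condition. For a
#' two-group coding this is the point-biserial correlation test, equivalent to
#' a pooled one-sided two-sample t-test on the scale values.
#'
#' @param scale A `semantic_scale`, or a numeric vector of predictions.
#' @param codes Codes vector (taken from `scale` when it is a
#'   `semantic_scale`).
#' @return One-row tibble with `r`, `p_value`, `n`.
#' @export
evaluate_scale <- function(scale, codes = NULL) {
  if (inherits(scale, "semantic_scale")) {
    values <- scale$value
    codes <- scale$code
  } else {
    values <- as.numeric(scale)
    if (is.null(codes)) abort("`codes` is required when `scale` is a plain vector")
    codes <- if (is.data.frame(codes)) codes$code else as.numeric(codes)
  }
  n <- length(values)
  if (n < 4) abort("need at least 4 data points")
  if (sd(values) == 0) {
    warn("zero-variance predictions: correlation undefined")
    return(tibble(r = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- cor.test(codes, values, alternative = "greater", method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' @export
tidy.semantic_scale <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.semantic_scale <- function(x, ...) {
  ev <- evaluate_scale(x)
  tibble(
    target = attr(x, "target") %||% NA_character_,
    scope = attr(x, "scope") %||% NA_character_,
    r = ev$r, p_value = ev$p_value, n = ev$n,
    subset_size = attr(x, "subset_size"),
    n_dims_used = attr(x, "n_dims_used")
  )
}

#' Per-word-class semantic scales
#'
#' Runs [loo_scale()] within each word class that has at least `min_n`
#' participants with representations; classes below the threshold are dropped
#' with a warning, as are classes whose representations show no
#' between-participant variation (e.g. a class with a single in-space word:
#' every participant's unit vector is identical, so the class carries no
#' discriminative content and its leave-one-out predictions would collapse to
#' the training-fold code mean — a pure function of the held-out code that
#' would corrupt the combination regression). Participants lacking a
#' representation for a retained class get the neutral value 0 for that class
#' (0 is the scale's neutral point since predictions straddle 0).
#'
#' @param class_representations [aggregate_participants()] output with
#'   `by_class = TRUE`.
#' @param codes Output of [code_conditions()].
#' @param subset_size Per-fold dimension budget; default `floor(n / 2)` per
#'   class.
#' @param min_n Minimum usable participants per class (default 4).
#' @return Tibble `participant_id`, `condition`, `code`, then one column per
#'   retained class holding that class's scale values; attribute
#'   `dropped_classes`.
#' @export
class_scales <- function(class_representations, codes, subset_size = NULL,
                         min_n = 4) {
  check_columns(codes, c("participant_id", "code"), "`codes`")
  base <- select(codes, "participant_id", "condition", "code")
  classes <- intersect(word_classes(), unique(class_representations$scope))
  dropped <- character(0)
  degenerate <- character(0)
  filled <- character(0)
  for (cl in classes) {
    usable <- filter(class_representations, .data$scope == cl,
                     !vapply(.data$vector, is.null, logical(1)))
    cl_codes <- filter(codes, .data$participant_id %in% usable$participant_id)
    if (nrow(usable) < min_n || length(unique(cl_codes$code)) < 2) {
      dropped <- c(dropped, cl)
      next
    }
    Xcl <- do.call(rbind, usable$vector)
    if (max(apply(Xcl, 2, function(col) diff(range(col)))) < 1e-8) {
      degenerate <- c(degenerate, cl)
      next
    }
    sc <- loo_scale(class_representations, codes, subset_size = subset_size,
                    scope = cl)
    base <- left_join(base, select(as_tibble(sc), "participant_id", value = "value"),
                      by = "participant_id")
    miss <- is.na(base$value)
    if (any(miss)) filled <- unique(c(filled, base$participant_id[miss]))
    base$value[miss] <- 0
    names(base)[names(base) == "value"] <- cl
  }
  if (length(dropped) > 0) {
    warn(sprintf("dropping word class(es) with fewer than %d usable participants: %s",
                 min_n, paste(dropped, collapse = ", ")))
  }
  if (length(degenerate) > 0) {
    warn(sprintf("dropping word class(es) with no between-participant variation: %s",
                 paste(degenerate, collapse = ", ")))
  }
  if (ncol(base) == 3) abort("no word class had enough usable participants")
  if (length(filled) > 0) {
    inform(sprintf("filled missing class values with 0 for %d participant(s)",
                   length(filled)))
  }
  attr(base, "dropped_classes") <- c(dropped, degenerate)
  attr(base, "target") <- attr(codes, "target")
  base
}

#' Combine per-class scales into one semantic scale
#'
#' Applies the same leave-one-subject-out multiple-regression step with the
#' per-class scale values as features (no dimension-subset step: the feature
#' count is at most 14, below half the sample size).
#'
#' @param class_values Output of [class_scales()].
#' @param codes Output of [code_conditions()]; defaults to the columns carried
#'   by `class_values`.
#' @return A `semantic_scale` with scope `"combined"`.
#' @export
combine_scales <- function(class_values, codes = NULL) {
  feature_cols <- setdiff(names(class_values),
                          c("participant_id", "condition", "code"))
  if (length(feature_cols) == 0) abort("no class-scale columns to combine")
  X <- as.matrix(class_values[, feature_cols, drop = FALSE])
  rownames(X) <- class_values$participant_id
  if (is.null(codes)) {
    codes <- select(class_values, "participant_id", "condition", "code")
    attr(codes, "target") <- attr(class_values, "target")
  }
  loo_scale(X, codes, subset_size = ncol(X), scope = "combined")
}

#' Build the participants x scales matrix
#'
#' Constructs one semantic scale per target condition — by default the
#' combined per-word-class scale; with `scope = "all"` the single all-words
#' scale — and assembles the four scales into one table, the input of the
#' hypothesis tests and the pairwise scatter plots.
#'
#' @param representations [aggregate_participants()] output: `by_class = TRUE`
#'   output for `scope = "classes"`, all-words output for `scope = "all"`.
#' @param scope `"classes"` (per-class scales combined by LOO regression) or
#'   `"all"` (all-words representations directly).
#' @param targets Conditions to build scales for (default all four).
#' @param subset_size Passed to [loo_scale()] / [class_scales()].
#' @return A `scale_matrix` tibble: `participant_id`, `condition`, and one
#'   numeric column per target condition.
#' @export
semantic_scale_matrix <- function(representations,
                                  scope = c("classes", "all"),
                                  targets = cue_conditions(),
                                  subset_size = NULL) {
  scope <- arg_match(scope)
  participants <- distinct(representations, .data$participant_id, .data$condition)
  out <- participants
  for (tg in targets) {
    codes <- code_conditions(participants, tg)
    sc <- if (scope == "classes") {
      combine_scales(class_scales(representations, codes,
                                  subset_size = subset_size))
    } else {
      loo_scale(representations, codes, subset_size = subset_size, scope = "all")
    }
    out <- left_join(out, select(as_tibble(sc), "participant_id", value = "value"),
                     by = "participant_id")
    names(out)[names(out) == "value"] <- tg
  }
  structure(out, class = c("scale_matrix", class(out)), scope = scope)
}

#' @rdname semantic_scale_matrix
#' @param object A `scale_matrix`.
#' @param ... Unused.
#' @export
autoplot.scale_matrix <- function(object, ...) {
  scales_present <- intersect(cue_conditions(), names(object))
  pairs <- utils::combn(scales_present, 2, simplify = FALSE)
  long <- purrr::map_dfr(pairs, function(pr) {
    tibble(
      panel = paste(pr[1], "vs", pr[2]),
      x = object[[pr[1]]], y = object[[pr[2]]],
      condition = object$condition
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$condition)) +
    ggplot2::geom_point(shape = 4, size = 1.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "first scale", y = "second scale",
                  title = "Pairwise semantic-scale projections") +
    ggplot2::theme_minimal()
}
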