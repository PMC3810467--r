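#' One-sided two-sample t-test (pooled variance)
#'
#' Tests the directed hypothesis `mean(x) > mean(y)` with the classical
#' pooled-variance two-sample t statistic.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @return The one-sided p-value.
#' @export
one_sided_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("both samples need at least 2 values")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 <= 0) abort("zero pooled variance: t-test undefined")
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  pt(t_stat, df = nx + ny - 2, lower.tail = FALSE)
}

#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' n-1-weighted pooled standard deviation; positive when `x` exceeds `y`.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("both samples need at least 2 values")
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (!is.finite(sp) || sp <= 0) abort("zero pooled standard deviation: d undefined")
  (mean(x) - mean(y)) / sp
}

#' Condition comparison tables (p-values and effect sizes)
#'
#' For each semantic scale (rows, in the fixed order multimodal, visual,
#' auditory, olfactory) computes the one-sided pooled t-test and Cohen's d of
#' the scale's own condition against (a) the three other conditions pooled
#' (`all_others`) and (b) each other condition pairwise, all evaluated on that
#' row's scale. The grids are asymmetric by construction: each row uses a
#' different scale. P-values are not corrected for multiple comparisons unless
#' `p_adjust = "holm"`.
#'
#' @param scale_matrix A [semantic_scale_matrix()] result (all four conditions
#'   present).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A `condition_comparison`: list of tibbles `p` and `d`, each with a
#'   `scale` column and columns `all_others`, `multimodal`, `visual`,
#'   `auditory`, `olfactory` (own-condition cells are `NA`).
#' @export
comparison_tables <- function(scale_matrix, p_adjust = c("none", "holm")) {
  p_adjust <- arg_match(p_adjust)
  check_columns(scale_matrix, c("condition", cue_conditions()), "`scale_matrix`")
  missing_cond <- setdiff(cue_conditions(), unique(scale_matrix$condition))
  if (length(missing_cond) > 0) {
    abort(sprintf("missing condition(s): %s", paste(missing_cond, collapse = ", ")))
  }
  row_order <- c("multimodal", "visual", "auditory", "olfactory")
  cols <- c("all_others", row_order)
  p_grid <- d_grid <- matrix(
    NA_real_, nrow = 4, ncol = 5, dimnames = list(row_order, cols)
  )
  for (sc in row_order) {
    values <- scale_matrix[[sc]]
    x <- values[scale_matrix$condition == sc]
    p_grid[sc, "all_others"] <- one_sided_t(x, values[scale_matrix$condition != sc])
    d_grid[sc, "all_others"] <- cohens_d(x, values[scale_matrix$condition != sc])
    for (other in setdiff(row_order, sc)) {
      y <- values[scale_matrix$condition == other]
      p_grid[sc, other] <- one_sided_t(x, y)
      d_grid[sc, other] <- cohens_d(x, y)
    }
  }
  if (p_adjust == "holm") {
    live <- !is.na(p_grid)
    p_grid[live] <- stats::p.adjust(p_grid[live], method = "holm")
  }
  as_grid_tbl <- function(g) {
    dplyr::bind_cols(tibble(scale = rownames(g)), as_tibble(g))
  }
  structure(
    list(p = as_grid_tbl(p_grid), d = as_grid_tbl(d_grid),
         p_adjust = p_adjust),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> one-sided p-values (rows = scales):\n")
  print(x$p)
  cat("Cohen's d:\n")
  print(x$d)
  invisible(x)
}

#' @rdname comparison_tables
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @export
tidy.condition_comparison <- function(x, ...) {
  long_p <- tidyr::pivot_longer(x$p, -"scale", names_to = "comparison",
                                values_to = "p_value")
  long_d <- tidyr::pivot_longer(x$d, -"scale", names_to = "comparison",
                                values_to = "cohens_d")
  filter(left_join(long_p, long_d, by = c("scale", "comparison")),
         !is.na(.data$p_value) | !is.na(.data$cohens_d))
}

#' Modality dominance ranking
#'
#' Orders the unimodal conditions by how close each sits to the multimodal
#' condition on its own scale: ascending absolute Cohen's d of the cell
#' (row = unimodal scale, column = multimodal condition). A lower effect size
#' means the unimodal condition contributes more to the multimodal
#' representation. Ties are broken by the fixed order visual, auditory,
#' olfactory.
#'
#' @param comparison A [comparison_tables()] result.
#' @return Tibble `rank`, `condition`, `abs_d`, closest (most dominant) first.
#' @export
dominance_ranking <- function(comparison) {
  if (!inherits(comparison, "condition_comparison")) {
    abort("`comparison` must come from comparison_tables()")
  }
  uni <- unimodal_conditions()
  abs_d <- vapply(uni, function(u) {
    abs(comparison$d$multimodal[comparison$d$scale == u])
  }, numeric(1))
  ord <- order(abs_d, match(uni, unimodal_conditions()))
  tibble(rank = seq_along(uni), condition = uni[ord], abs_d = unname(abs_d[ord]))
}

#' Condition mean with isotropic confidence radius
#'
#' Coordinate-wise mean of a condition's 2-D scale values together with the
#' radius of an isotropic confidence circle for that mean:
#' `radius = z * sqrt((var_x + var_y) / 2) / sqrt(n)` with `z` the two-sided
#' normal quantile for `level` (1.96 at 95%). The root-mean-square of the two
#' per-axis standard errors yields a circle rather than an ellipse.
#'
#' @param points Two-column matrix or data frame of 2-D points (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble `mean_x`, `mean_y`, `radius`, `n`.
#' @export
condition_mean_ci <- function(points, level = 0.95) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) abort("`points` must have exactly 2 columns")
  n <- nrow(pts)
  if (n < 2) abort("need at least 2 points for a confidence circle")
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    mean_x = mean(pts[, 1]),
    mean_y = mean(pts[, 2]),
    radius = z * sqrt((var(pts[, 1]) + var(pts[, 2])) / 2) / sqrt(n),
    n = n
  )
}

#' Classify a point against a triangle
#'
#' Barycentric-coordinate classification of a 2-D point against the triangle
#' with the given vertices; coordinates within `tol` of zero count as
#' boundary.
#'
#' @param p Numeric 2-vector.
#' @param tri 3 x 2 matrix of vertices.
#' @param tol Boundary tolerance on the barycentric coordinates.
#' @return `"inside"`, `"boundary"` or `"outside"`.
#' @export
point_in_triangle <- function(p, tri, tol = 1e-12) {
  tri <- as.matrix(tri)
  if (!all(dim(tri) == c(3, 2)) || length(p) != 2) {
    abort("`tri` must be 3 x 2 and `p` a 2-vector")
  }
  lam <- barycentric(matrix(p, nrow = 1), tri)
  if (any(lam < -tol)) "outside"
  else if (any(abs(lam) <= tol)) "boundary"
  else "inside"
}

# Barycentric coordinates of points (rows of P) w.r.t. triangle `tri`;
# errors on degenerate (collinear) triangles.
barycentric <- function(P, tri) {
  d <- (tri[2, 2] - tri[3, 2]) * (tri[1, 1] - tri[3, 1]) +
    (tri[3, 1] - tri[2, 1]) * (tri[1, 2] - tri[3, 2])
  scale <- max(abs(tri)) + 1
  if (abs(d) <= 1e-12 * scale^2) {
    abort("degenerate triangle: the three vertices are collinear")
  }
  l1 <- ((tri[2, 2] - tri[3, 2]) * (P[, 1] - tri[3, 1]) +
           (tri[3, 1] - tri[2, 1]) * (P[, 2] - tri[3, 2])) / d
  l2 <- ((tri[3, 2] - tri[1, 2]) * (P[, 1] - tri[3, 1]) +
           (tri[1, 1] - tri[3, 1]) * (P[, 2] - tri[3, 2])) / d
  cbind(l1, l2, 1 - l1 - l2)
}

# Distance from point p to segment [a, b].
dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t_par <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t_par * ab - p)^2))
}

# Exact circle-triangle overlap: the circle (center, radius) intersects the
# triangle iff its center lies inside, or some edge passes within radius.
circle_triangle_overlap_exact <- function(center, radius, tri, tol = 1e-9) {
  if (point_in_triangle(center, tri) != "outside") return(TRUE)
  edges <- list(c(1, 2), c(2, 3), c(3, 1))
  min_d <- min(vapply(edges, function(e) {
    dist_point_segment(center, tri[e[1], ], tri[e[2], ])
  }, numeric(1)))
  min_d <= radius + tol
}

#' Triangle test of the multimodal condition
#'
#' For each 2-D projection onto a pair of semantic scales, forms the triangle
#' whose vertices are the three unimodal condition means, computes the
#' multimodal condition's mean and confidence-circle radius
#' ([condition_mean_ci()]), and reports (a) whether the multimodal mean lies
#' inside the unimodal triangle and (b) how much of the multimodal confidence
#' circle overlaps the triangle (seeded Monte-Carlo fraction of uniform points
#' in the circle that fall inside, cross-checked by an exact segment-circle
#' intersection test). A multimodal mean inside the triangle is consistent
#' with the multimodal representation being a combination of the unimodal
#' ones; a mean outside signals supra-additivity.
#'
#' @param scale_matrix A [semantic_scale_matrix()] result.
#' @param projections `"unimodal"` (the three pairs of unimodal scales,
#'   default) or `"all"` (all six pairs of the four scales).
#' @param mc_samples Monte-Carlo sample size per projection (>= 1e4).
#' @param seed Integer seed for the Monte-Carlo draws (mandatory).
#' @param level Confidence level of the circles.
#' @return A `triangle_test` tibble, one row per projection: `scale_x`,
#'   `scale_y`, `verdict` (inside/boundary/outside), `mean_inside`,
#'   `overlap_fraction`, `circle_triangle_overlap`, `radius`, plus list-columns
#'   `condition_stats` (per-condition means and radii) and `triangle`
#'   (vertex matrix). Attributes record `mc_samples`, `seed`, `level`.
#' @export
triangular_test <- function(scale_matrix, projections = c("unimodal", "all"),
                            mc_samples = 1e4, seed, level = 0.95) {
  if (missing(seed)) abort("`seed` is mandatory for the Monte-Carlo overlap")
  if (mc_samples < 1e4) abort("`mc_samples` must be at least 10000")
  projections <- arg_match(projections)
  check_columns(scale_matrix, c("condition", cue_conditions()), "`scale_matrix`")
  missing_cond <- setdiff(cue_conditions(), unique(scale_matrix$condition))
  if (length(missing_cond) > 0) {
    abort(sprintf("missing condition(s): %s", paste(missing_cond, collapse = ", ")))
  }
  axes <- if (projections == "unimodal") unimodal_conditions() else cue_conditions()
  pair_list <- utils::combn(axes, 2, simplify = FALSE)
  rows <- withr::with_seed(seed, purrr::map(pair_list, function(pr) {
    stats_by_cond <- purrr::map_dfr(cue_conditions(), function(cond) {
      pts <- scale_matrix[scale_matrix$condition == cond, pr]
      mutate(condition_mean_ci(pts, level = level), condition = cond,
             .before = 1)
    })
    tri <- as.matrix(
      stats_by_cond[match(unimodal_conditions(), stats_by_cond$condition),
                    c("mean_x", "mean_y")]
    )
    rownames(tri) <- unimodal_conditions()
    mm <- stats_by_cond[stats_by_cond$condition == "multimodal", ]
    center <- c(mm$mean_x, mm$mean_y)
    verdict <- point_in_triangle(center, tri)
    radius <- mm$radius
    theta <- runif(mc_samples, 0, 2 * pi)
    r <- radius * sqrt(runif(mc_samples))
    pts_mc <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
    lam <- barycentric(pts_mc, tri)
    overlap_fraction <- mean(rowSums(lam >= -1e-12) == 3)
    exact <- circle_triangle_overlap_exact(center, radius, tri)
    if (overlap_fraction > 0 && !exact) {
      warn("Monte-Carlo overlap positive but exact test disjoint; check tangency")
    }
    tibble(
      scale_x = pr[1], scale_y = pr[2],
      verdict = verdict,
      mean_inside = verdict != "outside",
      overlap_fraction = overlap_fraction,
      circle_triangle_overlap = exact,
      radius = radius,
      condition_stats = list(stats_by_cond),
      triangle = list(tri)
    )
  }))
  out <- bind_rows(rows)
  structure(
    out,
    class = c("triangle_test", class(out)),
    mc_samples = mc_samples, seed = seed, level = level
  )
}

#' @export
tidy.triangle_test <- function(x, ...) {
  select(as_tibble(x), -"condition_stats", -"triangle")
}

#' @rdname triangular_test
#' @param object A `triangle_test`.
#' @param ... Unused.
#' @export
autoplot.triangle_test <- function(object, ...) {
  circle_pts <- function(cx, cy, r, n = 120) {
    th <- seq(0, 2 * pi, length.out = n)
    tibble(x = cx + r * cos(th), y = cy + r * sin(th))
  }
  panels <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    st <- object$condition_stats[[i]]
    mutate(st, panel = paste(object$scale_x[i], "vs", object$scale_y[i]))
  })
  circles <- panels %>%
    group_by(.data$panel, .data$condition) %>%
    dplyr::reframe(circle_pts(.data$mean_x, .data$mean_y, .data$radius))
  tri_df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    tri <- object$triangle[[i]]
    tibble(panel = paste(object$scale_x[i], "vs", object$scale_y[i]),
           x = tri[, 1], y = tri[, 2])
  })
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = tri_df,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$condition,
                                    group = .data$condition)) +
    ggplot2::geom_point(data = panels,
                        ggplot2::aes(x = .data$mean_x, y = .data$mean_y,
                                     colour = .data$condition),
                        shape = 4, size = 3, stroke = 1.2) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "first scale", y = "second scale",
                  title = "Condition means with confidence circles and unimodal triangle") +
    ggplot2::theme_minimal()
}
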