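test_that("one-sided pooled t-test matches the textbook formula and t.test", {
  x <- c(4.1, 5.2, 3.9, 4.8, 5.0)
  y <- c(3.2, 4.0, 3.5, 3.1, 3.9)
  p <- one_sided_t(x, y)
  # independent oracle: textbook pooled statistic + t CDF
  sp2 <- ((4) * var(x) + (4) * var(y)) / 8
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 5))
  expect_equal(p, pt(t_stat, 8, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(p, t.test(x, y, var.equal = TRUE,
                         alternative = "greater")$p.value,
               tolerance = 1e-12)
  # identical samples: t = 0, p = 1/2
  expect_equal(one_sided_t(x, x + 0 * x), 0.5, tolerance = 1e-12)
  # extreme separation
  withr::with_seed(1, {
    a <- rnorm(20, 5); b <- rnorm(20, 0)
  })
  expect_lt(one_sided_t(a, b), 1e-6)
  expect_error(one_sided_t(rep(1, 3), rep(1, 3)), "pooled variance")
  expect_error(one_sided_t(1, c(1, 2)), "at least 2")
})

test_that("Cohen's d is the pooled standardized mean difference", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # mean difference equal to the pooled SD gives exactly 1
  x <- c(1, 2, 3); y <- x - sd(x)
  expect_equal(cohens_d(x, y), 1, tolerance = 1e-12)
  withr::with_seed(2, {
    a <- rnorm(10); b <- rnorm(15, 1)
  })
  expect_equal(cohens_d(a, b), -cohens_d(b, a), tolerance = 1e-12)
  # invariant to common location/scale shifts
  expect_equal(cohens_d(3 * a + 7, 3 * b + 7), cohens_d(a, b),
               tolerance = 1e-12)
  expect_error(cohens_d(rep(2, 4), rep(2, 4)), "zero pooled")
})

fake_scale_matrix <- function(by_condition) {
  # by_condition: named list condition -> n x 4 matrix of scale values
  rows <- purrr::imap(by_condition, function(m, cond) {
    colnames(m) <- cue_conditions()
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = sprintf("%s%02d", substr(cond, 1, 2), seq_len(nrow(m))),
        condition = cond
      ),
      tibble::as_tibble(m)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("scale_matrix", class(out)))
}

test_that("comparison tables are asymmetric and complete off the diagonal", {
  sm <- scale_matrix_for(default_config(), rep_seed = 9001)
  cmp <- comparison_tables(sm)
  for (grid in list(cmp$p, cmp$d)) {
    expect_identical(grid$scale, c("multimodal", "visual", "auditory", "olfactory"))
    for (sc in grid$scale) {
      expect_true(is.na(grid[grid$scale == sc, ][[sc]]))
    }
    expect_false(anyNA(grid$all_others))
  }
  expect_true(all(cmp$p$all_others > 0 & cmp$p$all_others <= 1))
  # row scale != column scale: visual-vs-olfactory cells differ across rows
  expect_false(isTRUE(all.equal(
    cmp$p$olfactory[cmp$p$scale == "visual"],
    cmp$p$visual[cmp$p$scale == "olfactory"]
  )))
  missing_cond <- dplyr::filter(sm, condition != "olfactory")
  expect_error(comparison_tables(missing_cond), "olfactory")
})

test_that("Holm adjustment only ever increases p-values", {
  sm <- scale_matrix_for(default_config(), rep_seed = 9002)
  raw <- comparison_tables(sm)
  adj <- comparison_tables(sm, p_adjust = "holm")
  both <- dplyr::left_join(tidy(raw), tidy(adj), by = c("scale", "comparison"))
  expect_true(all(both$p_value.y >= both$p_value.x - 1e-15, na.rm = TRUE))
  expect_equal(adj$d, raw$d)  # effect sizes untouched
})

test_that("dominance ranking sorts unimodal scales by |d| to multimodal", {
  base <- matrix(0, 2, 4)
  sm <- fake_scale_matrix(list(
    visual = base, auditory = base, olfactory = base, multimodal = base
  ))
  # craft d values via group shifts on each unimodal scale's multimodal column
  sm$visual[sm$condition == "visual"] <- c(1.0, 1.4)      # |d| vs multimodal
  sm$auditory[sm$condition == "auditory"] <- c(0.2, 0.3)
  sm$olfactory[sm$condition == "olfactory"] <- c(2.2, 3.0)
  jitter <- withr::with_seed(3, rnorm(nrow(sm), sd = 0.4))
  for (cond in cue_conditions()) sm[[cond]] <- sm[[cond]] + jitter
  cmp <- comparison_tables(sm)
  dr <- dominance_ranking(cmp)
  d_of <- function(u) abs(cmp$d$multimodal[cmp$d$scale == u])
  expect_identical(dr$condition, unimodal_conditions()[order(
    vapply(unimodal_conditions(), d_of, numeric(1)))])
  expect_equal(dr$abs_d, sort(dr$abs_d))
})

test_that("tied dominance effect sizes fall back to the fixed condition order", {
  base <- matrix(0, 3, 4)
  sm <- fake_scale_matrix(list(
    visual = base, auditory = base, olfactory = base, multimodal = base
  ))
  # identical value patterns on every scale => identical |d| everywhere
  v <- c(-1, 0, 1)
  for (cond in cue_conditions()) sm[[cond]] <- rep(v, 4)
  dr <- dominance_ranking(comparison_tables(sm))
  expect_identical(dr$condition, c("visual", "auditory", "olfactory"))
})

test_that("confidence circles have the RMS-standard-error radius", {
  pts <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  ci <- condition_mean_ci(pts)
  # hand arithmetic: means 1,1; var_x = var_y = 4/3; radius = 1.96.. * sqrt(4/3)/2
  expect_equal(ci$mean_x, 1, tolerance = 1e-12)
  expect_equal(ci$mean_y, 1, tolerance = 1e-12)
  expect_equal(ci$radius, qnorm(0.975) * sqrt((4 / 3 + 4 / 3) / 2) / sqrt(4),
               tolerance = 1e-12)
  # identical points: zero radius at the point
  same <- condition_mean_ci(rbind(c(3, -1), c(3, -1)))
  expect_equal(same$radius, 0)
  expect_equal(c(same$mean_x, same$mean_y), c(3, -1))
  # doubled sample: exact hand formula, and ~1/sqrt(2) standard-error scaling
  pts8 <- rbind(pts, pts)
  ci2 <- condition_mean_ci(pts8)
  expect_equal(ci2$radius,
               qnorm(0.975) * sqrt((var(pts8[, 1]) + var(pts8[, 2])) / 2) /
                 sqrt(8),
               tolerance = 1e-12)
  expect_equal(ci2$radius, ci$radius / sqrt(2) * sqrt(6 / 7),
               tolerance = 1e-9)  # n-1 variance correction made explicit
  expect_error(condition_mean_ci(rbind(c(1, 2))), "at least 2")
})

test_that("point-in-triangle classification matches a half-plane oracle", {
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_identical(point_in_triangle(colMeans(tri), tri), "inside")
  expect_identical(point_in_triangle(c(0, 0), tri), "boundary")
  centroid <- colMeans(tri)
  edge_mid <- (tri[1, ] + tri[2, ]) / 2
  expect_identical(point_in_triangle(2 * edge_mid - centroid, tri), "outside")
  expect_error(point_in_triangle(c(1, 1), rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
  # brute-force same-side-of-each-edge oracle on random points
  half_plane_inside <- function(p, tri) {
    s <- vapply(list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)), function(idx) {
      a <- tri[idx[1], ]; b <- tri[idx[2], ]; c_ <- tri[idx[3], ]
      cr <- function(q) (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
      sign(cr(p)) == sign(cr(c_)) || cr(p) == 0
    }, logical(1))
    all(s)
  }
  withr::with_seed(12, {
    for (rep in 1:50) {
      p <- runif(2, -1, 5)
      expect_identical(point_in_triangle(p, tri) != "outside",
                       half_plane_inside(p, tri))
    }
  })
})

test_that("triangle test verdicts follow the geometry of the condition means", {
  base <- matrix(0, 20, 4)
  noise <- function(seed) withr::with_seed(seed, matrix(rnorm(80, sd = 0.05), 20, 4))
  # unimodal means pinned to a wide triangle in every unimodal projection
  vis <- base; vis[, 1:4] <- 2   # visual high on visual & others
  aud <- base; aud[, 1:4] <- -2
  olf <- base
  olf[, 1:4] <- rep(c(2, -2, 0, 0), each = 20)  # spread across axes
  centered <- (vis + aud + olf) / 3
  sm_in <- fake_scale_matrix(list(
    visual = vis + noise(1), auditory = aud + noise(2),
    olfactory = olf + noise(3), multimodal = centered + noise(4)
  ))
  tri_in <- triangular_test(sm_in, seed = 5)
  expect_true(all(tri_in$mean_inside))
  expect_true(all(tri_in$overlap_fraction > 0.99))
  expect_true(all(tri_in$circle_triangle_overlap))
  far <- centered + 50
  sm_out <- fake_scale_matrix(list(
    visual = vis + noise(1), auditory = aud + noise(2),
    olfactory = olf + noise(3), multimodal = far + noise(4)
  ))
  tri_out <- triangular_test(sm_out, seed = 5)
  expect_true(all(!tri_out$mean_inside))
  expect_true(all(tri_out$overlap_fraction == 0))
  expect_true(all(!tri_out$circle_triangle_overlap))
})

test_that("Monte-Carlo overlap agrees with the exact intersection test", {
  sm <- scale_matrix_for(default_config(), rep_seed = 9003)
  tri <- triangular_test(sm, projections = "all", seed = 6)
  expect_identical(tri$overlap_fraction > 0, tri$circle_triangle_overlap)
  expect_true(all(tri$overlap_fraction >= 0 & tri$overlap_fraction <= 1))
  expect_identical(nrow(tri), 6L)
  uni <- triangular_test(sm, seed = 6)
  expect_identical(nrow(uni), 3L)
  expect_error(triangular_test(sm, seed = 6, mc_samples = 100), "10000")
})

test_that("null t-test p-values are uniform over replicates", {
  withr::with_seed(99, {
    ps <- replicate(1000, {
      one_sided_t(rnorm(20), rnorm(20))
    })
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
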