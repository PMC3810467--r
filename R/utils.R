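# Internal numerical helpers.

# Least-squares fit of y on cbind(1, X) returning the coefficient vector.
# Falls back to the minimum-norm solution (via SVD pseudo-inverse) when the
# design is rank deficient; callers may inspect attr(, "rank_deficient").
ols_coef <- function(X, y) {
  A <- cbind(1, X)
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    keep <- sv$d > tol
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
    beta <- drop(beta)
    attr(beta, "rank_deficient") <- TRUE
    return(beta)
  }
  beta <- qr.coef(qr_A, y)
  attr(beta, "rank_deficient") <- FALSE
  beta
}

# Absolute Pearson correlation of each column of X with y; zero-variance
# columns (or zero-variance y) score 0 rather than NA.
abs_cor_with <- function(X, y) {
  r <- suppressWarnings(as.vector(cor(X, y)))
  r[!is.finite(r)] <- 0
  abs(r)
}

# Unit-normalize the rows of a matrix; rows with norm <= tol are flagged.
unit_rows <- function(m, tol = 1e-12) {
  norms <- sqrt(rowSums(m^2))
  zero <- norms <= tol
  list(vectors = m[!zero, , drop = FALSE] / norms[!zero], dropped = zero)
}

check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must have columns %s; missing: %s",
      what, paste(cols, collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

check_conditions <- function(x) {
  bad <- setdiff(unique(x), cue_conditions())
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown condition label(s): %s (must be one of %s)",
      paste(bad, collapse = ", "), paste(cue_conditions(), collapse = ", ")
    ))
  }
  invisible(x)
}
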