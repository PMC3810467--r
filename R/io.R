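# Readers and writers for the package's plain-text interchange formats.
# All are UTF-8 TSV (narratives may be CSV by extension); readers are strict
# by default and name the first malformed line, or drop bad lines with a
# warning in permissive mode.

read_delim_lines <- function(path, n_fields, what, strict = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!(lines == "" & seq_along(lines) == length(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad) > 0) {
    if (strict) {
      abort(sprintf("%s: line %d has %d field(s), expected %d",
                    what, bad[1], lengths(parts)[bad[1]], n_fields))
    }
    warn(sprintf("%s: dropping %d malformed line(s) (first at line %d)",
                 what, length(bad), bad[1]))
    parts <- parts[-bad]
  }
  parts
}

#' Read / write a 5-gram count file
#'
#' Headerless UTF-8 TSV with six columns `w1 w2 w3 w4 w5 count`.
#'
#' @param path File path.
#' @param strict Error on malformed lines (default) instead of dropping them.
#' @return Tibble with columns `w1`..`w5` and `count`.
#' @export
read_ngrams <- function(path, strict = TRUE) {
  parts <- read_delim_lines(path, 6L, "ngram file", strict)
  if (length(parts) == 0) abort("ngram file is empty")
  m <- do.call(rbind, parts)
  cnt <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(cnt)) {
    bad <- which(is.na(cnt))[1]
    if (strict) abort(sprintf("ngram file: line %d has a non-numeric count", bad))
    keep <- !is.na(cnt)
    m <- m[keep, , drop = FALSE]; cnt <- cnt[keep]
  }
  out <- as_tibble(m[, 1:5, drop = FALSE], .name_repair = ~paste0("w", 1:5))
  out$count <- cnt
  out
}

#' @rdname read_ngrams
#' @param ngrams Tibble as returned by [read_ngrams()].
#' @export
write_ngrams <- function(ngrams, path) {
  check_columns(ngrams, c(paste0("w", 1:5), "count"), "`ngrams`")
  readr::write_lines(
    paste(ngrams$w1, ngrams$w2, ngrams$w3, ngrams$w4, ngrams$w5,
          format(ngrams$count, scientific = FALSE, trim = TRUE), sep = "\t"),
    path
  )
  invisible(path)
}

#' Read / write a synonym-pair file
#'
#' Headerless UTF-8 TSV, two words per line.
#'
#' @inheritParams read_ngrams
#' @return Tibble with columns `word1`, `word2`.
#' @export
read_synonyms <- function(path, strict = TRUE) {
  parts <- read_delim_lines(path, 2L, "synonym file", strict)
  if (length(parts) == 0) abort("synonym file is empty")
  m <- do.call(rbind, parts)
  tibble(word1 = m[, 1], word2 = m[, 2])
}

#' @rdname read_synonyms
#' @param synonyms Tibble with two columns of words.
#' @export
write_synonyms <- function(synonyms, path) {
  readr::write_lines(paste(synonyms[[1]], synonyms[[2]], sep = "\t"), path)
  invisible(path)
}

#' Read / write a narratives table
#'
#' Delimited UTF-8 file with header `participant_id, condition, cue_id, text`;
#' comma-separated when the extension is `.csv`, tab-separated otherwise.
#'
#' @inheritParams read_ngrams
#' @return Tibble with the four narrative columns.
#' @export
read_narratives <- function(path, strict = TRUE) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    participant_id = readr::col_character(),
    condition = readr::col_character(),
    cue_id = readr::col_character(),
    text = readr::col_character()
  ), progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    msg <- sprintf("narratives file: %d parse problem(s), first at line %d",
                   nrow(probs), probs$row[1])
    if (strict) abort(msg) else warn(msg)
  }
  check_columns(out, c("participant_id", "condition", "cue_id", "text"),
                "narratives file")
  check_conditions(out$condition)
  out$text[is.na(out$text)] <- ""
  out
}

#' @rdname read_narratives
#' @param narratives Tibble with the four narrative columns.
#' @export
write_narratives <- function(narratives, path) {
  check_columns(narratives, c("participant_id", "condition", "cue_id", "text"),
                "`narratives`")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(narratives[, c("participant_id", "condition", "cue_id",
                                    "text")], path, delim = delim)
  invisible(path)
}

#' Read / write a word-class lexicon
#'
#' Headerless UTF-8 TSV `word<TAB>class`; classes must be among
#' [word_classes()].
#'
#' @inheritParams read_ngrams
#' @return Tibble with columns `word`, `word_class`.
#' @export
read_lexicon <- function(path, strict = TRUE) {
  parts <- read_delim_lines(path, 2L, "lexicon file", strict)
  if (length(parts) == 0) abort("lexicon file is empty")
  m <- do.call(rbind, parts)
  out <- tibble(word = m[, 1], word_class = m[, 2])
  validate_lexicon(out)
  out
}

#' @rdname read_lexicon
#' @param lexicon Tibble with columns `word`, `word_class`.
#' @export
write_lexicon <- function(lexicon, path) {
  validate_lexicon(lexicon)
  readr::write_lines(paste(lexicon$word, lexicon$word_class, sep = "\t"), path)
  invisible(path)
}

#' Read / write a semantic space
#'
#' UTF-8 TSV with a `#k=<k>` header line followed by `word<TAB>v1...<TAB>vk`
#' rows at full float precision.
#'
#' @inheritParams read_ngrams
#' @return A `semantic_space`.
#' @export
read_space <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) < 2 || !grepl("^#k=\\d+$", lines[1])) {
    abort("space file must start with a \"#k=<k>\" header line")
  }
  k <- as.integer(sub("^#k=", "", lines[1]))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != k + 1)
  if (length(bad) > 0) {
    abort(sprintf("space file: line %d has %d field(s), expected %d",
                  bad[1] + 1, lengths(parts)[bad[1]], k + 1))
  }
  m <- do.call(rbind, parts)
  vectors <- matrix(as.numeric(m[, -1, drop = FALSE]), ncol = k,
                    dimnames = list(m[, 1], NULL))
  as_semantic_space(vectors)
}

#' @rdname read_space
#' @param space A `semantic_space`.
#' @export
write_space <- function(space, path) {
  v <- space$vectors
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t")
  }, character(1))
  readr::write_lines(c(sprintf("#k=%d", space$k), body), path)
  invisible(path)
}

#' Write a semantic scale (long format)
#'
#' TSV with header `participant_id, condition, scale_target, value, z_value,
#' scope`, full float precision.
#'
#' @param scale A `semantic_scale`.
#' @param path File path.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "semantic_scale"))
  header <- "participant_id\tcondition\tscale_target\tvalue\tz_value\tscope"
  body <- sprintf("%s\t%s\t%s\t%.17g\t%.17g\t%s",
                  scale$participant_id, scale$condition,
                  attr(scale, "target") %||% NA_character_,
                  scale$value, scale$z_value, attr(scale, "scope"))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write a scale matrix (wide format)
#'
#' TSV with one row per participant and one column per scale, full float
#' precision.
#'
#' @param scale_matrix A [semantic_scale_matrix()] result.
#' @param path File path.
#' @export
write_scale_matrix <- function(scale_matrix, path) {
  cols <- intersect(cue_conditions(), names(scale_matrix))
  header <- paste(c("participant_id", "condition", cols), collapse = "\t")
  vals <- vapply(seq_len(nrow(scale_matrix)), function(i) {
    paste(sprintf("%.17g", unlist(scale_matrix[i, cols])), collapse = "\t")
  }, character(1))
  readr::write_lines(
    c(header, paste(scale_matrix$participant_id, scale_matrix$condition,
                    vals, sep = "\t")),
    path
  )
  invisible(path)
}
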