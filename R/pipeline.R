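#' Configuration for an end-to-end pipeline run
#'
#' Bundles the inputs (either file paths or an in-memory bundle from
#' [simulate_bundle()]) with the analysis parameters and seeds.
#'
#' @param bundle In-memory bundle (list with `ngrams`, `synonyms`,
#'   `narratives`, `lexicon`); mutually exclusive with the path arguments.
#' @param ngrams,synonyms,narratives,lexicon Input file paths.
#' @param row_size,col_size Vocabulary sizes (defaults: all words / 60).
#' @param k Space dimensionality; `NULL` selects it by the synonym test.
#' @param k_grid Candidate grid for selection (`NULL` for the doubling grid).
#' @param n_random Random pairs per synonym pair in the synonym test.
#' @param scope `"classes"` (per-word-class scales combined) or `"all"`.
#' @param subset_size Per-fold dimension budget (`NULL` for `floor(n / 2)`).
#' @param projections `"unimodal"` or `"all"` scale pairs for the triangle
#'   test.
#' @param mc_samples Monte-Carlo samples for the circle-triangle overlap.
#' @param seed Master seed; the synonym-test and Monte-Carlo seeds derive from
#'   it.
#' @param outdir Optional output directory for stage outputs and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bundle = NULL, ngrams = NULL, synonyms = NULL,
                            narratives = NULL, lexicon = NULL,
                            row_size = NULL, col_size = 60,
                            k = NULL, k_grid = NULL, n_random = 1000,
                            scope = c("classes", "all"), subset_size = NULL,
                            projections = c("unimodal", "all"),
                            mc_samples = 1e4, seed, outdir = NULL) {
  if (missing(seed)) abort("`seed` is mandatory")
  scope <- arg_match(scope)
  projections <- arg_match(projections)
  if (is.null(bundle)) {
    paths <- list(ngrams = ngrams, synonyms = synonyms,
                  narratives = narratives, lexicon = lexicon)
    missing_paths <- names(paths)[vapply(paths, is.null, logical(1))]
    if (length(missing_paths) > 0) {
      abort(sprintf("missing input path(s): %s",
                    paste(missing_paths, collapse = ", ")))
    }
    absent <- names(paths)[!vapply(paths, file.exists, logical(1))]
    if (length(absent) > 0) {
      abort(sprintf("input file(s) not found: %s",
                    paste(vapply(paths[absent], identity, character(1)),
                          collapse = ", ")))
    }
  }
  structure(
    list(bundle = bundle, ngrams = ngrams, synonyms = synonyms,
         narratives = narratives, lexicon = lexicon,
         row_size = row_size, col_size = col_size, k = k, k_grid = k_grid,
         n_random = n_random, scope = scope, subset_size = subset_size,
         projections = projections, mc_samples = mc_samples,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Sequences the stages end to end: build (or select) the semantic space from
#' the 5-gram corpus, aggregate participant narratives into representations,
#' construct the four leave-one-subject-out semantic scales, and run the
#' differential, dominance and triangular hypothesis tests. Fails fast with
#' the failing stage named. When the config has an `outdir`, the stage outputs
#' (space, scale matrix, comparison grids, triangle verdicts) and a run
#' manifest (config echo, per-stage counts, seeds, package version) are
#' written there; rerunning with identical config and seeds reproduces the
#' numeric outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return List with `space`, `selection`, `representations`, `scale_matrix`,
#'   `evaluation` (per-target predictive validity), `comparison`, `dominance`,
#'   `triangle`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage \"%s\" failed: %s", name,
                    conditionMessage(e)))
    })
  }
  inputs <- stage("read-inputs", {
    if (!is.null(config$bundle)) {
      config$bundle
    } else {
      list(
        ngrams = read_ngrams(config$ngrams),
        synonyms = read_synonyms(config$synonyms),
        narratives = read_narratives(config$narratives),
        lexicon = read_lexicon(config$lexicon)
      )
    }
  })
  space_stage <- stage("build-space", {
    vocab <- build_vocabulary(inputs$ngrams, row_size = config$row_size,
                              col_size = config$col_size)
    cooc <- log_normalize(count_cooccurrences(inputs$ngrams, vocab))
    if (is.null(config$k)) {
      sel <- select_dimensionality(
        cooc, inputs$synonyms, k_grid = config$k_grid,
        n_random = config$n_random, seed = config$seed + 101L
      )
      list(space = build_selected_space(sel), selection = sel)
    } else {
      list(space = build_space(cooc, config$k), selection = NULL)
    }
  })
  space <- space_stage$space
  selection <- space_stage$selection
  representations <- stage("represent", {
    aggregate_participants(inputs$narratives, space,
                           lexicon = inputs$lexicon,
                           by_class = config$scope == "classes")
  })
  scale_matrix <- stage("scales", {
    semantic_scale_matrix(representations, scope = config$scope,
                          subset_size = config$subset_size)
  })
  evaluation <- stage("evaluate", {
    participants <- distinct(inputs$narratives, .data$participant_id,
                             .data$condition)
    purrr::map_dfr(cue_conditions(), function(tg) {
      codes <- code_conditions(participants, tg)
      joined <- left_join(codes, scale_matrix[, c("participant_id", tg)],
                          by = "participant_id")
      mutate(evaluate_scale(joined[[tg]], joined), target = tg, .before = 1)
    })
  })
  comparison <- stage("test-differential", comparison_tables(scale_matrix))
  dominance <- stage("test-dominance", dominance_ranking(comparison))
  triangle <- stage("test-triangular", {
    triangular_test(scale_matrix, projections = config$projections,
                    mc_samples = config$mc_samples,
                    seed = config$seed + 202L)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("memscale")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    scope = config$scope,
    chosen_k = space$k,
    k_selected_by_synonym_test = is.null(config$k),
    n_participants = length(unique(inputs$narratives$participant_id)),
    n_narratives = nrow(inputs$narratives),
    n_space_words = nrow(space$vectors),
    n_dropped_words = length(space$dropped),
    n_scales = length(intersect(cue_conditions(), names(scale_matrix))),
    n_projections = nrow(triangle),
    tokens_used = sum(representations$n_tokens_used),
    tokens_oov = sum(representations$n_tokens_oov)
  )
  result <- list(
    space = space, selection = selection, representations = representations,
    scale_matrix = scale_matrix, evaluation = evaluation,
    comparison = comparison, dominance = dominance, triangle = triangle,
    manifest = manifest
  )
  if (!is.null(config$outdir)) {
    stage("write-outputs", {
      dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
      write_space(space, file.path(config$outdir, "space.tsv"))
      write_scale_matrix(scale_matrix,
                         file.path(config$outdir, "scale_matrix.tsv"))
      readr::write_tsv(comparison$p, file.path(config$outdir, "comparison_p.tsv"))
      readr::write_tsv(comparison$d, file.path(config$outdir, "comparison_d.tsv"))
      readr::write_tsv(dominance, file.path(config$outdir, "dominance.tsv"))
      jsonlite::write_json(tidy(triangle),
                           file.path(config$outdir, "triangle.json"),
                           auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  result
}
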