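# End-to-end study runner: files -> AHP -> strengths -> strategy -> report.

#' Study configuration
#'
#' Collects everything one SWOT-AHP study needs: a factor definition file
#' and either one comparison-matrix CSV per group or per-expert score
#' files to be aggregated first.  Exactly one of the two input routes must
#' be supplied.
#'
#' @param factor_file Path to the factor definition file (CSV or YAML).
#' @param matrix_files Named list/vector of matrix CSV paths, names being
#'   the group letters.
#' @param judgments_file,intensities_file Per-expert long-format CSVs (see
#'   [read_expert_scores()]); used when `matrix_files` is `NULL`.
#' @param aggregation `"arithmetic"` or `"geometric"` expert pooling.
#' @param cr_threshold CR acceptance threshold, default 0.1.
#' @param ri_table Random-index lookup, default [random_index_table()].
#' @param allow_inconsistent Keep going (with warnings) past CR failures.
#' @param maintain_band Passed to [build_strategy()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(factor_file, matrix_files = NULL,
                         judgments_file = NULL, intensities_file = NULL,
                         aggregation = "arithmetic", cr_threshold = 0.1,
                         ri_table = random_index_table(),
                         allow_inconsistent = FALSE,
                         maintain_band = c(0.45, 0.55)) {
  has_matrices <- !is.null(matrix_files)
  has_experts <- !is.null(judgments_file)
  if (has_matrices == has_experts) {
    stop_swot("config",
              "supply exactly one of matrix_files or expert score files")
  }
  paths <- c(factor_file, unlist(matrix_files), judgments_file,
             intensities_file)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop_swot("config", sprintf("missing input file(s): %s",
                                paste(missing, collapse = ", ")))
  }
  structure(list(factor_file = factor_file, matrix_files = matrix_files,
                 judgments_file = judgments_file,
                 intensities_file = intensities_file,
                 aggregation = aggregation, cr_threshold = cr_threshold,
                 ri_table = ri_table,
                 allow_inconsistent = allow_inconsistent,
                 maintain_band = maintain_band),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Keys mirror the arguments of [study_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) NULL
    else vapply(p, function(x) {
      if (file.exists(x)) x else file.path(base, x)
    }, "", USE.NAMES = TRUE)
  }
  study_config(
    factor_file = resolve(y$factor_file)[[1]],
    matrix_files = resolve(y$matrix_files),
    judgments_file = if (is.null(y$judgments_file)) NULL else
      resolve(y$judgments_file)[[1]],
    intensities_file = if (is.null(y$intensities_file)) NULL else
      resolve(y$intensities_file)[[1]],
    aggregation = y$aggregation %||% "arithmetic",
    cr_threshold = y$cr_threshold %||% 0.1,
    ri_table = if (is.null(y$ri_table)) random_index_table() else
      stats::setNames(as.numeric(y$ri_table), seq_along(y$ri_table)),
    allow_inconsistent = isTRUE(y$allow_inconsistent))
}

#' Run the full SWOT-AHP pipeline
#'
#' Loads factors and matrices (aggregating expert scores first if the
#' config uses the expert route), derives weights and runs the
#' consistency test per group, computes factor strengths and the four
#' signed totals, and builds the strategy quadrilateral.  A CR failure in
#' any group aborts (naming the group) unless `allow_inconsistent` is
#' set.
#'
#' @param config A `study_config`, or the path of a YAML study file.
#' @return An object of class `swot_study`: list with `factors`, `ahp`
#'   (per group), `strengths` (per group), `totals` and `strategy`.
#' @examples
#' study <- run_pipeline(media_health_config())
#' round(study$strategy$theta_deg, 2)  # -13.26
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  factors <- read_factors(config$factor_file)
  if (!is.null(config$matrix_files)) {
    mats <- lapply(names(config$matrix_files), function(g) {
      read_matrix_csv(config$matrix_files[[g]], group_id = g)
    })
    names(mats) <- names(config$matrix_files)
  } else {
    panel <- read_expert_scores(config$judgments_file,
                                config$intensities_file)
    mats <- aggregate_judgments(panel, method = config$aggregation)
    ints <- aggregate_intensities(panel)
    # aggregated intensities replace the factor file's (which may hold
    # placeholders when the expert route is used)
    for (g in names(ints)) {
      idx <- match(colnames(as.matrix(panel$intensities[[g]])), factors$id)
      if (!anyNA(idx)) factors$intensity[idx] <- ints[[g]]
    }
  }
  groups <- c("S", "W", "O", "T")
  if (!all(groups %in% names(mats))) {
    stop_swot("config", "need one comparison matrix per group S/W/O/T")
  }
  ahp <- lapply(mats[groups], consistency, ri_table = config$ri_table,
                cr_threshold = config$cr_threshold)
  strengths <- lapply(groups, function(g) {
    f <- factors[factors$group == g, , drop = FALSE]
    ids <- attr(mats[[g]], "factor_ids")
    f <- f[match(ids, f$id), , drop = FALSE]
    if (anyNA(f$id)) {
      stop_swot("config", sprintf(
        "group '%s': matrix factors not all present in the factor file", g))
    }
    factor_strengths(f, ahp[[g]],
                     allow_inconsistent = config$allow_inconsistent)
  })
  names(strengths) <- groups
  totals <- assemble_swot(strengths)
  structure(list(factors = factors, ahp = ahp, strengths = strengths,
                 totals = totals,
                 strategy = build_strategy(totals, config$maintain_band)),
            class = "swot_study")
}

#' @export
print.swot_study <- function(x, digits = 4, ...) {
  cat("SWOT-AHP study\n==============\n")
  for (g in names(x$ahp)) {
    print(x$ahp[[g]], digits = digits)
    cat("\n")
  }
  for (g in names(x$strengths)) print(x$strengths[[g]], digits = digits)
  cat("\n")
  print(x$strategy, digits = digits)
  invisible(x)
}

#' Render study artifacts to disk
#'
#' Writes a machine-readable JSON report at full precision, a
#' human-readable text report with values rounded (half-even) to four
#' decimals, and optionally the quadrilateral plot.
#'
#' @param study A `swot_study` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @param formats Character subset of `c("json", "text", "plot")`.
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(study, dir, formats = c("json", "text")) {
  stopifnot(inherits(study, "swot_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if ("json" %in% formats) {
    path <- file.path(dir, "study.json")
    writeLines(study_json(study), path)
    written["json"] <- path
  }
  if ("text" %in% formats) {
    path <- file.path(dir, "study.txt")
    txt <- utils::capture.output(print(study))
    writeLines(txt, path)
    written["text"] <- path
  }
  if ("plot" %in% formats) {
    path <- file.path(dir, "quadrilateral.svg")
    grDevices::svg(path, width = 6, height = 6)
    plot(study$strategy, main = "SWOT strategy quadrilateral")
    grDevices::dev.off()
    written["plot"] <- path
  }
  invisible(written)
}

#' Serialize a full study to JSON at full precision
#'
#' @param study A `swot_study`.
#' @return A JSON string.
#' @export
study_json <- function(study) {
  stopifnot(inherits(study, "swot_study"))
  jsonlite::toJSON(list(
    factors = study$factors,
    ahp = lapply(study$ahp, function(a) jsonlite::fromJSON(
      ahp_result_json(a))),
    strengths = lapply(study$strengths, function(s) list(
      group = s$group, factor_ids = s$factor_ids,
      intensities = s$intensities, weights = s$weights,
      factor_strengths = unname(s$factor_strengths), total = s$total)),
    totals = as.list(study$totals),
    strategy = jsonlite::fromJSON(strategy_json(study$strategy),
                                  simplifyVector = FALSE)),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
}

#' Configuration for the bundled worked example
#'
#' The package ships a complete published-style case study of new-media
#' empowerment of public health — four comparison matrices (4, 3, 4 and 3
#' factors for S, W, O, T) and expert-estimated intensities — under
#' `inst/extdata/media_health/`.  It exercises every pipeline stage and
#' anchors the regression tests.
#'
#' @return A `study_config` pointing at the installed fixture files.
#' @examples
#' study <- run_pipeline(media_health_config())
#' study$strategy$zone$label
#' @export
media_health_config <- function() {
  base <- system.file("extdata", "media_health", package = "swotahp",
                      mustWork = TRUE)
  study_config(
    factor_file = file.path(base, "factors.csv"),
    matrix_files = list(S = file.path(base, "matrix_S.csv"),
                        W = file.path(base, "matrix_W.csv"),
                        O = file.path(base, "matrix_O.csv"),
                        T = file.path(base, "matrix_T.csv")))
}
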