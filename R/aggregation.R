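# Delphi expert-panel pooling: judgments and intensities.

#' Construct an expert panel
#'
#' Holds the final-round Delphi scores of a panel of experts: for every
#' group, each expert's upper-triangle pairwise judgments, and each
#' expert's signed intensity score per factor.  Judgments are collected on
#' the upper triangle only — reciprocity is a scale convention, so the
#' lower triangle is implied — which also keeps the aggregated matrix
#' reciprocal by construction (the cell-wise arithmetic mean of full
#' reciprocal matrices is generally not reciprocal).
#'
#' @param judgments Named list (by group) of lists (by expert) of
#'   comparison matrices; only each matrix's upper triangle is read.
#' @param intensities Named list (by group) of numeric matrices, experts
#'   in rows, factors in columns.
#' @param expert_ids Optional expert identifiers.
#' @param strict_saaty Require every individual judgment to lie on the
#'   Saaty grid (default `TRUE`: raw expert scores are grid values).
#' @return An object of class `expert_panel`.
#' @export
expert_panel <- function(judgments, intensities, expert_ids = NULL,
                         strict_saaty = TRUE) {
  if (length(judgments) == 0) {
    stop_swot("panel", "empty panel: no judgment sets")
  }
  n_exp <- unique(vapply(judgments, length, 0L))
  if (length(n_exp) != 1 || n_exp == 0) {
    stop_swot("panel", "every group needs the same non-empty expert list")
  }
  if (is.null(expert_ids)) expert_ids <- paste0("E", seq_len(n_exp))
  if (length(expert_ids) != n_exp) {
    stop_swot("panel", "expert_ids length does not match the score sets")
  }
  for (g in names(judgments)) {
    dims <- vapply(judgments[[g]], function(m) nrow(as.matrix(m)), 0L)
    if (length(unique(dims)) != 1) {
      stop_swot("panel", sprintf(
        "group '%s': experts scored different factor sets", g))
    }
    # fill reciprocals for upper-triangle-only inputs, then validate
    judgments[[g]] <- lapply(judgments[[g]], function(m) {
      comparison_matrix(as.matrix(m), group_id = g, validate = FALSE)
    })
    for (m in judgments[[g]]) {
      v <- validate_matrix(m, strict_saaty = strict_saaty)
      if (length(v) > 0) {
        stop_swot("panel", sprintf("group '%s': %s", g, v[[1]]$message))
      }
    }
    if (!is.null(intensities[[g]]) &&
        ncol(as.matrix(intensities[[g]])) != dims[1]) {
      stop_swot("panel", sprintf(
        "group '%s': intensity columns do not match factor count", g))
    }
  }
  structure(list(judgments = judgments, intensities = intensities,
                 expert_ids = expert_ids),
            class = "expert_panel")
}

#' Aggregate expert judgments into one comparison matrix per group
#'
#' Pools the experts' upper-triangle Saaty scores cell by cell — by the
#' arithmetic mean (the default, matching Delphi consensus practice of
#' averaging final-round scores) or the geometric mean (the classical AHP
#' recommendation for ratio-scale judgments) — then mirrors reciprocals
#' into the lower triangle.  Aggregated cells are not snapped back to the
#' Saaty grid.
#'
#' @param panel An `expert_panel`.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return Named list of `comparison_matrix` objects, one per group.
#' @examples
#' a <- rbind(c(1, 3), c(NA, 1)); b <- rbind(c(1, 5), c(NA, 1))
#' p <- expert_panel(list(S = list(a, b)),
#'                   intensities = list(S = rbind(c(2, 4), c(4, 6))))
#' aggregate_judgments(p)$S[1, 2]                        # 4
#' aggregate_judgments(p, "geometric")$S[1, 2]           # sqrt(15)
#' @export
aggregate_judgments <- function(panel, method = c("arithmetic", "geometric")) {
  stopifnot(inherits(panel, "expert_panel"))
  method <- match.arg(method)
  out <- lapply(names(panel$judgments), function(g) {
    ms <- lapply(panel$judgments[[g]], as.matrix)
    n <- nrow(ms[[1]])
    upper <- vapply(ms, function(m) m[upper.tri(m)],
                    numeric(n * (n - 1) / 2))
    upper <- matrix(upper, ncol = length(ms))
    agg <- switch(method,
                  arithmetic = rowMeans(upper),
                  geometric = exp(rowMeans(log(upper))))
    m <- matrix(NA_real_, n, n)
    m[upper.tri(m)] <- agg
    ids <- colnames(ms[[1]]) %||% paste0(g, seq_len(n))
    comparison_matrix(m, factor_ids = ids, group_id = g)
  })
  names(out) <- names(panel$judgments)
  out
}

#' Aggregate expert intensity scores
#'
#' Arithmetic mean per factor across experts, preserving sign.  All
#' experts must agree on the sign of each factor (the group's sign
#' convention makes a mixed-sign factor a scoring error, not a tie to
#' average away); means are typically non-integer.
#'
#' @param panel An `expert_panel`.
#' @return Named list (by group) of numeric mean-intensity vectors.
#' @export
aggregate_intensities <- function(panel) {
  stopifnot(inherits(panel, "expert_panel"))
  out <- lapply(names(panel$intensities), function(g) {
    sc <- as.matrix(panel$intensities[[g]])
    signs <- apply(sc, 2, function(col) length(unique(sign(col))))
    if (any(signs != 1)) {
      stop_swot("sign_convention", sprintf(
        "group '%s': experts disagree on the sign of factor(s) %s",
        g, paste(which(signs != 1), collapse = ", ")))
    }
    colMeans(sc)
  })
  names(out) <- names(panel$intensities)
  out
}

#' Read per-expert scores from CSV
#'
#' Two long-format files: judgments with columns
#' `expert, group, factor_i, factor_j, score` (upper-triangle pairs only)
#' and intensities with columns `expert, group, factor, intensity`.
#'
#' @param judgments_path,intensities_path CSV file paths.
#' @param strict_saaty Passed to [expert_panel()].
#' @return An `expert_panel`.
#' @export
read_expert_scores <- function(judgments_path, intensities_path,
                               strict_saaty = TRUE) {
  jd <- utils::read.csv(judgments_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  it <- utils::read.csv(intensities_path, stringsAsFactors = FALSE)
  experts <- unique(jd$expert)
  judgments <- lapply(split(jd, jd$group), function(gdf) {
    ids <- unique(c(gdf$factor_i, gdf$factor_j))
    ids <- ids[order(ids)]
    lapply(experts, function(e) {
      edf <- gdf[gdf$expert == e, ]
      m <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
      for (r in seq_len(nrow(edf))) {
        m[edf$factor_i[r], edf$factor_j[r]] <- parse_judgment(edf$score[r])
      }
      diag(m) <- 1
      if (anyNA(m[upper.tri(m)])) {
        stop_swot("panel", sprintf(
          "expert '%s' left pairs unscored in group '%s'", e,
          gdf$group[1]))
      }
      m[lower.tri(m)] <- 1 / t(m)[lower.tri(m)]
      m
    })
  })
  intensities <- lapply(split(it, it$group), function(gdf) {
    ids <- unique(gdf$factor)
    t(vapply(experts, function(e) {
      edf <- gdf[gdf$expert == e, ]
      stats::setNames(edf$intensity[match(ids, edf$factor)], ids)
    }, numeric(length(ids))))
  })
  expert_panel(judgments, intensities, expert_ids = experts,
               strict_saaty = strict_saaty)
}
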