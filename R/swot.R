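# Factor strengths and group totals: strength_i = intensity_i x weight_i.

#' Define SWOT factors
#'
#' Builds the factor table for one study: identifier, group letter,
#' free-text description and the expert-estimated signed intensity.  The
#' sign convention is enforced: strengths (S) and opportunities (O) carry
#' positive intensities, weaknesses (W) and threats (T) negative ones, and
#' every magnitude lies on (or, after Delphi averaging, within) the 1..9
#' judgment scale.
#'
#' @param id Character vector of factor ids (e.g. `"S1"`).
#' @param group Group letter per factor, each one of `"S"`, `"W"`, `"O"`,
#'   `"T"`.
#' @param intensity Signed numeric intensity per factor (need not be an
#'   integer: Delphi panel means are accepted).
#' @param description Optional free text per factor.
#' @param validate Check the sign convention and `|intensity| <= 9`.
#' @return A `data.frame` of class `swot_factors` with columns `id`,
#'   `group`, `intensity`, `description`.
#' @export
swot_factors <- function(id, group, intensity, description = "",
                         validate = TRUE) {
  df <- data.frame(id = as.character(id), group = as.character(group),
                   intensity = as.numeric(intensity),
                   description = rep_len(as.character(description),
                                         length(id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) {
    stop_swot("factors", "duplicated factor ids")
  }
  bad <- !df$group %in% c("S", "W", "O", "T")
  if (any(bad)) {
    stop_swot("factors", sprintf("unknown group for factor(s): %s",
                                 paste(df$id[bad], collapse = ", ")))
  }
  if (validate) {
    check_intensity_signs(df$intensity, df$group, df$id)
  }
  structure(df, class = c("swot_factors", "data.frame"))
}

check_intensity_signs <- function(intensity, group, id) {
  pos <- group %in% c("S", "O")
  bad_sign <- (pos & intensity <= 0) | (!pos & intensity >= 0)
  if (any(bad_sign)) {
    stop_swot("sign_convention", sprintf(
      "intensity sign violates the S/O positive, W/T negative convention for: %s",
      paste(id[bad_sign], collapse = ", ")))
  }
  too_big <- abs(intensity) > 9
  if (any(too_big)) {
    stop_swot("sign_convention", sprintf(
      "|intensity| exceeds the 1-9 scale for: %s",
      paste(id[too_big], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a factor definition file
#'
#' Accepts CSV (columns `id`, `group`, `intensity`, optional `description`)
#' or YAML (a list of records with the same fields, or a top-level
#' `factors:` key holding one).
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` vs
#'   anything else = CSV).
#' @param validate Passed to [swot_factors()].
#' @return A `swot_factors` table.
#' @export
read_factors <- function(path, validate = TRUE) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$factors)) y <- y$factors
    df <- do.call(rbind, lapply(y, function(f) {
      data.frame(id = f$id, group = f$group,
                 intensity = as.numeric(f$intensity),
                 description = f$description %||% "",
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(df$description)) df$description <- ""
  }
  need <- setdiff(c("id", "group", "intensity"), names(df))
  if (length(need) > 0) {
    stop_swot("parse", sprintf("factor file '%s' lacks column(s): %s",
                               path, paste(need, collapse = ", ")))
  }
  swot_factors(df$id, df$group, df$intensity, df$description,
               validate = validate)
}

#' Per-factor strengths and the group total
#'
#' Multiplies each factor's signed estimated intensity by its AHP weight
#' (`strength_i = I_i * w_i`) and sums over the group.  Because the weights
#' are a convex combination, the group total is bounded by the largest
#' intensity magnitude, and its sign follows the group's sign convention.
#'
#' @param factors A `swot_factors` table (all rows one group) or a
#'   data.frame with columns `id`, `group`, `intensity`.
#' @param ahp An `ahp_result` for the same factors in the same order, or a
#'   bare weight vector.
#' @param allow_inconsistent Proceed (with a warning) when the AHP result
#'   failed its consistency test.  Default `FALSE`: inconsistent judgments
#'   make the weights unreliable.
#' @param validate_signs Enforce the sign convention on intensities.  Set
#'   to `FALSE` for exploratory inputs such as all-zero intensities.
#' @return An object of class `group_strength`: list with `group`,
#'   `factor_ids`, `intensities`, `weights`, `factor_strengths`, `total`.
#' @examples
#' m <- comparison_matrix(rbind(c(1, 1/7, 1/2), c(7, 1, 4), c(2, 1/4, 1)),
#'                        group_id = "W")
#' f <- swot_factors(c("W1", "W2", "W3"), "W", c(-2, -5, -1))
#' factor_strengths(f, consistency(m))$total  # -3.9581
#' @export
factor_strengths <- function(factors, ahp, allow_inconsistent = FALSE,
                             validate_signs = TRUE) {
  group <- unique(factors$group)
  if (length(group) != 1) {
    stop_swot("factors", "factor_strengths() expects a single group")
  }
  if (inherits(ahp, "ahp_result")) {
    w <- ahp$weights
    if (!ahp$consistent) {
      if (!allow_inconsistent) {
        stop_swot("inconsistent", sprintf(
          "group '%s' failed the consistency test (CR = %.4f >= 0.1)",
          group, ahp$cr))
      }
      warning(sprintf(
        "group '%s' failed the consistency test (CR = %.4f); proceeding",
        group, ahp$cr))
    }
  } else {
    w <- as.numeric(ahp)
  }
  if (length(w) != nrow(factors)) {
    stop_swot("dim_mismatch", sprintf(
      "group '%s': %d weights for %d factors", group, length(w),
      nrow(factors)))
  }
  if (validate_signs) {
    check_intensity_signs(factors$intensity, factors$group, factors$id)
  }
  s <- factors$intensity * unname(w)
  names(s) <- factors$id
  structure(list(group = group, factor_ids = factors$id,
                 intensities = factors$intensity, weights = unname(w),
                 factor_strengths = s, total = sum(s)),
            class = "group_strength")
}

#' @export
print.group_strength <- function(x, digits = 4, ...) {
  cat(sprintf("Group %s strengths:\n", x$group))
  tab <- data.frame(factor = x$factor_ids, weight = round(x$weights, digits),
                    intensity = x$intensities,
                    strength = round(x$factor_strengths, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("total = %.*f\n", digits, x$total))
  invisible(x)
}

#' Assemble the four signed group totals
#'
#' Collects one [factor_strengths()] result per SWOT group into the ordered
#' quadruple (S', W', O', T') that defines the strategy quadrilateral.
#'
#' @param groups List of four `group_strength` objects, one per letter, in
#'   any order.
#' @return Named numeric vector `c(S = S', W = W', O = O', T = T')`.
#' @export
assemble_swot <- function(groups) {
  letters4 <- vapply(groups, function(g) g$group, "")
  if (!setequal(letters4, c("S", "W", "O", "T")) ||
      anyDuplicated(letters4)) {
    stop_swot("groups", sprintf(
      "need exactly one group per letter S/W/O/T, got: %s",
      paste(sort(letters4), collapse = ", ")))
  }
  totals <- vapply(groups, function(g) g$total, 0)
  out <- totals[match(c("S", "W", "O", "T"), letters4)]
  names(out) <- c("S", "W", "O", "T")
  out
}
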