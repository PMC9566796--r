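# AHP weight derivation (sum-product method) and the consistency test.

#' Random consistency index table
#'
#' Average consistency index of randomly filled reciprocal matrices, by
#' matrix order n = 1..9, as used by the CR = CI/RI test.  Note the values
#' at n = 3 and n = 4 (0.52, 0.89) differ slightly from Saaty's classic
#' table (0.58, 0.90); this variant is the package default and can be
#' overridden per call via the `ri_table` argument of [consistency()].
#'
#' @return Named numeric vector; names are the orders "1".."9".
#' @export
random_index_table <- function() {
  c("1" = 0, "2" = 0, "3" = 0.52, "4" = 0.89, "5" = 1.12,
    "6" = 1.26, "7" = 1.36, "8" = 1.41, "9" = 1.46)
}

#' Derive priority weights by the sum-product method
#'
#' The arithmetic-mean (sum-product) approximation of the principal
#' eigenvector: each column of the judgment matrix is divided by its column
#' sum, then each row of the normalised matrix is averaged.  The result is
#' a positive weight vector summing to 1.  This approximation — not power
#' iteration — is the package's weight definition; the exact eigenvector
#' differs in the third decimal for mildly inconsistent matrices and is
#' used only as a cross-check in the test suite.
#'
#' @param m A `comparison_matrix` (or plain positive square matrix).
#' @return Named numeric weight vector, one entry per factor.
#' @examples
#' m <- comparison_matrix(rbind(c(1, 1/7, 1/2), c(7, 1, 4), c(2, 1/4, 1)),
#'                        group_id = "W")
#' compute_weights(m)  # 0.0978 0.7151 0.1871
#' @export
compute_weights <- function(m) {
  m <- assert_valid_matrix(m)
  w <- rowMeans(sweep(m, 2, colSums(m), "/"))
  names(w) <- colnames(m)
  w
}

#' Weighted row sums AW of the judgment matrix
#'
#' Multiplies the original (not the column-normalised) judgment matrix by
#' the weight vector: `AW = A %*% w`.  The ratio `AW_i / w_i` estimates the
#' principal eigenvalue along each row and feeds [consistency()].
#'
#' @param m A `comparison_matrix`.
#' @param weights Weight vector, typically from [compute_weights()].
#' @return Named numeric vector `AW`.
#' @export
compute_aw <- function(m, weights) {
  m <- assert_valid_matrix(m)
  if (length(weights) != nrow(m)) {
    stop_swot("dim_mismatch", sprintf(
      "weights length %d does not match matrix order %d",
      length(weights), nrow(m)))
  }
  aw <- as.vector(m %*% weights)
  names(aw) <- colnames(m)
  aw
}

#' AHP consistency test of a judgment matrix
#'
#' Computes the full consistency diagnostic for one pairwise-comparison
#' matrix: sum-product weights, `AW`, the maximum-eigenvalue estimate
#' `lambda_max = mean(AW_i / w_i)`, the consistency index
#' `CI = (lambda_max - n) / (n - 1)`, the random index RI from
#' [random_index_table()] and the consistency ratio `CR = CI / RI`.  The
#' matrix passes when `CR < cr_threshold` (strict: CR exactly at the
#' threshold fails).  For n <= 2 the random index is 0 and any reciprocal
#' matrix is perfectly consistent; CR is then defined as 0.
#'
#' @param m A `comparison_matrix` of order 2..9 (order 1 is accepted as the
#'   degenerate single-factor case).
#' @param ri_table Optional replacement RI lookup, a numeric vector indexed
#'   by order as in [random_index_table()].
#' @param cr_threshold Acceptance threshold for CR, default 0.1.
#' @return An object of class `ahp_result`: list with `group_id`,
#'   `factor_ids`, `n`, `weights`, `aw`, `column_sums`, `lambda_max`, `ci`,
#'   `ri`, `cr`, `consistent`.
#' @examples
#' m <- comparison_matrix(rbind(c(1, 1/7, 1/2), c(7, 1, 4), c(2, 1/4, 1)),
#'                        group_id = "W")
#' consistency(m)  # lambda_max 3.002, CR 0.0019, consistent
#' @export
consistency <- function(m, ri_table = random_index_table(),
                        cr_threshold = 0.1) {
  if (length(m) == 1 && is.numeric(m)) {  # degenerate one-factor group
    return(new_ahp_result(attr(m, "group_id") %||% "G", "F1", 1,
                          weights = 1, aw = 1, column_sums = 1,
                          lambda_max = 1, ci = 0, ri = 0, cr = 0,
                          consistent = TRUE))
  }
  m <- assert_valid_matrix(m)
  n <- nrow(m)
  if (n > length(ri_table) || is.na(ri_table[n])) {
    stop_swot("order", sprintf(
      "no random index for order %d: consistency test undefined", n))
  }
  w <- compute_weights(m)
  aw <- compute_aw(m, w)
  lambda_max <- mean(aw / w)
  ci <- (lambda_max - n) / (n - 1)
  ri <- unname(ri_table[n])
  cr <- if (ri > 0) ci / ri else 0
  new_ahp_result(attr(m, "group_id") %||% "G", colnames(m), n,
                 weights = w, aw = aw, column_sums = colSums(m),
                 lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
                 consistent = cr < cr_threshold)
}

new_ahp_result <- function(group_id, factor_ids, n, weights, aw, column_sums,
                           lambda_max, ci, ri, cr, consistent) {
  structure(list(group_id = group_id, factor_ids = factor_ids, n = n,
                 weights = weights, aw = aw, column_sums = column_sums,
                 lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
                 consistent = consistent),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, digits = 4, ...) {
  cat(sprintf("AHP result for group '%s' (n = %d)\n", x$group_id, x$n))
  tab <- data.frame(factor = x$factor_ids,
                    weight = round(x$weights, digits),
                    AW = round(x$aw, digits), row.names = NULL)
  print(tab, row.names = FALSE)
  cat(sprintf("lambda_max = %.*f, CI = %.*f, RI = %.2f, CR = %.*f -> %s\n",
              digits, x$lambda_max, digits, x$ci, x$ri, digits, x$cr,
              if (x$consistent) "consistent (CR < 0.1)" else "INCONSISTENT"))
  invisible(x)
}

#' Serialize an AHP result to JSON
#'
#' Full-precision JSON with fields `weights`, `aw`, `lambda_max`, `ci`,
#' `ri`, `cr`, `consistent` (plus `group_id` and `factor_ids`).
#'
#' @param x An `ahp_result`.
#' @param ... Passed to [jsonlite::toJSON()].
#' @return A JSON string.
#' @export
ahp_result_json <- function(x, ...) {
  stopifnot(inherits(x, "ahp_result"))
  jsonlite::toJSON(list(
    group_id = x$group_id, factor_ids = x$factor_ids,
    weights = unname(x$weights), aw = unname(x$aw),
    lambda_max = x$lambda_max, ci = x$ci, ri = x$ri, cr = x$cr,
    consistent = x$consistent), auto_unbox = TRUE, digits = NA, ...)
}

assert_valid_matrix <- function(m) {
  if (!inherits(m, "comparison_matrix")) {
    m <- comparison_matrix(m, validate = TRUE)
  }
  unclass(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
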