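# Pairwise-comparison matrices on the Saaty 1-9 scale.

#' The Saaty judgment grid
#'
#' The admissible values of a pairwise judgment: the integers 1..9 and their
#' reciprocals 1/2..1/9.  1 means equal importance, 9 extreme importance of
#' the row factor over the column factor; a reciprocal expresses the inverse
#' preference.
#'
#' @return Numeric vector of the 17 grid values, sorted increasing.
#' @export
saaty_scale <- function() {
  sort(c(1 / (9:2), 1:9))
}

#' Construct a pairwise-comparison matrix
#'
#' Wraps a square matrix of Saaty judgments for one SWOT group (or any other
#' criterion set) together with its factor identifiers.  If only the upper
#' triangle is supplied (lower triangle `NA`), the lower triangle and the
#' unit diagonal are filled in by the reciprocal convention `a_ji = 1/a_ij`.
#' Fully specified matrices are checked, not repaired: an inconsistent lower
#' triangle is reported by [validate_matrix()], never silently overwritten.
#'
#' @param entries Square numeric matrix (judgments), or anything coercible
#'   by [as.matrix()].  `NA` below the diagonal (and on it) requests
#'   reciprocal auto-fill.
#' @param factor_ids Character vector of factor identifiers, one per row.
#'   Defaults to existing dimnames or `F1..Fn`.
#' @param group_id Label for the criterion group, conventionally one of
#'   `"S"`, `"W"`, `"O"`, `"T"`.
#' @param validate If `TRUE` (default), fail on any invariant violation.
#' @param strict_saaty Require every entry to lie exactly on the Saaty grid
#'   (within relative tolerance 1e-9).  Off by default: aggregated expert
#'   judgments are legitimately off-grid.
#' @return An object of class `comparison_matrix`: the numeric matrix with
#'   attributes `group_id` and `factor_ids`.
#' @seealso [validate_matrix()], [read_matrix_csv()]
#' @examples
#' m <- comparison_matrix(rbind(c(1, 3, 5), c(NA, 1, 2), c(NA, NA, 1)))
#' m[3, 1]  # 1/5, filled by reciprocity
#' @export
comparison_matrix <- function(entries, factor_ids = NULL, group_id = "G",
                              validate = TRUE, strict_saaty = FALSE) {
  m <- as.matrix(entries)
  if (!is.numeric(m)) {
    storage.mode(m) <- "double"
  }
  if (nrow(m) != ncol(m)) {
    stop_swot("non_square", sprintf(
      "comparison matrix must be square, got %d x %d", nrow(m), ncol(m)))
  }
  n <- nrow(m)
  if (is.null(factor_ids)) {
    factor_ids <- rownames(m)
    if (is.null(factor_ids)) factor_ids <- paste0("F", seq_len(n))
  }
  if (length(factor_ids) != n) {
    stop_swot("bad_ids", "factor_ids length does not match matrix order")
  }
  # upper-triangle input: mirror reciprocals, set unit diagonal
  if (anyNA(m[lower.tri(m, diag = TRUE)]) && !anyNA(m[upper.tri(m)])) {
    diag(m) <- 1
    m[lower.tri(m)] <- 1 / t(m)[lower.tri(m)]
  }
  dimnames(m) <- list(factor_ids, factor_ids)
  out <- structure(m, class = "comparison_matrix",
                   group_id = group_id, factor_ids = factor_ids)
  if (validate) {
    v <- validate_matrix(out, strict_saaty = strict_saaty)
    if (length(v) > 0) {
      stop_swot("invalid_matrix", paste(
        c("invalid comparison matrix:", vapply(v, `[[`, "", "message")),
        collapse = "\n  "))
    }
  }
  out
}

#' @export
print.comparison_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise comparison matrix '%s' (%d factors)\n",
              attr(x, "group_id"), nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Validate a pairwise-comparison matrix
#'
#' Checks the structural invariants of a Saaty judgment matrix: square
#' shape, order between 2 and 9 (the random-index table stops at 9),
#' positivity, a unit diagonal, reciprocity `a_ji = 1/a_ij` within relative
#' tolerance 1e-9 and, optionally, membership of every entry in the Saaty
#' grid.
#'
#' @param m Matrix or `comparison_matrix`.
#' @param strict_saaty Also require every entry to be a grid value.
#' @return A list of violations, empty when the matrix is valid.  Each
#'   violation is a list with elements `rule` (one of `"non_square"`,
#'   `"order"`, `"positive"`, `"diagonal"`, `"reciprocal"`, `"saaty_scale"`),
#'   `cells` (matrix of offending `(i, j)` indices, possibly empty) and a
#'   human-readable `message`.
#' @export
validate_matrix <- function(m, strict_saaty = FALSE) {
  m <- as.matrix(m)
  violations <- list()
  add <- function(rule, cells, message) {
    violations[[length(violations) + 1L]] <<-
      list(rule = rule, cells = cells, message = message)
  }
  if (nrow(m) != ncol(m)) {
    add("non_square", cbind(i = integer(), j = integer()),
        sprintf("matrix is %d x %d, not square", nrow(m), ncol(m)))
    return(violations)
  }
  n <- nrow(m)
  if (n < 2 || n > 9) {
    add("order", cbind(i = integer(), j = integer()),
        sprintf("matrix order %d outside the supported range 2..9", n))
  }
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    add("positive", bad, sprintf(
      "non-positive or non-finite entries at %s",
      paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", ")))
    return(violations)  # remaining checks assume positive entries
  }
  d <- which(abs(diag(m) - 1) > 1e-9)
  if (length(d) > 0) {
    add("diagonal", cbind(i = d, j = d),
        sprintf("diagonal entries differ from 1 at %s",
                paste(d, collapse = ", ")))
  }
  rel <- abs(m * t(m) - 1)  # a_ij * a_ji = 1 under reciprocity
  bad <- which(rel > 1e-9 & lower.tri(rel), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    add("reciprocal", bad, sprintf(
      "reciprocity a_ji = 1/a_ij violated at %s",
      paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", ")))
  }
  if (strict_saaty) {
    grid <- saaty_scale()
    off <- matrix(
      vapply(m, function(x) min(abs(x - grid)) > 1e-9 * max(1, x), NA),
      n, n)
    bad <- which(off, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      add("saaty_scale", bad, sprintf(
        "entries off the 1-9 / reciprocal grid at %s",
        paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", ")))
    }
  }
  violations
}

#' Read a comparison matrix from CSV
#'
#' Expects the dialect: first row a header of factor ids, one body row per
#' factor whose first cell repeats the factor id, remaining cells judgments
#' written either as decimals or as fraction strings such as `"1/7"`.
#' Fractions are parsed as numerator over denominator, not via string
#' `eval`.  Cells left empty below the diagonal are auto-filled as
#' reciprocals.
#'
#' @param path CSV file path.
#' @param group_id Group label; defaults to the file name without extension.
#' @param ... Passed to [comparison_matrix()] (e.g. `strict_saaty`).
#' @return A `comparison_matrix`.
#' @export
read_matrix_csv <- function(path, group_id = NULL, ...) {
  if (is.null(group_id)) {
    group_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                         colClasses = "character", strip.white = TRUE)
  ids <- colnames(raw)
  if (!identical(rownames(raw), ids)) {
    stop_swot("parse", sprintf(
      "matrix CSV '%s': row ids must equal column ids in order", path))
  }
  m <- apply(as.matrix(raw), c(1, 2), parse_judgment)
  comparison_matrix(m, factor_ids = ids, group_id = group_id, ...)
}

#' Write a comparison matrix to CSV
#'
#' Inverse of [read_matrix_csv()]: grid values are written back as exact
#' fraction strings (`"1/7"`), off-grid values as full-precision decimals.
#'
#' @param m A `comparison_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  ids <- attr(m, "factor_ids")
  chr <- matrix(vapply(as.vector(m), format_judgment, ""), nrow(m),
                dimnames = list(ids, ids))
  utils::write.csv(as.data.frame(chr, check.names = FALSE), path,
                   quote = FALSE)
  invisible(path)
}

# "1/7" -> 1/7; "0.25" -> 0.25; "" / NA -> NA (reciprocal auto-fill)
parse_judgment <- function(x) {
  x <- trimws(x)
  if (is.na(x) || x == "") return(NA_real_)
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (length(num) != 2 || anyNA(num) || num[2] == 0) {
      stop_swot("parse", sprintf("cannot parse judgment '%s'", x))
    }
    return(num[1] / num[2])
  }
  out <- suppressWarnings(as.numeric(x))
  if (is.na(out)) stop_swot("parse", sprintf("cannot parse judgment '%s'", x))
  out
}

format_judgment <- function(x) {
  for (k in 2:9) {
    if (abs(x - 1 / k) < 1e-12) return(sprintf("1/%d", k))
  }
  if (abs(x - round(x)) < 1e-12) return(sprintf("%d", as.integer(round(x))))
  format(x, digits = 17)
}

# classed conditions so callers (and the CLI) can map errors to exit codes
stop_swot <- function(code, message) {
  stop(structure(
    class = c(paste0("swotahp_", code), "swotahp_error", "error", "condition"),
    list(message = message, call = sys.call(-1))))
}
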