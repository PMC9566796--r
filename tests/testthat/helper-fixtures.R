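# In-code copy of the bundled media-health study inputs, so unit tests do
# not depend on system.file() resolution.

fixture_matrices <- function() {
  list(
    S = comparison_matrix(rbind(c(1, 1/2, 1/3, 1/7),
                                c(2, 1,   1/5, 1/6),
                                c(3, 5,   1,   1/4),
                                c(7, 6,   4,   1)),
                          factor_ids = paste0("S", 1:4), group_id = "S"),
    W = comparison_matrix(rbind(c(1, 1/7, 1/2),
                                c(7, 1,   4),
                                c(2, 1/4, 1)),
                          factor_ids = paste0("W", 1:3), group_id = "W"),
    O = comparison_matrix(rbind(c(1,   2,   1/2, 4),
                                c(1/2, 1,   1/3, 3),
                                c(2,   3,   1,   5),
                                c(1/4, 1/3, 1/5, 1)),
                          factor_ids = paste0("O", 1:4), group_id = "O"),
    T = comparison_matrix(rbind(c(1,   2, 1/3),
                                c(1/2, 1, 1/5),
                                c(3,   5, 1)),
                          factor_ids = paste0("T", 1:3), group_id = "T"))
}

fixture_intensities <- function() {
  list(S = c(1, 2, 4, 6), W = c(-2, -5, -1),
       O = c(4, 3, 6, 2), T = c(-3, -2, -6))
}

fixture_factors <- function() {
  ints <- fixture_intensities()
  swot_factors(
    id = c(paste0("S", 1:4), paste0("W", 1:3),
           paste0("O", 1:4), paste0("T", 1:3)),
    group = rep(c("S", "W", "O", "T"), times = c(4, 3, 4, 3)),
    intensity = unlist(ints, use.names = FALSE))
}

fixture_strategy <- function() {
  mats <- fixture_matrices()
  ints <- fixture_intensities()
  strengths <- lapply(names(mats), function(g) {
    f <- swot_factors(attr(mats[[g]], "factor_ids"),
                      rep(g, nrow(mats[[g]])), ints[[g]])
    factor_strengths(f, consistency(mats[[g]]))
  })
  build_strategy(assemble_swot(strengths))
}

# random on-grid reciprocal matrix (upper triangle uniform over the grid)
random_saaty_matrix <- function(n) {
  m <- matrix(NA_real_, n, n)
  m[upper.tri(m)] <- sample(saaty_scale(), n * (n - 1) / 2, replace = TRUE)
  comparison_matrix(m)
}

random_weights <- function(n) {
  w <- stats::runif(n, 0.05, 1)
  w / sum(w)
}
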