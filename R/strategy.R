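# Strategy quadrilateral: centroid, azimuth, zone, intensity coefficient.

#' Build the strategy quadrilateral from the four group totals
#'
#' Places the signed totals as the vertices (S', 0), (0, O'), (W', 0),
#' (0, T') of a convex quadrilateral containing the origin, takes the
#' centroid as the arithmetic mean of the four vertices, and derives the
#' strategic azimuth theta (the centroid's direction from the origin),
#' the Table-of-eight zone label, and the strategic intensity coefficient
#' `rho = U / (U + V)` with positive intensity `U = O' * S'` and negative
#' intensity `V = T' * W'`.
#'
#' The azimuth is computed with the two-argument arctangent so that all
#' four quadrants are distinguished; it is reported both signed in
#' (-180, 180] and normalised to [0, 360), the form the zone partition is
#' defined on.
#'
#' @param totals Numeric quadruple (S', W', O', T') — named or in this
#'   order — with S', O' >= 0 and W', T' <= 0.
#' @param maintain_band Passed to [intensity_interpretation()].
#' @return An object of class `swot_strategy`: list with `totals`,
#'   `vertices` (4 x 2 matrix), `centroid` `c(x, y)`, `theta_deg` (signed),
#'   `theta_deg_normalized` in [0, 360), `quadrant` (1-4), `zone` (list
#'   `type`, `area`, `quadrant`, `label`), `u`, `v`, `rho` and `guidance`.
#' @examples
#' s <- build_strategy(c(S = 4.8007, W = -3.9577, O = 4.6231, T = -4.8215))
#' round(s$theta_deg, 3)  # -13.244
#' round(s$rho, 4)        # 0.5377
#' @export
build_strategy <- function(totals, maintain_band = c(0.45, 0.55)) {
  if (length(totals) != 4) {
    stop_swot("totals", "expected four group totals (S', W', O', T')")
  }
  if (!is.null(names(totals)) && setequal(names(totals),
                                          c("S", "W", "O", "T"))) {
    totals <- totals[c("S", "W", "O", "T")]
  }
  sp <- totals[[1]]; wp <- totals[[2]]; op <- totals[[3]]; tp <- totals[[4]]
  if (sp < 0 || op < 0 || wp > 0 || tp > 0) {
    stop_swot("totals",
              "need S', O' >= 0 and W', T' <= 0 (signed totals)")
  }
  if (sp == 0 && wp == 0 && op == 0 && tp == 0) {
    stop_swot("degenerate", "all four totals are zero: direction undefined")
  }
  vertices <- rbind(S = c(sp, 0), O = c(0, op), W = c(wp, 0), T = c(0, tp))
  colnames(vertices) <- c("x", "y")
  centroid <- colMeans(vertices)  # = ((S' + W')/4, (O' + T')/4)
  if (all(centroid == 0)) {
    stop_swot("degenerate",
              "centroid at the origin: strategic direction undefined")
  }
  theta <- atan2(centroid[["y"]], centroid[["x"]]) * 180 / pi
  theta_norm <- theta %% 360
  zone <- classify_zone(theta_norm * pi / 180)
  u <- op * sp
  v <- tp * wp
  rho <- u / (u + v)
  structure(list(totals = c(S = sp, W = wp, O = op, T = tp),
                 vertices = vertices, centroid = centroid,
                 theta_deg = theta, theta_deg_normalized = theta_norm,
                 quadrant = zone$quadrant, zone = zone, u = u, v = v,
                 rho = rho,
                 guidance = intensity_interpretation(rho, maintain_band)),
            class = "swot_strategy")
}

# quadrant areas and half-quadrant types, anticlockwise from the +x axis
zone_table <- function() {
  data.frame(
    lo = pi / 4 * (0:7),
    hi = pi / 4 * (1:8),
    quadrant = rep(1:4, each = 2),
    area = rep(c("pioneering strategic area", "ambitious strategic area",
                 "conservative strategic area", "resistant strategic area"),
               each = 2),
    type = c("strength type", "opportunity type",
             "aggressive type", "adjustment type",
             "retreating type", "avoidance type",
             "adjustment type", "aggressive type"),
    stringsAsFactors = FALSE)
}

#' Map a normalised azimuth to its strategy zone
#'
#' Total partition of [0, 2pi) into eight half-quadrant zones, two per
#' quadrant area.  Intervals are half-open `[a, b)` with one exception
#' honoured from the published partition: the opportunity-type zone is
#' closed at pi/2, so an azimuth of exactly 90 degrees is opportunity
#' type, not aggressive type.  Angles outside [0, 2pi) are wrapped.
#'
#' @param theta_rad Azimuth in radians.
#' @return List with `type`, `area`, `quadrant` and the combined `label`.
#' @examples
#' classify_zone(346.76 * pi / 180)$label
#' @export
classify_zone <- function(theta_rad) {
  if (!is.finite(theta_rad)) {
    stop_swot("degenerate", "azimuth must be finite")
  }
  th <- theta_rad %% (2 * pi)
  zt <- zone_table()
  idx <- if (th == pi / 2) 2L else which(th >= zt$lo & th < zt$hi)[1]
  if (is.na(idx)) idx <- 8L  # th just below 2*pi after %% rounding
  list(type = zt$type[idx], area = zt$area[idx], quadrant = zt$quadrant[idx],
       label = paste(zt$area[idx], zt$type[idx], sep = " / "))
}

#' Interpret the strategic intensity coefficient
#'
#' `rho` near 0.5 means the positive (opportunity x strength) and negative
#' (threat x weakness) intensities balance and the current pace of
#' development should be maintained; low `rho` calls for a more
#' conservative, high `rho` for a more aggressive intensity.
#'
#' @param rho Strategic intensity coefficient in [0, 1].
#' @param maintain_band Closed interval of `rho` values read as "maintain",
#'   default `c(0.45, 0.55)`.
#' @return One of `"conservative"`, `"maintain"`, `"aggressive"`.
#' @export
intensity_interpretation <- function(rho, maintain_band = c(0.45, 0.55)) {
  if (is.na(rho) || rho < 0 || rho > 1) {
    stop_swot("rho", "rho must lie in [0, 1]")
  }
  if (rho < maintain_band[1]) "conservative"
  else if (rho > maintain_band[2]) "aggressive"
  else "maintain"
}

#' @export
print.swot_strategy <- function(x, digits = 4, ...) {
  cat("SWOT strategy quadrilateral\n")
  cat(sprintf("  totals: S' = %.*f, W' = %.*f, O' = %.*f, T' = %.*f\n",
              digits, x$totals[["S"]], digits, x$totals[["W"]],
              digits, x$totals[["O"]], digits, x$totals[["T"]]))
  cat(sprintf("  centroid P = (%.5f, %.5f)\n",
              x$centroid[["x"]], x$centroid[["y"]]))
  cat(sprintf("  azimuth theta = %.3f deg (%.3f deg normalised), quadrant %d\n",
              x$theta_deg, x$theta_deg_normalized, x$quadrant))
  cat(sprintf("  zone: %s\n", x$zone$label))
  cat(sprintf("  U = %.*f, V = %.*f, rho = %.5f -> %s\n",
              digits, x$u, digits, x$v, x$rho, x$guidance))
  invisible(x)
}

#' Serialize a strategy result to JSON
#'
#' @param x A `swot_strategy`.
#' @param ... Passed to [jsonlite::toJSON()].
#' @return A JSON string at full precision.
#' @export
strategy_json <- function(x, ...) {
  stopifnot(inherits(x, "swot_strategy"))
  jsonlite::toJSON(list(
    totals = as.list(x$totals),
    vertices = unname(apply(x$vertices, 1, as.list, simplify = FALSE)),
    centroid = as.list(x$centroid),
    theta_deg = x$theta_deg,
    theta_deg_normalized = x$theta_deg_normalized,
    quadrant = x$quadrant, zone = x$zone,
    u = x$u, v = x$v, rho = x$rho, guidance = x$guidance),
    auto_unbox = TRUE, digits = NA, ...)
}

#' Plot the strategy quadrilateral
#'
#' Draws the quadrilateral, the axes, the centroid and the azimuth ray
#' from the origin through the centroid.
#'
#' @param x A `swot_strategy`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.swot_strategy <- function(x, ...) {
  v <- x$vertices[c("S", "O", "W", "T"), ]  # anticlockwise polygon order
  lim <- max(abs(v)) * 1.1
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "S' / W'", ylab = "O' / T'", asp = 1, ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::polygon(v[, "x"], v[, "y"], border = "steelblue", lwd = 2)
  graphics::points(x$centroid[["x"]], x$centroid[["y"]], pch = 19,
                   col = "firebrick")
  r <- lim * c(0, 1)
  th <- x$theta_deg_normalized * pi / 180
  graphics::lines(r * cos(th), r * sin(th), lty = 2, col = "firebrick")
  graphics::text(x$centroid[["x"]], x$centroid[["y"]],
                 labels = sprintf("P (%.3f, %.3f)", x$centroid[["x"]],
                                  x$centroid[["y"]]),
                 pos = 4, cex = 0.8)
  invisible(x)
}
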