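# Synthetic expert panels with controlled judgment noise, for testing the
# pipeline end to end and for Monte-Carlo sensitivity analysis.

#' Specify a synthetic expert panel
#'
#' A panel spec fixes, per SWOT group, the latent "truth" the simulated
#' experts perceive — a positive weight vector and a signed intensity
#' vector — together with the panel size, the judgment noise level and
#' whether judgments are snapped to the Saaty grid.  Judgment noise is
#' multiplicative log-normal: each latent ratio `w_i / w_j` is multiplied
#' by `exp(eps)`, `eps ~ N(0, sigma^2)`, the natural perturbation for
#' ratio-scale scores.  With `sigma = 0` and snapping off the generated
#' matrices are exactly consistent and the synthetic pipeline reproduces
#' the analytic one.
#'
#' @param weights Named list (by group letter) of positive latent weight
#'   vectors; each is normalised to sum to 1.
#' @param intensities Named list (same groups) of latent signed intensity
#'   vectors obeying the S/O positive, W/T negative convention.
#' @param n_experts Number of simulated experts, default 10.
#' @param sigma Judgment noise standard deviation on the log scale,
#'   default 0.
#' @param snap Snap each noisy judgment to the nearest Saaty grid value
#'   (nearest in log space; a midpoint tie snaps toward 1), default
#'   `FALSE`.
#' @param intensity_jitter Maximum size of the integer jitter applied to
#'   each expert's intensity scores (uniform on -j..j, clamped to
#'   magnitude 1..9, sign preserved), default 0.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(weights, intensities, n_experts = 10, sigma = 0,
                       snap = FALSE, intensity_jitter = 0) {
  if (sigma < 0) stop_swot("spec", "sigma must be >= 0")
  if (!setequal(names(weights), names(intensities))) {
    stop_swot("spec", "weights and intensities must cover the same groups")
  }
  for (g in names(weights)) {
    w <- weights[[g]]
    if (any(w <= 0)) {
      stop_swot("spec", sprintf("group '%s': latent weights must be > 0", g))
    }
    if (length(w) < 2 || length(w) > 9) {
      stop_swot("spec", sprintf("group '%s': need 2..9 factors", g))
    }
    if (length(intensities[[g]]) != length(w)) {
      stop_swot("spec", sprintf(
        "group '%s': intensity and weight lengths differ", g))
    }
    weights[[g]] <- w / sum(w)
    if (g %in% c("S", "W", "O", "T")) {
      check_intensity_signs(intensities[[g]], rep(g, length(w)),
                            paste0(g, seq_along(w)))
    }
  }
  structure(list(weights = weights, intensities = intensities,
                 n_experts = n_experts, sigma = sigma, snap = snap,
                 intensity_jitter = intensity_jitter),
            class = "panel_spec")
}

#' Read a panel spec from YAML
#'
#' Expects top-level keys `groups` (a map from group letter to `weights`
#' and `intensities` lists) and optional `n_experts`, `sigma`, `snap`,
#' `intensity_jitter`.
#'
#' @param path YAML file path.
#' @return A `panel_spec`.
#' @export
read_panel_spec <- function(path) {
  y <- yaml::read_yaml(path)
  panel_spec(
    weights = lapply(y$groups, function(g) as.numeric(g$weights)),
    intensities = lapply(y$groups, function(g) as.numeric(g$intensities)),
    n_experts = y$n_experts %||% 10,
    sigma = y$sigma %||% 0,
    snap = isTRUE(y$snap),
    intensity_jitter = y$intensity_jitter %||% 0)
}

#' Generate a perfectly consistent comparison matrix
#'
#' Builds the matrix of latent ratios `a_ij = w_i / w_j`, which is exactly
#' reciprocal and has CI = 0; [compute_weights()] recovers `w` from it
#' exactly.
#'
#' @param weights Positive latent weight vector (normalised internally).
#' @param group_id Group label.
#' @return A `comparison_matrix`.
#' @export
generate_consistent_matrix <- function(weights, group_id = "G") {
  if (any(weights <= 0)) {
    stop_swot("spec", "latent weights must be strictly positive")
  }
  w <- weights / sum(weights)
  ids <- names(w) %||% paste0(group_id, seq_along(w))
  comparison_matrix(outer(w, w, "/"), factor_ids = ids, group_id = group_id)
}

#' Perturb a comparison matrix with multiplicative judgment noise
#'
#' Multiplies every upper-triangle entry by `exp(eps)` with independent
#' `eps ~ N(0, sigma^2)`, optionally snaps to the nearest Saaty grid value
#' in log space (ties snap toward the less extreme judgment, i.e. toward
#' 1), and mirrors reciprocals into the lower triangle.  Deterministic for
#' a fixed seed.
#'
#' @param m A `comparison_matrix`.
#' @param sigma Noise standard deviation on the log scale, >= 0.
#' @param snap Snap to the Saaty grid.
#' @param seed Optional integer seed (local to this call).
#' @return A perturbed `comparison_matrix`.
#' @export
perturb_matrix <- function(m, sigma, snap = FALSE, seed = NULL) {
  if (sigma < 0) stop_swot("spec", "sigma must be >= 0")
  stopifnot(inherits(m, "comparison_matrix"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  n <- nrow(m)
  out <- unclass(m)
  up <- upper.tri(out)
  out[up] <- out[up] * exp(stats::rnorm(sum(up), 0, sigma))
  if (snap) out[up] <- snap_to_saaty(out[up])
  out[lower.tri(out)] <- 1 / t(out)[lower.tri(out)]
  comparison_matrix(out, factor_ids = attr(m, "factor_ids"),
                    group_id = attr(m, "group_id"), strict_saaty = snap)
}

# nearest grid value in log space; exact midpoint ties -> toward 1
snap_to_saaty <- function(x) {
  grid <- saaty_scale()
  lg <- log(grid)
  vapply(x, function(xi) {
    d <- abs(log(xi) - lg)
    cand <- grid[d - min(d) < 1e-12]  # near-ties count as ties
    cand[which.min(abs(log(cand)))]
  }, 0)
}

#' Generate a synthetic expert panel
#'
#' Simulates the final Delphi round: each expert's judgment matrix is the
#' latent consistent matrix of the spec perturbed by that expert's own
#' log-normal noise (optionally grid-snapped), and each expert's intensity
#' scores are the latent intensities with optional integer jitter, clamped
#' to magnitude 1..9 with sign preserved.
#'
#' @param spec A `panel_spec`.
#' @param seed Optional integer seed (local to this call).
#' @return An `expert_panel`.
#' @export
generate_panel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  judgments <- lapply(names(spec$weights), function(g) {
    base <- generate_consistent_matrix(spec$weights[[g]], group_id = g)
    lapply(seq_len(spec$n_experts), function(e) {
      perturb_matrix(base, spec$sigma, snap = spec$snap)
    })
  })
  names(judgments) <- names(spec$weights)
  intensities <- lapply(names(spec$intensities), function(g) {
    lat <- spec$intensities[[g]]
    t(vapply(seq_len(spec$n_experts), function(e) {
      if (spec$intensity_jitter > 0) {
        j <- sample(-spec$intensity_jitter:spec$intensity_jitter,
                    length(lat), replace = TRUE)
        mag <- pmin(pmax(abs(lat) + j, 1), 9)
        sign(lat) * mag
      } else {
        lat
      }
    }, numeric(length(lat))))
  })
  names(intensities) <- names(spec$intensities)
  expert_panel(judgments, intensities, strict_saaty = spec$snap)
}

#' Monte-Carlo distribution of the strategy under judgment noise
#'
#' Repeats the full pipeline — perturb the latent consistent matrices,
#' aggregate (when the spec has more than one expert), test consistency,
#' compute strengths, build the strategy — and summarises the azimuth,
#' the intensity coefficient and the zone frequencies across replicates.
#' Replicates in which any group fails the CR test are rejected and
#' counted, mirroring how an inconsistent real panel would be sent back
#' for another Delphi round.
#'
#' @param spec A `panel_spec` with groups S, W, O, T.
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Integer seed; each replicate uses `seed + r`.
#' @param cr_threshold CR acceptance threshold, default 0.1.
#' @return List with `n_accepted`, `n_rejected`, `theta` (vector),
#'   `rho` (vector), `theta_summary`, `rho_summary` (mean and quartiles),
#'   `zone_counts` (table) and `replicates`.
#' @export
simulate_strategy_distribution <- function(spec, replicates = 200,
                                           seed = 1, cr_threshold = 0.1) {
  stopifnot(inherits(spec, "panel_spec"))
  if (!setequal(names(spec$weights), c("S", "W", "O", "T"))) {
    stop_swot("spec", "simulation needs all four groups S, W, O, T")
  }
  theta <- rho <- rep(NA_real_, replicates)
  zones <- character(replicates)
  for (r in seq_len(replicates)) {
    panel <- generate_panel(spec, seed = seed + r)
    mats <- aggregate_judgments(panel)
    ints <- aggregate_intensities(panel)
    res <- lapply(c("S", "W", "O", "T"), function(g) {
      ahp <- consistency(mats[[g]], cr_threshold = cr_threshold)
      if (!ahp$consistent) return(NULL)
      f <- swot_factors(attr(mats[[g]], "factor_ids"),
                        rep(g, ahp$n), ints[[g]])
      factor_strengths(f, ahp)
    })
    if (any(vapply(res, is.null, TRUE))) next  # CR rejection
    st <- build_strategy(assemble_swot(res))
    theta[r] <- st$theta_deg
    rho[r] <- st$rho
    zones[r] <- st$zone$label
  }
  ok <- !is.na(theta)
  if (!any(ok)) {
    stop_swot("all_rejected",
              "every replicate failed the consistency test")
  }
  summ <- function(x) c(mean = mean(x),
                        stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  list(n_accepted = sum(ok), n_rejected = sum(!ok),
       theta = theta[ok], rho = rho[ok],
       theta_summary = summ(theta[ok]), rho_summary = summ(rho[ok]),
       zone_counts = table(zones[ok]), replicates = replicates)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
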