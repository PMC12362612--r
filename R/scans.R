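# Parameter-scan drivers: control gain, production-rate ratio, adaptive
# metric and sequestration-rate sweeps, each built on find_equilibria() so
# per-point results equal the single-point module calls exactly.

new_scan_result <- function(parameter, grid, counts, points, summary) {
  structure(list(parameter = parameter, grid = grid, counts = counts,
                 points = points, summary = summary),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Scan over %s (%d points)\n", x$parameter, length(x$grid)))
  print(x$counts, row.names = FALSE)
  if (length(x$summary)) utils::str(x$summary, give.head = FALSE)
  invisible(x)
}

census_point <- function(spec, grid_n = 60) {
  eq <- find_equilibria(spec, grid_n = grid_n)
  list(eq = eq, stable = stable_states(eq), counts = count_equilibria(eq))
}

scan_counts_df <- function(parameter, grid, censuses) {
  data.frame(value = grid,
             n_eq = vapply(censuses, function(cs)
               length(cs$eq$equilibria), integer(1)),
             n_stable = vapply(censuses, function(cs)
               unname(cs$counts["stable"]), integer(1)))
}

scan_points_df <- function(grid, censuses, baseline_stable = NULL) {
  rows <- lapply(seq_along(grid), function(i) {
    S <- censuses[[i]]$stable
    if (!nrow(S)) return(NULL)
    df <- data.frame(value = grid[i], y1 = S[, "Y1"], y2 = S[, "Y2"])
    if (!is.null(baseline_stable) && nrow(baseline_stable)) {
      ref_idx <- match_equilibria(baseline_stable, S)
      df$dominant_alteration <- vapply(seq_len(nrow(S)), function(k) {
        ref <- baseline_stable[ref_idx[k], ]
        dom <- which.max(ref)
        alteration_percent(ref, S[k, ], dom)
      }, numeric(1))
      df$point_alteration <- vapply(seq_len(nrow(S)), function(k)
        point_shift_percent(baseline_stable[ref_idx[k], ], S[k, ]),
        numeric(1))
    }
    df
  })
  do.call(rbind, rows)
}

# controlled toggle with a gain/parameter override; double configs tie
# beta_prime = beta unless beta_prime was set explicitly
controlled_toggle_at <- function(params, config, beta = NULL, gamma = NULL,
                                 xi = NULL) {
  p <- params
  if (!is.null(beta)) {
    p$beta <- beta
    if (config$duplicated == "double" && is.null(params$beta_prime))
      p$beta_prime <- beta
  }
  if (!is.null(gamma)) p$gamma <- gamma
  if (!is.null(xi)) p$xi <- xi
  make_controlled_toggle(p, config)
}

#' Control-gain sweep of the controlled toggle switch
#'
#' For each gain in \code{betas}, locates the equilibria of the controlled
#' toggle and reports counts, stable values (with alterations vs the
#' uncontrolled toggle) and the monostability threshold: the smallest grid
#' gain at which exactly one stable equilibrium remains.
#'
#' @param params a [kinetic_params()] object.
#' @param config a [controller_config()] for the toggle.
#' @param betas increasing gain grid (/h), normally including 0.
#' @param grid_n lattice resolution for [find_equilibria()].
#' @return A \code{"scan_result"}; \code{summary$threshold} is NA when no
#'   grid gain is monostable.
#' @export
scan_gain <- function(params, config, betas, grid_n = 60) {
  censuses <- lapply(betas, function(b)
    census_point(controlled_toggle_at(params, config, beta = b), grid_n))
  base <- census_point(make_toggle(params), grid_n)
  counts <- scan_counts_df("beta", betas, censuses)
  mono <- counts$value[counts$n_stable == 1]
  new_scan_result("beta", betas, counts,
                  scan_points_df(betas, censuses, base$stable),
                  list(threshold = if (length(mono)) min(mono) else NA_real_))
}

#' Production-ratio robustness sweep of the (controlled) toggle switch
#'
#' Sweeps the ratio alpha2/alpha1 by changing one of the two production
#' rates while the other stays at its nominal value, counts stable
#' equilibria per point, and reports the bistable range: the maximal
#' contiguous grid interval with two stable equilibria that contains
#' ratio 1.
#'
#' @param params a [kinetic_params()] object; the fixed rate is taken from
#'   it (\code{alpha1} when varying alpha2, \code{alpha2} when varying
#'   alpha1).
#' @param vary which rate realises the ratio change: "alpha2" or "alpha1".
#' @param ratios positive ratio grid (the reporting resolution is 0.1).
#' @param config optional [controller_config()]; when supplied the
#'   controlled toggle is scanned (with \code{params$beta}), otherwise the
#'   isolated toggle.
#' @param grid_n lattice resolution for [find_equilibria()].
#' @return A \code{"scan_result"}; \code{summary$bistable_range} holds the
#'   grid endpoints (NA when ratio 1 is not bistable).
#' @export
scan_ratio <- function(params, vary = c("alpha2", "alpha1"), ratios,
                       config = NULL, grid_n = 60) {
  vary <- match.arg(vary)
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  make_at <- function(r) {
    p <- params
    if (vary == "alpha2") p$alpha2 <- r * params$alpha1
    else p$alpha1 <- params$alpha2 / r
    if (is.null(config)) make_toggle(p) else make_controlled_toggle(p, config)
  }
  censuses <- lapply(ratios, function(r) census_point(make_at(r), grid_n))
  counts <- scan_counts_df("ratio", ratios, censuses)
  bi <- counts$n_stable == 2
  rng <- c(NA_real_, NA_real_)
  i1 <- which.min(abs(ratios - 1))
  if (bi[i1]) {
    lo <- i1; while (lo > 1 && bi[lo - 1]) lo <- lo - 1
    hi <- i1; while (hi < length(bi) && bi[hi + 1]) hi <- hi + 1
    rng <- c(ratios[lo], ratios[hi])
  }
  base <- lapply(ratios, function(r) {
    p <- params
    if (vary == "alpha2") p$alpha2 <- r * params$alpha1
    else p$alpha1 <- params$alpha2 / r
    census_point(make_toggle(p), grid_n)$stable
  })
  points <- do.call(rbind, lapply(seq_along(ratios), function(i)
    scan_points_df(ratios[i], censuses[i], base[[i]])))
  new_scan_result(paste0("ratio (vary ", vary, ")"), ratios, counts, points,
                  list(bistable_range = rng))
}

#' Adaptive-metric sweep of the controlled toggle switch
#'
#' Varies the metric r = xi*delta/(k*theta) through xi alone (delta also
#' enters the endogenous network, so changing it would not isolate the
#' controller mismatch). For each r the controlled toggle's equilibria are
#' located and compared to the isolated toggle at the same endogenous
#' parameters: per matched stable equilibrium both the dominant-species
#' percent alteration and the relative Euclidean shift of the whole
#' equilibrium point are reported.
#'
#' @param params a [kinetic_params()] object.
#' @param config a [controller_config()].
#' @param r_values metric grid (e.g. seq(0.9, 1.1, 0.01)).
#' @param beta,gamma control gain and sequestration rate for the sweep.
#' @param grid_n lattice resolution for [find_equilibria()].
#' @return A \code{"scan_result"}; summary holds
#'   \code{max_dominant_alteration}, \code{max_point_alteration} and
#'   \code{bistable_everywhere}.
#' @export
scan_metric <- function(params, config, r_values, beta = 1, gamma = 100,
                        grid_n = 60) {
  xi_of_r <- function(r) r * params$k * params$theta / params$delta
  censuses <- lapply(r_values, function(r)
    census_point(controlled_toggle_at(params, config, beta = beta,
                                      gamma = gamma, xi = xi_of_r(r)),
                 grid_n))
  base <- census_point(make_toggle(params), grid_n)
  counts <- scan_counts_df("r", r_values, censuses)
  points <- scan_points_df(r_values, censuses, base$stable)
  new_scan_result("r", r_values, counts, points, list(
    max_dominant_alteration = if (is.null(points)) NA_real_
      else max(points$dominant_alteration),
    max_point_alteration = if (is.null(points)) NA_real_
      else max(points$point_alteration),
    bistable_everywhere = all(counts$n_stable == 2)))
}

#' Sequestration-rate sweep of the controlled toggle switch
#'
#' For each gamma, locates the controlled toggle's equilibria and their
#' alterations versus the uncontrolled toggle; optionally runs a stochastic
#' ensemble per gamma and reports the Y1-high fate fraction.
#'
#' @param params a [kinetic_params()] object.
#' @param config a [controller_config()].
#' @param gammas positive sequestration-rate grid (/uM/h).
#' @param beta control gain for the sweep.
#' @param fate_n ensemble size per gamma (0 disables the fate assay).
#' @param t_end,omega,seed ensemble protocol (horizon in h, system size,
#'   master seed).
#' @param grid_n lattice resolution for [find_equilibria()].
#' @return A \code{"scan_result"}; summary holds \code{y1_high_fraction}
#'   per gamma when the fate assay ran.
#' @export
scan_sequestration <- function(params, config, gammas, beta = 1,
                               fate_n = 0, t_end = 200, omega = 1, seed = 1,
                               grid_n = 60) {
  if (any(gammas <= 0)) stop("gammas must be positive", call. = FALSE)
  censuses <- lapply(gammas, function(g)
    census_point(controlled_toggle_at(params, config, beta = beta,
                                      gamma = g), grid_n))
  base <- census_point(make_toggle(params), grid_n)
  counts <- scan_counts_df("gamma", gammas, censuses)
  points <- scan_points_df(gammas, censuses, base$stable)
  summary <- list()
  if (fate_n > 0) {
    fr <- vapply(seq_along(gammas), function(i) {
      spec <- controlled_toggle_at(params, config, beta = beta,
                                   gamma = gammas[i])
      finals <- run_ensemble(spec, rep(0, length(spec$species)), fate_n,
                             t_end, mode = "ssa", omega = omega,
                             seed = seed + i - 1L)
      att <- censuses[[i]]$stable
      fd <- fate_distribution(finals, att, species = "Y1")
      fd$fractions[match("Y1-high", fd$fraction_labels)]
    }, numeric(1))
    summary$y1_high_fraction <- stats::setNames(fr, paste0("gamma=", gammas))
  }
  new_scan_result("gamma", gammas, counts, points, summary)
}
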