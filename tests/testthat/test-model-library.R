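p_nom <- kinetic_params()

test_that("toggle right-hand side matches the mutual-repression ODEs", {
  tg <- make_toggle(p_nom)
  # at the origin both Hill terms equal alpha
  expect_equal(rhs(tg, c(0, 0)), c(2.2, 2.2))
  # near the asymmetric fixed point the derivative is tiny
  fp <- toggle_roots_1d(2.2, 2.2)
  hi <- fp[which.max(fp[, "y1"]), ]
  expect_lt(max(abs(rhs(tg, hi))), 1e-8)
  expect_lt(max(abs(rhs(tg, c(2.185, 0.192)))), 1e-2)
  # swap symmetry of the symmetric toggle
  s <- c(0.7, 1.9)
  expect_equal(rhs(tg, s), rev(rhs(tg, rev(s))))
})

test_that("state validation rejects malformed input", {
  tg <- make_toggle(p_nom)
  expect_error(rhs(tg, c(-0.1, 1)), "negative")
  expect_error(rhs(tg, c(NaN, 1)), "finite")
  expect_error(rhs(tg, c(1, 1, 1)), "species")
})

test_that("isolated controller reproduces its steady-state balances", {
  ic0 <- make_isolated_controller(p_nom, function(t) 0 * t)
  expect_equal(rhs(ic0, c(0, 0, 0)), c(0, 0, 0))
  # constant unit input: x_bar = theta/delta = 1, u1_bar from the
  # sequestration quadratic
  ic1 <- make_isolated_controller(p_nom, function(t) rep(1, length(t)))
  tr <- simulate_ode(ic1, c(0, 0, 0), 40, n_out = 200)
  fin <- tr$states[nrow(tr$states), ]
  names(fin) <- ic1$species
  expect_close(fin["X"], 1, 1e-6)
  expect_close(fin["U1"], (-1 + sqrt(401)) / 200, 1e-5)
  expect_error(make_isolated_controller(p_nom, function(t) -1), "nonnegative")
})

test_that("controlled toggle reduces exactly to the toggle at beta = 0", {
  p0 <- kinetic_params(beta = 0, alpha1 = 2.0, alpha2 = 2.6)
  ct <- make_controlled_toggle(p0, negative_feedback_config())
  tg <- make_toggle(p0)
  for (y in list(c(0, 0), c(1.3, 0.4), c(2.2, 2.2))) {
    full <- rhs(ct, c(y, 0.3, 0.2, 0.1))
    expect_equal(full[1:2], rhs(tg, y))
  }
})

test_that("controller actuation adds beta * u1 with u1 from the QSS", {
  # with the toggle frozen at its Y1-high state, p = 1/(1 + 2.185^3) and the
  # sequestration quadratic gives u1 = 0.0250 exactly
  ct <- make_controlled_toggle(p_nom, negative_feedback_config())
  tg <- make_toggle(p_nom)
  y <- c(2.185, 0.192)
  p_sense <- 1 / (1 + y[1]^3)
  qs <- controller_qss(p_sense, p_nom)
  dy_ct <- rhs(ct, c(y, qs$x, qs$u1, qs$u2))
  dy_tg <- rhs(tg, y)
  expect_close(dy_ct[1] - dy_tg[1], p_nom$beta * 0.0250, 1e-3)
  expect_equal(dy_ct[2], dy_tg[2])
})

test_that("U2-input wiring differs from U1-input in exactly one term", {
  ct1 <- make_controlled_toggle(p_nom, negative_feedback_config("U1"))
  ct2 <- make_controlled_toggle(p_nom, negative_feedback_config("U2"))
  key <- function(tm) paste(tm$type, tm$target %||% "", tm$source %||% "",
                            sep = "|")
  `%||%` <- function(a, b) if (is.null(a)) b else a
  k1 <- vapply(ct1$terms, key, character(1))
  k2 <- vapply(ct2$terms, key, character(1))
  expect_length(setdiff(k1, k2), 1L)
  expect_length(setdiff(k2, k1), 1L)
  expect_match(setdiff(k1, k2), "additive_control\\|Y1\\|U1")
  expect_match(setdiff(k2, k1), "additive_control\\|Y1\\|U2")
})

test_that("double controller requires beta_prime and mirrors the wiring", {
  expect_error(
    make_controlled_toggle(p_nom, positive_feedback_config(duplicated = "double")),
    "beta_prime")
  pd <- kinetic_params(beta_prime = 1)
  ctd <- make_controlled_toggle(pd, positive_feedback_config(duplicated = "double"))
  expect_length(ctd$species, 8L)
  expect_length(ctd$controllers, 2L)
  expect_identical(ctd$controllers[[2]]$target_species, "Y2")
  expect_identical(ctd$controllers[[2]]$sense_species, "Y1")
})

test_that("self-activation loop vanishes at alpha3 = 0 and balances on the diagonal", {
  sa0 <- make_toggle_selfactivation(kinetic_params(alpha3 = 0))
  tg <- make_toggle(p_nom)
  for (y in list(c(0.5, 1.5), c(2, 2)))
    expect_equal(rhs(sa0, y), rhs(tg, y))
  # on the diagonal the repressing and activating Hill terms sum to 1, so
  # ydot = alpha - delta*y vanishes at y = alpha/delta
  tri <- make_toggle_selfactivation(tristable_params(), double = TRUE)
  expect_equal(rhs(tri, c(1.2, 1.2)), c(0, 0))
})

test_that("controlled mutual activation matches its saturated-degradation form", {
  ma <- make_controlled_mutual_activation(p_nom)
  expect_equal(rhs(ma, rep(0, 5)), rep(0, 5))
  # uncontrolled symmetric high state: largest root of y^3 - 2.2 y^2 + 1
  r <- sort(Re(polyroot(c(1, 0, -2.2, 1))))
  y_hi <- r[length(r)]
  p0 <- kinetic_params(beta = 0)
  ma0 <- make_controlled_mutual_activation(p0)
  st <- fatecontrol:::lift_state(ma0, y_hi, y_hi)
  expect_lt(max(abs(rhs(ma0, st))), 1e-9)
  expect_error(
    make_controlled_mutual_activation(p_nom,
      controller_config("Y1", "activating", "U1",
                        "additive_activation", "Y1")),
    "additive")
})

test_that("tristable factory composes both controllers and reduces at zero gain", {
  pt <- tristable_params(beta = 0, beta_prime = 0)
  cfgs <- tristable_inhibition_configs()
  ts <- make_controlled_tristable(pt, cfgs$y1, cfgs$y2)
  expect_length(ts$species, 8L)
  base <- make_toggle_selfactivation(pt, double = TRUE)
  for (y in list(c(0, 0), c(1.2, 1.2), c(0.3, 2)))
    expect_equal(rhs(ts, c(y, rep(0.2, 6)))[1:2], rhs(base, y))
  expect_error(make_controlled_tristable(pt, cfgs$y1), "config_y2")
  # mixed design: additive term on Y1, saturated degradation on Y2
  mix <- tristable_mixed_configs()
  tsm <- make_controlled_tristable(tristable_params(), mix$y1, mix$y2)
  types <- vapply(tsm$terms, function(tm)
    if (!is.null(tm$target) && tm$target %in% c("Y1", "Y2") &&
        tm$type %in% c("additive_control", "mm_degradation_control"))
      paste(tm$type, tm$target) else "", character(1))
  expect_true("additive_control Y1" %in% types)
  expect_true("mm_degradation_control Y2" %in% types)
})

test_that("reaction lists mirror the chemical reaction listings", {
  rx_tg <- reactions(make_toggle(p_nom))
  expect_length(rx_tg, 4L)  # 2 production, 2 decay
  rx_ct <- reactions(make_controlled_toggle(p_nom, negative_feedback_config()))
  # 6 production (incl. catalytic U1 output and the control action),
  # 5 decay, 1 sequestration
  expect_length(rx_ct, 12L)
  labs <- vapply(rx_ct, `[[`, character(1), "label")
  expect_length(grep("^[A-Za-z0-9]+ -> 0$", labs), 5L)
  expect_length(grep("U1 \\+ U2 -> 0", labs), 1L)
  # sequestration removes one of each partner
  seq_rx <- rx_ct[[grep("U1 \\+ U2", labs)]]
  expect_equal(unname(seq_rx$stoich[c("U1", "U2")]), c(-1L, -1L))
  # input-driven terms have no exact reaction mapping
  ic <- make_isolated_controller(p_nom, function(t) rep(1, length(t)))
  expect_error(reactions(ic), "no stochastic reaction mapping")
})

test_that("reaction drift equals the ODE right-hand side everywhere", {
  specs <- list(
    make_toggle(p_nom),
    make_controlled_toggle(p_nom, negative_feedback_config()),
    make_controlled_toggle(p_nom, positive_feedback_config("U2")),
    make_controlled_mutual_activation(p_nom),
    make_controlled_tristable(tristable_params(),
                              tristable_inhibition_configs()$y1,
                              tristable_inhibition_configs()$y2))
  set.seed(99)
  for (spec in specs) {
    rx <- reactions(spec)
    for (i in 1:20) {
      st <- runif(length(spec$species), 0, 3)
      expect_lt(max(abs(fatecontrol:::reaction_drift(rx, st) -
                          rhs(spec, st))), 1e-12)
    }
  }
})

test_that("the nonnegative orthant is forward-invariant", {
  set.seed(4)
  tg <- make_toggle(p_nom)
  for (i in 1:100) {
    tr <- simulate_ode(tg, runif(2, 0, 5), 5, n_out = 50)
    expect_gte(min(tr$states), 0)
  }
  ct <- make_controlled_toggle(p_nom, negative_feedback_config())
  for (i in 1:20) {
    tr <- simulate_ode(ct, runif(5, 0, 3), 5, n_out = 50)
    expect_gte(min(tr$states), 0)
  }
})
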