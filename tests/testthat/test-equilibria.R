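p_nom <- kinetic_params()

test_that("controller QSS solves the sequestration quadratic", {
  expect_equal(controller_qss(0, p_nom), list(u1 = 0, u2 = 0, x = 0))
  qs <- controller_qss(1, p_nom)
  expect_equal(qs$u1, (-1 + sqrt(401)) / 200, tolerance = 1e-12)
  expect_equal(qs$u2, qs$u1)  # r = 1: d = 0
  expect_equal(qs$x, 1)
  # r != 1 shifts u1 - u2 by d = p (k*theta - xi*delta) / delta^2
  p9 <- kinetic_params(xi = 0.9)
  qs9 <- controller_qss(0.5, p9)
  expect_equal(qs9$u1 - qs9$u2, 0.5 * 0.1, tolerance = 1e-12)
  # residual check against the steady-state equations themselves
  res_u1 <- p9$k * qs9$x - p9$delta * qs9$u1 - p9$gamma * qs9$u1 * qs9$u2
  res_u2 <- p9$xi * 0.5 - p9$delta * qs9$u2 - p9$gamma * qs9$u1 * qs9$u2
  expect_lt(abs(res_u1), 1e-12)
  expect_lt(abs(res_u2), 1e-12)
  # fast-sequestration scaling at r = 1: u1 * sqrt(gamma) -> sqrt(k theta p / delta)
  sc <- vapply(c(1e4, 1e6, 1e8), function(g)
    controller_qss(1, kinetic_params(gamma = g))$u1 * sqrt(g), numeric(1))
  expect_close(sc[3], 1, 1e-3)
  expect_true(all(diff(abs(sc - 1)) < 0))
  # gamma = 0 linear fallback
  qs0 <- controller_qss(2, kinetic_params(gamma = 0))
  expect_equal(qs0$u1, 2)
  expect_equal(qs0$u2, 2)
  expect_error(controller_qss(-1, p_nom), "nonnegative")
})

test_that("nullclines solve the reduced equations branch by branch", {
  tg <- make_toggle(p_nom)
  nc1 <- nullclines(tg, axis = 1, grid = c(0.5, 1, 2))
  # closed form: y1 = (alpha/delta) / (1 + y2^m)
  for (i in seq_len(nrow(nc1))) {
    expect_close(nc1$y1[i], 2.2 / (1 + nc1$y2[i]^3), 1e-8)
  }
  expect_close(nc1$y1[nc1$y2 == 1], 1.1, 1e-8)
  # the controlled y1-nullcline lies strictly above the uncontrolled one
  # (the QSS controller output is positive wherever the drive is)
  ct <- make_controlled_toggle(p_nom, negative_feedback_config())
  ncc <- nullclines(ct, axis = 1, grid = c(0.5, 1, 2))
  for (y2v in c(0.5, 1, 2)) {
    expect_gt(max(ncc$y1[ncc$y2 == y2v]), max(nc1$y1[nc1$y2 == y2v]))
  }
})

test_that("equilibrium census of the toggle matches the 1-D elimination oracle", {
  eq <- find_equilibria(make_toggle(p_nom))
  oracle <- toggle_roots_1d(2.2, 2.2)
  expect_length(eq$equilibria, nrow(oracle))
  locs <- t(vapply(eq$equilibria, function(e) e$location[1:2], numeric(2)))
  for (i in seq_len(nrow(oracle))) {
    d <- sqrt(rowSums((locs - matrix(oracle[i, ], nrow(locs), 2,
                                     byrow = TRUE))^2))
    expect_lt(min(d), 1e-8)
  }
  expect_equal(unname(count_equilibria(eq)[c("stable", "saddle")]), c(2L, 1L))
  # nullcline intersections agree with the census locations
  stab <- stable_states(eq)
  nc <- nullclines(make_toggle(p_nom), axis = 1,
                   grid = stab[, "Y2"])
  for (i in seq_len(nrow(stab))) {
    cand <- nc$y1[abs(nc$y2 - stab[i, "Y2"]) < 1e-12]
    expect_lt(min(abs(cand - stab[i, "Y1"])), 1e-3)
  }
})

test_that("mutual activation equilibria are the roots of the cubic", {
  p0 <- kinetic_params(beta = 0)
  eq <- find_equilibria(make_controlled_mutual_activation(p0))
  locs <- t(vapply(eq$equilibria, function(e) e$location[1:2], numeric(2)))
  labs <- vapply(eq$equilibria, `[[`, character(1), "label")
  expect_length(labs, 3L)
  # diagonal fixed points: y * (y^3 - 2.2 y^2 + 1) = 0, nonnegative roots
  r <- sort(Re(polyroot(c(1, 0, -2.2, 1))))
  r <- r[r > 0]
  expected <- rbind(c(0, 0), rep(min(r), 2), rep(max(r), 2))
  o <- order(locs[, 1])
  expect_close(locs[o, ], expected, 1e-6)
  expect_identical(labs[o][1], "stable")
  expect_identical(labs[o][3], "stable")
  expect_false(labs[o][2] == "stable")
  expect_close(locs[o, ][3, 1], 1.93, 1e-2)
})

test_that("tristable census: three stable states with two saddles between", {
  eq <- find_equilibria(make_toggle_selfactivation(tristable_params(),
                                                   double = TRUE))
  cnt <- count_equilibria(eq)
  expect_equal(unname(cnt["stable"]), 3L)
  expect_equal(unname(cnt["saddle"] + cnt["unstable"]), 2L)
  stab <- stable_states(eq)
  d <- sqrt(rowSums((stab - 1.2)^2))
  expect_lt(min(d), 1e-9)  # the intermediate state sits exactly at (1.2, 1.2)
})

test_that("stability labels come from the Jacobian spectrum", {
  tg <- make_toggle(p_nom)
  y_sym <- uniroot(function(y) y + y^4 - 2.2, c(0.5, 2), tol = 1e-13)$root
  eq <- classify_stability(tg, c(y_sym, y_sym))
  expect_identical(eq$label, "saddle")
  # analytic 2x2 Jacobian on the diagonal: eigenvalues -delta +/- g with
  # g = alpha m y^(m-1) K^m / (K^m + y^m)^2
  g <- 2.2 * 3 * y_sym^2 / (1 + y_sym^3)^2
  ev <- sort(Re(eq$eigenvalues))
  expect_close(ev, sort(c(-1 - g, -1 + g)), 1e-5)
  expect_close(g, 1.585, 2e-3)
  # a stable point has a fully negative spectrum
  fp <- toggle_roots_1d(2.2, 2.2)
  hi <- fp[which.max(fp[, "y1"]), ]
  expect_identical(classify_stability(tg, unname(hi))$label, "stable")
  # linear decay-only system: eigenvalue exactly -delta
  dec <- model_spec("decay", "Y1", p_nom,
                    list(fatecontrol:::term_linear_decay("Y1", 1)))
  expect_equal(Re(classify_stability(dec, 0)$eigenvalues), -1,
               tolerance = 1e-9)
  expect_error(classify_stability(tg, c(1, 1)), "not a fixed point")
})

test_that("alteration percent behaves as a relative shift", {
  expect_equal(alteration_percent(c(2, 1), c(2, 1), 1), 0)
  expect_equal(alteration_percent(c(2, 1), c(4, 1), 1), 100)
  z <- alteration_percent(c(0, 1), c(0.3, 1), 1)
  expect_equal(as.numeric(z), 0.3)
  expect_true(attr(z, "absolute"))
  expect_equal(alteration_percent(c(2, 1), c(2.2, 1), "Y1",
                                  species_names = c("Y1", "Y2")), 10)
})

test_that("root-finder counts equal the brute-force lattice scan", {
  specs <- list(
    make_toggle(p_nom),
    make_controlled_toggle(p_nom, negative_feedback_config()),
    make_controlled_toggle(p_nom, positive_feedback_config()),
    make_controlled_mutual_activation(kinetic_params(beta = 0)),
    make_toggle_selfactivation(tristable_params(), double = TRUE))
  for (spec in specs) {
    expect_equal(length(find_equilibria(spec)$equilibria),
                 brute_equilibrium_count(spec),
                 label = spec$name)
  }
})

test_that("full controlled dynamics settle onto a computed equilibrium", {
  ct <- make_controlled_toggle(p_nom, negative_feedback_config())
  eq <- find_equilibria(ct)
  tr <- simulate_ode(ct, c(0.1, 0, 0, 0, 0), 500, n_out = 500)
  fin <- tr$states[nrow(tr$states), ]
  d <- vapply(eq$equilibria, function(e)
    sqrt(sum((fin - e$location)^2)), numeric(1))
  expect_lt(min(d), 1e-3)
})

test_that("equilibrium alteration scales like 1/sqrt(gamma) at r = 1", {
  tg_stable <- stable_states(find_equilibria(make_toggle(p_nom)))
  hi_ref <- tg_stable[which.max(tg_stable[, "Y1"]), ]
  gammas <- c(1e2, 1e3, 1e4)
  alts <- vapply(gammas, function(g) {
    ct <- make_controlled_toggle(kinetic_params(gamma = g),
                                 negative_feedback_config())
    S <- stable_states(find_equilibria(ct))
    hi <- S[which.max(S[, "Y1"]), ]
    fatecontrol:::point_shift_percent(hi_ref, hi)
  }, numeric(1))
  slope <- coef(lm(log(alts) ~ log(gammas)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  # and the controller output itself adapts away: u1_bar -> 0 monotonically
  u1s <- vapply(gammas, function(g) {
    ct <- make_controlled_toggle(kinetic_params(gamma = g),
                                 negative_feedback_config())
    eq <- find_equilibria(ct)
    hiY1 <- which.max(vapply(eq$equilibria, function(e) e$location[1],
                             numeric(1)))
    eq$equilibria[[hiY1]]$location[match("U1", ct$species)]
  }, numeric(1))
  expect_true(all(diff(u1s) < 0))
})

test_that("controlled variants keep their multistability with shifted states", {
  # double-inhibition tristable control pulls the intermediate state down
  # from (1.2, 1.2) without destroying tristability
  cfgs <- tristable_inhibition_configs()
  ts <- make_controlled_tristable(tristable_params(beta = 1),
                                  cfgs$y1, cfgs$y2)
  eq <- find_equilibria(ts)
  cnt <- count_equilibria(eq)
  expect_equal(unname(cnt["stable"]), 3L)
  expect_equal(unname(cnt["saddle"] + cnt["unstable"]), 2L)
  mid <- stable_states(eq)
  mid <- mid[abs(mid[, "Y1"] - mid[, "Y2"]) < 1e-6, , drop = FALSE]
  expect_equal(nrow(mid), 1L)
  expect_lt(mid[1, "Y1"], 1.2)
  # mutual activation under inhibitory control stays bistable, with the
  # high state pulled down on the degraded species
  ma <- make_controlled_mutual_activation(kinetic_params(beta = 3))
  eqm <- find_equilibria(ma)
  expect_equal(unname(count_equilibria(eqm)["stable"]), 2L)
  S <- stable_states(eqm)
  hi <- S[which.max(S[, "Y1"]), ]
  r <- sort(Re(polyroot(c(1, 0, -2.2, 1))))
  y_free <- r[length(r)]
  expect_lt(hi["Y1"], y_free)  # degradation acts on Y1
  expect_lt(hi["Y1"], hi["Y2"])
})
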