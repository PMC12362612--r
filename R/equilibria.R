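# Quasi-steady-state reduction of the controller, nullclines in the
# (y1, y2) plane, equilibrium location and stability classification.

#' Controller quasi-steady state given its sensing drive
#'
#' For a frozen value p of the sensing Hill function, the controller's
#' steady state is x = theta*p/delta and, with
#' d = p*(k*theta - xi*delta)/delta^2, u1 is the positive root of
#' gamma*u^2 + (delta - gamma*d)*u - k*theta*p/delta = 0, with
#' u2 = u1 - d. At gamma = 0 the sequestration-free linear steady state
#' u1 = k*theta*p/delta^2, u2 = xi*p/delta is returned instead.
#'
#' @param p value(s) of the sensing Hill function, >= 0.
#' @param params a [kinetic_params()] object (gamma may be 0).
#' @return A list with numeric vectors \code{u1}, \code{u2}, \code{x}
#'   (same length as p), all nonnegative.
#' @export
controller_qss <- function(p, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(p < 0)) stop("p must be nonnegative", call. = FALSE)
  del <- params$delta; gam <- params$gamma
  kth <- params$k * params$theta; xi <- params$xi
  x <- params$theta * p / del
  if (gam == 0) {
    return(list(u1 = kth * p / del^2, u2 = xi * p / del, x = x))
  }
  d <- p * (kth - xi * del) / del^2
  b <- del - gam * d
  u1 <- (-b + sqrt(b^2 + 4 * gam * kth * p / del)) / (2 * gam)
  list(u1 = u1, u2 = u1 - d, x = x)
}

# reduced 2-D right-hand side on the (y1, y2) plane with every controller
# eliminated at its quasi-steady state; vectorized, tolerant of slightly
# negative probes (clamped) so Newton steps can overshoot safely
reduced_rhs_fn <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("Y1", "Y2") %in% spec$species))
    stop("spec is not reducible to the (Y1, Y2) plane", call. = FALSE)
  endo <- c("Y1", "Y2")
  ctrl_species <- setdiff(spec$species, endo)
  endo_terms <- Filter(function(tm) {
    refs <- unlist(tm[names(tm) %in% c("target", "source", "source2")])
    all(refs %in% endo)
  }, spec$terms)
  ctl <- spec$controllers
  p <- spec$params
  if (length(ctrl_species) && !length(ctl))
    stop("spec has auxiliary species but no controller descriptors; ",
         "cannot reduce", call. = FALSE)
  function(y1, y2) {
    n <- max(length(y1), length(y2))
    y1 <- rep_len(pmax(y1, 0), n); y2 <- rep_len(pmax(y2, 0), n)
    f1 <- numeric(n); f2 <- numeric(n)
    y <- list(Y1 = y1, Y2 = y2)
    for (tm in endo_terms) {
      v <- switch(tm$type,
        hill_production = tm$rate *
          hill_value(y[[tm$source]], tm$K, tm$m, tm$regulation),
        constant_production = rep(tm$rate, length(y1)),
        linear_decay = -tm$rate * y[[tm$target]],
        stop("unexpected endogenous term: ", tm$type, call. = FALSE))
      if (tm$target == "Y1") f1 <- f1 + v else f2 <- f2 + v
    }
    for (cd in ctl) {
      ps <- hill_value(y[[cd$sense_species]], p$K, p$m, cd$sense_regulation)
      qs <- controller_qss(ps, p)
      u <- if (cd$input_species == "U1") qs$u1 else qs$u2
      yt <- y[[cd$target_species]]
      v <- if (cd$actuation == "additive_activation") {
        cd$gain * u
      } else {
        -cd$gain * u * yt / (yt + p$K_deg)
      }
      if (cd$target_species == "Y1") f1 <- f1 + v else f2 <- f2 + v
    }
    cbind(f1, f2)
  }
}

# default search box: production maxima per endogenous species / delta, x1.5
search_box <- function(spec) {
  prod_max <- c(Y1 = 0, Y2 = 0)
  for (tm in spec$terms) {
    if (tm$type %in% c("hill_production", "constant_production") &&
        tm$target %in% names(prod_max))
      prod_max[tm$target] <- prod_max[tm$target] + tm$rate
  }
  c(0, 1.5 * max(prod_max) / spec$params$delta)
}

# all roots of g on [lo, hi] by sign-change bracketing on an n-point grid;
# g must accept a vector argument
bracket_roots <- function(g, lo, hi, n = 400, tol = 1e-10) {
  xs <- seq(lo, hi, length.out = n)
  gv <- g(xs)
  idx <- which(is.finite(gv[-n]) & is.finite(gv[-1]) &
                 sign(gv[-n]) * sign(gv[-1]) < 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root, numeric(1))
  exact <- xs[which(gv == 0)]
  sort(unique(c(roots, exact)))
}

#' Nullclines of the reduced system in the (y1, y2) plane
#'
#' Computes the locus where the time derivative of one endogenous species
#' vanishes, with all controller states eliminated at quasi-steady state.
#' For each abscissa of the sampling grid (the other species' value), every
#' ordinate solving the scalar equation is found by sign-change bracketing
#' and bisection, so disconnected and multivalued branches are captured.
#'
#' @param spec a reducible [model_spec()].
#' @param axis 1 for the y1-dot = 0 curve, 2 for y2-dot = 0.
#' @param grid abscissa values; defaults to 400 points over the search box.
#' @return A data.frame with columns \code{y1}, \code{y2} and
#'   \code{branch} (index of the root within its column).
#' @export
nullclines <- function(spec, axis = 1, grid = NULL) {
  stopifnot(axis %in% c(1, 2))
  f <- reduced_rhs_fn(spec)
  box <- search_box(spec)
  if (is.null(grid)) grid <- seq(box[1], box[2], length.out = 400)
  pts <- lapply(grid, function(ab) {
    g <- if (axis == 1) function(v) f(v, ab)[, 1] else function(v) f(ab, v)[, 2]
    r <- bracket_roots(g, box[1], box[2])
    if (!length(r)) return(NULL)
    if (axis == 1) data.frame(y1 = r, y2 = ab, branch = seq_along(r))
    else data.frame(y1 = ab, y2 = r, branch = seq_along(r))
  })
  out <- do.call(rbind, pts)
  if (is.null(out)) out <- data.frame(y1 = numeric(0), y2 = numeric(0),
                                      branch = integer(0))
  attr(out, "axis") <- axis
  out
}

# damped Newton on the reduced map from one seed; NULL if not converged
newton_2d <- function(f, y, tol = 1e-11, maxit = 60) {
  for (it in seq_len(maxit)) {
    F0 <- drop(f(y[1], y[2]))
    if (!all(is.finite(F0))) return(NULL)
    if (max(abs(F0)) < tol) return(pmax(y, 0))
    h <- 1e-7 * max(1, abs(y))
    J <- cbind((drop(f(y[1] + h, y[2])) - F0) / h,
               (drop(f(y[1], y[2] + h)) - F0) / h)
    dy <- tryCatch(solve(J, -F0), error = function(e) NULL)
    if (is.null(dy) || any(!is.finite(dy))) return(NULL)
    step <- 1
    repeat {
      yn <- y + step * dy
      Fv <- suppressWarnings(max(abs(drop(f(yn[1], yn[2])))))
      if ((is.finite(Fv) && Fv < max(abs(F0))) || step < 1e-6) break
      step <- step / 2
    }
    y <- y + step * dy
    if (any(!is.finite(y)) || any(y < -1) || max(y) > 1e3) return(NULL)
  }
  NULL
}

# lift a point of the (y1, y2) plane to the full state via the controller
# quasi-steady state (exact at equilibria: the controller subsystem is
# driven only by y1, y2)
lift_state <- function(spec, y1, y2) {
  st <- stats::setNames(numeric(length(spec$species)), spec$species)
  st["Y1"] <- y1; st["Y2"] <- y2
  p <- spec$params
  for (i in seq_along(spec$controllers)) {
    cd <- spec$controllers[[i]]
    ps <- hill_value(if (cd$sense_species == "Y1") y1 else y2,
                     p$K, p$m, cd$sense_regulation)
    qs <- controller_qss(ps, p)
    suff <- if (i == 1) c("X", "U1", "U2") else c("Xp", "U1p", "U2p")
    st[suff] <- c(qs$x, qs$u1, qs$u2)
  }
  unname(st)
}

#' Classify the stability of a fixed point
#'
#' Builds the full-system Jacobian by central finite differences (relative
#' step 1e-6) and labels the point from the eigenvalue real parts with
#' threshold 1e-6: "stable" (all < -1e-6), "unstable" (all > 1e-6),
#' "saddle" (mixed signs), or "marginal" (some real part within the
#' threshold of zero).
#'
#' @param spec a [model_spec()].
#' @param point full-state vector at (or very near) a fixed point;
#'   an error is raised if the residual exceeds 1e-6.
#' @return A list (class \code{"equilibrium"}) with \code{location},
#'   \code{eigenvalues} and \code{label}.
#' @export
classify_stability <- function(spec, point) {
  res <- max(abs(rhs_eval(spec, point)))
  if (res >= 1e-6)
    stop("point is not a fixed point: max |rhs| = ", format(res),
         call. = FALSE)
  ns <- length(point)
  J <- matrix(0, ns, ns)
  for (j in seq_len(ns)) {
    h <- 1e-6 * max(1, abs(point[j]))
    ep <- em <- point
    ep[j] <- point[j] + h
    em[j] <- max(point[j] - h, 0)
    J[, j] <- (rhs_eval(spec, ep) - rhs_eval(spec, em)) / (ep[j] - em[j])
  }
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  label <- if (any(abs(re) <= 1e-6)) "marginal"
  else if (all(re < 0)) "stable"
  else if (all(re > 0)) "unstable"
  else "saddle"
  structure(list(location = point, eigenvalues = ev, label = label),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium at (%s)\n", x$label,
              paste(signif(x$location, 5), collapse = ", ")))
  invisible(x)
}

#' Locate all equilibria of a (possibly controlled) two-gene network
#'
#' Seeds a lattice over the search box, keeps seeds that are local minima of
#' the reduced-map residual, adds seeds where the two reduced nullclines
#' cross (sign changes of one component along the bracketed branches of the
#' other), polishes every seed with damped Newton iteration on the reduced
#' 2-D map, lifts converged roots to the full state via the controller
#' quasi-steady state, deduplicates at 1e-4 uM, and classifies each point
#' from the full Jacobian spectrum.
#'
#' @param spec a reducible [model_spec()].
#' @param box search box (length-2, same for both axes); default
#'   \code{[0, 1.5 * max production / delta]}.
#' @param grid_n lattice resolution per axis.
#' @param tol Newton convergence tolerance on the reduced residual.
#' @return An object of class \code{"equilibrium_set"}: a list of
#'   \code{"equilibrium"} objects plus the search box and species names.
#' @export
find_equilibria <- function(spec, box = NULL, grid_n = 60, tol = 1e-11) {
  f <- reduced_rhs_fn(spec)
  if (is.null(box)) box <- search_box(spec)
  g <- seq(box[1], box[2], length.out = grid_n)
  G <- expand.grid(y1 = g, y2 = g)
  Fv <- f(G$y1, G$y2)
  nrm <- matrix(pmax(abs(Fv[, 1]), abs(Fv[, 2])), grid_n, grid_n)
  seeds <- list()
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    nb <- nrm[max(1, i - 1):min(grid_n, i + 1),
              max(1, j - 1):min(grid_n, j + 1)]
    if (nrm[i, j] <= min(nb)) seeds[[length(seeds) + 1L]] <- c(g[i], g[j])
  }
  # nullcline-crossing seeds: along each y2-dot = 0 branch (y2 solved per y1
  # column), bracket sign changes of y1-dot between adjacent columns
  cols <- seq(box[1], box[2], length.out = 400)
  prev <- NULL
  for (y1c in cols) {
    r2 <- bracket_roots(function(v) f(y1c, v)[, 2], box[1], box[2], n = 200)
    cur <- if (length(r2)) {
      data.frame(y1 = y1c, y2 = r2, f1 = f(rep(y1c, length(r2)), r2)[, 1])
    } else NULL
    if (!is.null(prev) && !is.null(cur)) {
      for (ii in seq_len(nrow(cur))) {
        jj <- which.min(abs(prev$y2 - cur$y2[ii]))
        if (abs(prev$y2[jj] - cur$y2[ii]) < diff(box) / 10 &&
            sign(prev$f1[jj]) * sign(cur$f1[ii]) < 0) {
          seeds[[length(seeds) + 1L]] <-
            c((prev$y1[jj] + cur$y1[ii]) / 2, (prev$y2[jj] + cur$y2[ii]) / 2)
        }
      }
    }
    prev <- cur
  }
  roots <- list()
  for (s in seeds) {
    y <- newton_2d(f, s, tol = tol)
    if (!is.null(y) && all(y >= -1e-9) &&
        all(y <= box[2] + 1) && max(abs(drop(f(y[1], y[2])))) < 1e-9)
      roots[[length(roots) + 1L]] <- pmax(y, 0)
  }
  if (length(roots)) {
    R <- do.call(rbind, roots)
    keep <- rep(TRUE, nrow(R))
    for (i in seq_len(nrow(R))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(R))) {
        if (j > i && keep[j] && max(abs(R[i, ] - R[j, ])) < 1e-4)
          keep[j] <- FALSE
      }
    }
    R <- R[keep, , drop = FALSE]
  } else {
    R <- matrix(numeric(0), 0, 2)
  }
  eqs <- lapply(seq_len(nrow(R)), function(i) {
    classify_stability(spec, lift_state(spec, R[i, 1], R[i, 2]))
  })
  structure(list(equilibria = eqs, search_box = box,
                 species = spec$species, model = spec$name),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  labs <- vapply(x$equilibria, `[[`, character(1), "label")
  cat(sprintf("%d equilibria of '%s' (%s)\n", length(labs), x$model,
              paste(names(table(labs)), table(labs),
                    sep = ": ", collapse = ", ")))
  for (e in x$equilibria) print(e)
  invisible(x)
}

#' Extract the stable equilibria of an equilibrium set
#'
#' @param eqset an \code{"equilibrium_set"} from [find_equilibria()].
#' @param species optional columns to keep (default: Y1, Y2).
#' @return Matrix of stable-equilibrium locations (one row each).
#' @export
stable_states <- function(eqset, species = c("Y1", "Y2")) {
  stopifnot(inherits(eqset, "equilibrium_set"))
  idx <- match(species, eqset$species)
  st <- Filter(function(e) e$label == "stable", eqset$equilibria)
  out <- t(vapply(st, function(e) e$location[idx], numeric(length(idx))))
  colnames(out) <- species
  out
}

#' Count equilibria by stability class
#'
#' @param eqset an \code{"equilibrium_set"}.
#' @return Named integer vector with counts of stable, saddle, unstable and
#'   marginal points (saddles are unstable equilibria with a mixed
#'   spectrum; "unstable" here means fully repelling).
#' @export
count_equilibria <- function(eqset) {
  stopifnot(inherits(eqset, "equilibrium_set"))
  labs <- vapply(eqset$equilibria, `[[`, character(1), "label")
  c(stable = sum(labs == "stable"), saddle = sum(labs == "saddle"),
    unstable = sum(labs == "unstable"), marginal = sum(labs == "marginal"))
}

#' Percent alteration of an equilibrium coordinate
#'
#' 100 * |new - ref| / ref on the named species, the standard measure of how
#' much the controller (or a parameter change) shifts a matched equilibrium.
#' If the reference coordinate is zero the absolute difference is returned,
#' flagged with attribute \code{absolute = TRUE}.
#'
#' @param reference_eq,new_eq \code{"equilibrium"} objects or bare state
#'   vectors matched to the same species ordering.
#' @param species species name (requires \code{species_names}) or index.
#' @param species_names species ordering for name lookup.
#' @return Percent alteration (scalar).
#' @export
alteration_percent <- function(reference_eq, new_eq, species,
                               species_names = NULL) {
  loc <- function(e) if (inherits(e, "equilibrium")) e$location else e
  r <- loc(reference_eq); n <- loc(new_eq)
  i <- if (is.character(species)) {
    if (is.null(species_names))
      stop("species_names needed to resolve '", species, "'", call. = FALSE)
    match(species, species_names)
  } else species
  if (r[i] == 0) {
    out <- abs(n[i] - r[i])
    attr(out, "absolute") <- TRUE
    return(out)
  }
  100 * abs(n[i] - r[i]) / r[i]
}

# relative Euclidean shift of the whole equilibrium point (percent); the
# convention behind the "maximum alteration" summaries of the r-scan
point_shift_percent <- function(ref, new) {
  100 * sqrt(sum((new - ref)^2)) / sqrt(sum(ref^2))
}

# match each row of `new` to the nearest row of `ref` (indices into ref)
match_equilibria <- function(ref, new) {
  apply(new, 1, function(x)
    which.min(colSums((t(ref) - x)^2)))
}
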