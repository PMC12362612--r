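# Cell-fate classification of terminal states and the 8-bin endpoint
# histograms summarising stochastic ensembles.

#' Classify a terminal state by its nearest attractor
#'
#' Euclidean nearest-attractor assignment restricted to the endogenous
#' species. If the two smallest distances differ by less than 5% (relative
#' to the smaller), the state is "unresolved" rather than force-assigned.
#'
#' @param final_state terminal state (concentrations), full or endogenous.
#' @param attractors matrix of stable-equilibrium locations, one row per
#'   attractor, columns matching the endogenous species; row names are the
#'   fate labels (defaulted to "Y1-high"-style labels via
#'   [label_attractors()] when absent).
#' @param endo_idx columns of \code{final_state} holding the endogenous
#'   species (default: the first \code{ncol(attractors)}).
#' @return The winning attractor's label, or "unresolved".
#' @export
classify_fate <- function(final_state, attractors, endo_idx = NULL) {
  if (is.null(dim(attractors)) || nrow(attractors) < 1)
    stop("at least one attractor is required", call. = FALSE)
  if (is.null(rownames(attractors)))
    rownames(attractors) <- label_attractors(attractors)
  if (is.null(endo_idx)) endo_idx <- seq_len(ncol(attractors))
  y <- final_state[endo_idx]
  d <- sqrt(colSums((t(attractors) - y)^2))
  o <- order(d)
  if (nrow(attractors) > 1) {
    d1 <- d[o[1]]; d2 <- d[o[2]]
    if (d2 - d1 < 0.05 * max(d1, .Machine$double.eps)) return("unresolved")
  }
  rownames(attractors)[o[1]]
}

#' Default fate labels for a set of attractors
#'
#' Names each attractor by its dominant endogenous species ("Y1-high",
#' "Y2-high"), or "low" / "intermediate" when no species dominates.
#'
#' @param attractors matrix of attractor locations (columns = endogenous
#'   species, defaulting to Y1, Y2).
#' @return Character vector of labels.
#' @export
label_attractors <- function(attractors) {
  nm <- colnames(attractors)
  if (is.null(nm)) nm <- paste0("Y", seq_len(ncol(attractors)))
  apply(attractors, 1, function(x) {
    if (max(x) < 0.05 * max(attractors, 1e-12)) return("low")
    rel <- x / max(x)
    if (sum(rel > 0.95) > 1) "intermediate"
    else paste0(nm[which.max(x)], "-high")
  })
}

#' Fate distribution of an ensemble of terminal states
#'
#' Classifies every terminal state by nearest attractor, tallies the
#' per-attractor fractions (plus an "unresolved" bucket), and builds the
#' 8-bin histogram of one species' terminal values over [0, max]. SSA
#' terminal counts are converted back to concentrations (/ omega) before
#' classification so attractors in uM are comparable.
#'
#' @param finals matrix of terminal states, one row per run (counts for SSA
#'   ensembles, uM otherwise); typically the output of [run_ensemble()].
#' @param attractors matrix of attractor locations in uM (rows labelled, or
#'   labelled automatically).
#' @param species column (name or index of \code{finals}) to histogram.
#' @param bins number of histogram bins (default 8).
#' @param omega system size used to generate \code{finals}; taken from
#'   \code{attr(finals, "omega")} when present.
#' @return An object of class \code{"fate_distribution"} with elements
#'   \code{attractors}, \code{fractions} (summing to 1), \code{labels}
#'   (per run), \code{histogram} (breaks + counts summing to n), and
#'   provenance fields \code{n}, \code{t_end}, \code{seed}, \code{omega}.
#' @export
fate_distribution <- function(finals, attractors, species = "Y1", bins = 8,
                              omega = NULL) {
  if (!is.matrix(finals) || nrow(finals) < 1)
    stop("finals must be a nonempty matrix", call. = FALSE)
  if (is.null(omega)) {
    omega <- attr(finals, "omega")
    if (is.null(omega) || is.na(omega)) omega <- 1
  }
  conc <- finals / omega
  if (is.null(rownames(attractors)))
    rownames(attractors) <- label_attractors(attractors)
  endo_idx <- match(colnames(attractors), colnames(conc))
  if (anyNA(endo_idx)) endo_idx <- seq_len(ncol(attractors))
  labels <- apply(conc, 1, classify_fate, attractors = attractors,
                  endo_idx = endo_idx)
  lv <- c(rownames(attractors), "unresolved")
  fr <- table(factor(labels, levels = lv)) / nrow(conc)
  vals <- conc[, species]
  top <- max(vals, .Machine$double.eps)
  breaks <- seq(0, top, length.out = bins + 1)
  counts <- as.integer(table(cut(vals, breaks, include.lowest = TRUE)))
  structure(list(attractors = attractors,
                 fractions = as.numeric(fr),
                 fraction_labels = lv,
                 labels = labels,
                 histogram = list(breaks = breaks, counts = counts,
                                  species = species),
                 n = nrow(conc), omega = omega,
                 t_end = attr(finals, "t_end"),
                 seed = attr(finals, "seeds")[1]),
            class = "fate_distribution")
}

#' @export
print.fate_distribution <- function(x, ...) {
  cat(sprintf("Fate distribution over %d runs:\n", x$n))
  for (i in seq_along(x$fractions))
    cat(sprintf("  %-12s %.3f\n", x$fraction_labels[i], x$fractions[i]))
  invisible(x)
}

#' Bias index of a fate distribution
#'
#' fraction(target) minus the largest fraction among the other attractors
#' (the unresolved bucket is not an attractor and is excluded); ranges over
#' [-1, 1], with 0 for an unbiased two-attractor split and 1 for complete
#' convergence to the target.
#'
#' @param dist a [fate_distribution()] object.
#' @param target label of the favoured attractor.
#' @return Scalar bias index.
#' @export
bias_index <- function(dist, target) {
  stopifnot(inherits(dist, "fate_distribution"))
  labs <- rownames(dist$attractors)
  if (!target %in% labs)
    stop("unknown attractor label: ", target, call. = FALSE)
  fr <- dist$fractions[match(labs, dist$fraction_labels)]
  names(fr) <- labs
  others <- fr[names(fr) != target]
  unname(fr[target] - if (length(others)) max(others) else 0)
}
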