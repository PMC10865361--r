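# Persistence length from orientation correlations. The mean dot product of
# chain orientation vectors separated by k beads decays exponentially with
# the contour separation s = k * dl for a worm-like chain,
# <e_j . e_{j+k}> = exp(-s / L_P), and L_P is obtained from a weighted
# log-linear fit with the intercept fixed at zero (the correlation is exactly
# 1 at s = 0). The naive direct estimator (contour integral of the
# correlation) is also provided: it is bounded by the chain length and hence
# unphysical for short, stiff chains, which motivates the exponential fit.

#' Orientation correlation curve
#'
#' Pools `e_j . e_{j+k}` over all start indices j, all chains and all frames,
#' for bead separations k = 0..k_max. The value at k = 0 is exactly 1.
#'
#' @param sets list of `orientation_set` matrices (one per chain per frame).
#' @param k_max largest bead separation (default: longest possible).
#' @param spacing mean bead spacing dl in nm used to convert separations to
#'   contour length (default 1, i.e. separations in bead units).
#' @return object of class `correlation_curve`: data.frame with columns `k`,
#'   `separation` (k * spacing, nm), `correlation`, `count`.
#' @export
orientation_correlation <- function(sets, k_max = NULL, spacing = 1) {
  if (inherits(sets, "orientation_set")) sets <- list(sets)
  if (length(sets) == 0) stop("no orientation sets")
  lens <- vapply(sets, nrow, integer(1))
  if (any(lens < 1)) stop("orientation sets must contain at least one vector")
  if (is.null(k_max)) k_max <- max(lens) - 1
  if (k_max < 1) stop("k_max must be >= 1")
  sums <- numeric(k_max + 1)
  counts <- numeric(k_max + 1)
  for (e in sets) {
    n <- nrow(e)
    sums[1] <- sums[1] + n
    counts[1] <- counts[1] + n
    for (k in seq_len(min(k_max, n - 1))) {
      dots <- rowSums(e[1:(n - k), , drop = FALSE] * e[(k + 1):n, , drop = FALSE])
      sums[k + 1] <- sums[k + 1] + sum(dots)
      counts[k + 1] <- counts[k + 1] + length(dots)
    }
  }
  keep <- counts > 0
  if (any(!keep)) {
    warning("no vector pairs at separations k = ",
            paste(which(!keep) - 1, collapse = ", "), "; omitted")
  }
  k <- (0:k_max)[keep]
  out <- data.frame(k = k, separation = k * spacing,
                    correlation = sums[keep] / counts[keep],
                    count = counts[keep])
  class(out) <- c("correlation_curve", "data.frame")
  attr(out, "spacing") <- spacing
  out
}

#' Fit the persistence length to a correlation curve
#'
#' Weighted least squares of `log(correlation)` against contour separation,
#' with zero intercept and the sample counts as weights, using only
#' separations k >= 1 whose mean correlation exceeds `eps_pos` (log of
#' noise-dominated values near or below zero would otherwise corrupt the
#' fit). `L_P = -1/slope`. A curve that does not decay (fitted slope >= 0)
#' is reported as divergent (`L_P = Inf`), the signature of a rigid chain.
#'
#' @param curve a `correlation_curve` (or data.frame with `separation`,
#'   `correlation`, `count`).
#' @param spacing optional bead spacing (nm) overriding the curve's own
#'   separations: separations are recomputed as `k * spacing`.
#' @param eps_pos positive-correlation threshold for inclusion (default 0.05).
#' @return object of class `persistence_estimate`: list with `L_P` (nm),
#'   `stderr` (nm), `divergent` flag, `k_range`, `n_points`, `n_samples`.
#' @export
fit_persistence_length <- function(curve, spacing = NULL, eps_pos = 0.05) {
  s <- curve$separation
  if (!is.null(spacing)) s <- curve$k * spacing
  use <- curve$k >= 1 & curve$correlation > eps_pos
  if (sum(use) < 1) stop("persistence fit failed: no separations with correlation > ", eps_pos)
  y <- log(curve$correlation[use])
  x <- s[use]
  w <- curve$count[use]
  slope <- sum(w * x * y) / sum(w * x^2)
  # slopes indistinguishable from zero at floating precision count as rigid
  if (slope >= -1e-12) {
    est <- list(L_P = Inf, stderr = NA_real_, divergent = TRUE,
                k_range = range(curve$k[use]), n_points = sum(use),
                n_samples = sum(w))
    class(est) <- "persistence_estimate"
    return(est)
  }
  res <- y - slope * x
  dof <- max(sum(use) - 1, 1)
  sigma2 <- sum(w * res^2) / dof
  se_slope <- sqrt(sigma2 / sum(w * x^2))
  L_P <- -1 / slope
  est <- list(L_P = L_P, stderr = se_slope / slope^2, divergent = FALSE,
              k_range = range(curve$k[use]), n_points = sum(use),
              n_samples = sum(w))
  class(est) <- "persistence_estimate"
  est
}

#' @export
print.persistence_estimate <- function(x, ...) {
  if (x$divergent) {
    cat("persistence_estimate: divergent (no measurable decay)\n")
  } else {
    cat(sprintf("persistence_estimate: L_P = %.3f nm (se %.3f), %d separations, %g samples\n",
                x$L_P, x$stderr, x$n_points, x$n_samples))
  }
  invisible(x)
}

#' Naive direct persistence estimate (finite-size bounded)
#'
#' The direct contour integral of the correlation curve,
#' `dl * sum_k <e.e>(k)`. By construction it can never exceed the chain
#' contour length, so for short stiff chains it underestimates badly; it is
#' kept as the reference against which the exponential fit is compared.
#'
#' @param curve a `correlation_curve`.
#' @param spacing bead spacing dl (nm); default the curve's own spacing.
#' @return numeric, nm
#' @export
naive_persistence_sum <- function(curve, spacing = NULL) {
  if (is.null(spacing)) spacing <- attr(curve, "spacing")
  if (is.null(spacing)) spacing <- mean(diff(curve$separation))
  spacing * sum(curve$correlation)
}

#' Persistence length from a trajectory
#'
#' Builds bead chains for every frame, pools orientation correlations per
#' chain-length class (number of coiled-coil dimers in the chain), and fits
#' one persistence length per class. Chain source `"fixed"` treats all dimers
#' of the system, in index order, as one oligomer; `"assembly"` identifies
#' oligomer chains per frame from inter-dimer salt bridges (see
#' [identify_chains()]). Classes with fewer than `min_points` nearest-
#' neighbour vector pairs are excluded, as are chains longer than `max_cc`
#' coiled coils when that filter is enabled (long chains are sampled too
#' erratically to fit).
#'
#' @param stream a [frame_stream()].
#' @param system a [molecular_system()].
#' @param source `"fixed"` or `"assembly"`.
#' @param min_points minimum number of k = 1 vector pairs per class
#'   (default 2000).
#' @param max_cc maximum chain length in coiled coils (default 7); `Inf`
#'   disables the filter.
#' @param criteria salt-bridge criteria for `source = "assembly"`.
#' @param eps_pos passed to [fit_persistence_length()].
#' @return list with `estimates` (named list of `persistence_estimate` per
#'   class), `curves` (per-class correlation curves), `range` (min/max finite
#'   L_P over classes), `spacing` (empirical mean bead spacing, nm).
#' @export
persistence_from_trajectory <- function(stream, system,
                                        source = c("fixed", "assembly"),
                                        min_points = 2000, max_cc = 7,
                                        criteria = salt_bridge_criteria(),
                                        eps_pos = 0.05) {
  source <- match.arg(source)
  if (!is.finite(max_cc)) max_cc <- .Machine$integer.max
  sets_by_class <- list()
  spacing_sum <- 0
  spacing_n <- 0
  for (fr in stream$frames) {
    chains <- if (source == "fixed") {
      list(system$dimers)
    } else {
      tl <- frame_chains(fr, system, criteria)
      c(lapply(tl$chains, `[[`, "dimers"), as.list(tl$unbound))
    }
    for (ch in chains) {
      cls <- as.character(length(ch))
      bc <- build_bead_chain(fr, system, ch)
      e <- chain_orientations(bc)
      sets_by_class[[cls]] <- c(sets_by_class[[cls]], list(e))
      spacing_sum <- spacing_sum + bc$spacing * (nrow(bc$beads) - 1)
      spacing_n <- spacing_n + (nrow(bc$beads) - 1)
    }
  }
  spacing <- spacing_sum / spacing_n
  classes <- sort(as.integer(names(sets_by_class)))
  estimates <- list()
  curves <- list()
  for (cls in classes) {
    if (cls > max_cc) next
    sets <- sets_by_class[[as.character(cls)]]
    curve <- orientation_correlation(sets, spacing = spacing)
    n1 <- curve$count[curve$k == 1]
    if (length(n1) == 0 || n1 < min_points) next
    estimates[[as.character(cls)]] <- fit_persistence_length(curve, eps_pos = eps_pos)
    curves[[as.character(cls)]] <- curve
  }
  if (length(estimates) == 0) {
    stop("no chain-length class passes the filters (min_points = ", min_points,
         ", max_cc = ", max_cc, ")")
  }
  lps <- vapply(estimates, function(e) e$L_P, numeric(1))
  finite <- lps[is.finite(lps)]
  rng <- if (length(finite) > 0) range(finite) else c(Inf, Inf)
  list(estimates = estimates, curves = curves, range = rng, spacing = spacing)
}
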