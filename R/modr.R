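#' Discretize the factor space into an inclusive grid
#'
#' Builds the Cartesian grid of factor settings used for MODR mapping. Each
#' axis is the inclusive arithmetic sequence from the factor's `low` to `high`
#' by its `grid_step`; rows are ordered with the first factor varying fastest.
#'
#' @param factors List of [factor_spec()] objects, each with a `grid_step`.
#' @return Tibble of natural-unit settings (one column per factor) carrying
#'   `"axes"` (named list of axis values) and `"factors"` attributes.
#' @examples
#' g <- build_grid(fa_factors())
#' nrow(g) # 21 * 21 * 11 = 4851
#' @export
build_grid <- function(factors) {
  stopifnot(all(vapply(factors, inherits, TRUE, "factor_spec")))
  axes <- lapply(factors, function(f) {
    if (is.na(f$grid_step)) {
      abort(sprintf("Factor '%s' has no `grid_step`; cannot grid it.", f$name))
    }
    n_pts <- round((f$high - f$low) / f$grid_step) + 1L
    f$low + (seq_len(n_pts) - 1L) * f$grid_step
  })
  names(axes) <- vapply(factors, `[[`, "", "name")
  out <- tibble::as_tibble(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  attr(out, "axes") <- axes
  attr(out, "factors") <- factors
  out
}

# Coefficient draw matrices (p x n_draws) for every model, in list order,
# term by term, so a fixed seed fixes the whole simulation.
draw_coefficients <- function(models, n_draws, method) {
  lapply(models, function(m) {
    p <- length(m$coefficients)
    if (any(!is.finite(m$std_errors))) {
      abort(sprintf(
        "Model '%s' has missing standard errors; refit it before Monte Carlo propagation.",
        m$response))
    }
    if (all(m$vcov == 0)) {
      # degenerate fit (zero residual variance): coefficients are exact
      matrix(m$coefficients, nrow = p, ncol = n_draws)
    } else if (method == "covariance") {
      z <- matrix(rnorm(p * n_draws), nrow = p)
      m$coefficients + t(chol(m$vcov)) %*% z
    } else {
      matrix(rnorm(p * n_draws, mean = m$coefficients, sd = m$std_errors),
             nrow = p)
    }
  })
}

#' Monte Carlo probability of meeting all CMA rules across the factor grid
#'
#' Propagates model-coefficient uncertainty: each iteration perturbs every
#' model's coefficient vector once and evaluates all grid points under that
#' perturbed set of surfaces, so an iteration represents one plausible "true"
#' model. A point's probability is the fraction of iterations in which every
#' rule holds jointly. With all standard errors zero the probabilities are
#' exactly 0 or 1.
#'
#' The default perturbation draws from the multivariate normal with the full
#' estimated coefficient covariance of each fit — the sampling distribution of
#' the least-squares estimates. `method = "independent"` instead perturbs each
#' coefficient independently by its standard error; this ignores the
#' correlation between estimates (intercept and quadratic terms of a
#' face-centered design are strongly correlated) and typically overstates
#' prediction uncertainty.
#'
#' @param grid Tibble of natural-unit factor settings, e.g. from
#'   [build_grid()] (any data frame of settings works; grid attributes are
#'   carried through for [extract_modr()]).
#' @param models Named list of [fit_rsm()] objects covering every CMA the
#'   rules reference.
#' @param rules A [cma_rules()] table.
#' @param n_draws Number of Monte Carlo iterations.
#' @param seed Integer seed; identical settings give bit-identical output.
#' @param method `"covariance"` (default) or `"independent"`, see Details.
#' @param chunk_size Iterations evaluated per block, a memory/speed trade-off
#'   with no effect on results.
#' @return `grid` plus a `probability` column, with simulation settings stored
#'   in attributes.
#' @examples
#' models <- fit_fa_models()
#' wp <- tibble::tibble(flow = 0.575, tgrad = 14.2, temp = 33)
#' modr_probability(wp, models, fa_cma_rules(), n_draws = 500, seed = 1)
#' @export
modr_probability <- function(grid, models, rules, n_draws = 5000, seed = 1,
                             method = c("covariance", "independent"),
                             chunk_size = 1000) {
  method <- match.arg(method)
  stopifnot(inherits(rules, "cma_rules"), nrow(grid) >= 1, n_draws >= 1)
  stopifnot(!is.null(names(models)), all(vapply(models, inherits, TRUE, "rsm_fit")))

  factors <- models[[1]]$factors
  coded <- coded_matrix(grid, factors)
  Xs <- lapply(models, function(m) rsm_model_matrix(coded, m$terms))

  set.seed(seed)
  draws <- draw_coefficients(models, n_draws, method)

  pass <- numeric(nrow(grid))
  starts <- seq(1L, n_draws, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n_draws)
    preds <- lapply(names(models), function(nm) {
      inverse_transform(Xs[[nm]] %*% draws[[nm]][, idx, drop = FALSE],
                        models[[nm]]$transform)
    })
    names(preds) <- names(models)
    cmas <- derive_cmas(preds, rules$cma)
    ok <- NULL
    for (r in seq_len(nrow(rules))) {
      this <- if (rules$comparator[r] == ">") cmas[[rules$cma[r]]] > rules$bound[r]
              else cmas[[rules$cma[r]]] < rules$bound[r]
      ok <- if (is.null(ok)) this else ok & this
    }
    pass <- pass + rowSums(ok)
  }

  out <- tibble::as_tibble(grid)
  out$probability <- unname(pass) / n_draws
  attr(out, "axes") <- attr(grid, "axes")
  attr(out, "factors") <- attr(grid, "factors") %||% factors
  attr(out, "rules") <- rules
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# probability tibble -> 3-D array in axis order
prob_array <- function(prob) {
  axes <- attr(prob, "axes")
  if (is.null(axes)) abort("Probability table lacks grid axes; build it from `build_grid()` output.")
  array(prob$probability, dim = lengths(axes), dimnames = NULL)
}

# logical array shifted by +/-1 along axis `ax`, padded with `fill`
shift_pad <- function(a, ax, dir, fill) {
  out <- array(fill, dim = dim(a))
  n <- dim(a)[ax]
  idx_all <- lapply(dim(a), seq_len)
  src <- idx_all; dst <- idx_all
  dst[[ax]] <- seq_len(n - 1L) + 1L
  src[[ax]] <- seq_len(n - 1L)
  if (dir < 0) { tmp <- src; src <- dst; dst <- tmp }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract the Method Operable Design Region from a probability map
#'
#' Thresholds the per-point joint probability into the MODR mask and labels
#' each in-mask point `"interior"` when all of its existing face neighbors
#' (up to 6 on the 3-D grid) are also in the mask, `"edge"` otherwise. Edge
#' points meet the criteria but sit within one grid step of conditions that do
#' not — operating there risks drifting out of the robust region.
#'
#' @param prob Probability table from [modr_probability()] evaluated on a full
#'   [build_grid()] grid.
#' @param threshold Probability threshold; defaults to the rule set's
#'   `probability_threshold` (0.90 in the packaged study).
#' @return A `modr_result`: the probability table plus `in_modr` (logical) and
#'   `zone` (`"outside"`, `"edge"`, `"interior"`).
#' @examples
#' \donttest{
#' models <- fit_fa_models()
#' pr <- modr_probability(build_grid(fa_factors()), models, fa_cma_rules(),
#'                        n_draws = 500, seed = 1)
#' modr <- extract_modr(pr)
#' summary(modr)
#' }
#' @export
extract_modr <- function(prob, threshold = NULL) {
  rules <- attr(prob, "rules")
  threshold <- threshold %||% attr(rules, "probability_threshold") %||% 0.90
  arr <- prob_array(prob)
  mask <- arr >= threshold

  interior <- mask
  for (ax in 1:3) {
    interior <- interior &
      shift_pad(mask, ax, +1, TRUE) & shift_pad(mask, ax, -1, TRUE)
  }
  zone <- ifelse(mask, ifelse(interior, "interior", "edge"), "outside")

  out <- tibble::as_tibble(prob)
  out$in_modr <- as.vector(mask)
  out$zone <- as.vector(zone)
  for (a in c("axes", "factors", "rules", "n_draws", "seed", "method")) {
    attr(out, a) <- attr(prob, a)
  }
  attr(out, "threshold") <- threshold
  class(out) <- c("modr_result", class(out))
  out
}

#' @export
summary.modr_result <- function(object, ...) {
  axes <- attr(object, "axes")
  tibble::tibble(
    threshold = attr(object, "threshold"),
    n_grid = nrow(object),
    n_in_modr = sum(object$in_modr),
    n_interior = sum(object$zone == "interior"),
    volume_fraction = mean(object$in_modr),
    n_draws = attr(object, "n_draws") %||% NA_integer_
  )
}

#' @export
print.modr_result <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "<modr_result> %d grid points, threshold %.2f: %d in MODR (%.1f%%), %d interior\n",
    s$n_grid, s$threshold, s$n_in_modr, 100 * s$volume_fraction, s$n_interior))
  invisible(x)
}

#' Select a working point from the center of the MODR
#'
#' Computes the erosion-depth distance transform of the MODR mask (6-neighbor
#' connectivity; conditions outside the grid count as out-of-mask) and returns
#' the deepest in-mask grid point — the setting farthest, in grid steps, from
#' any condition that fails the criteria. Ties resolve to the highest joint
#' probability, then to the lowest value on the first axis (for the packaged
#' study that is flow rate, i.e. solvent economy), then lowest on the
#' remaining axes.
#'
#' @param modr A [extract_modr()] result with a nonempty mask.
#' @return One-row tibble: the selected natural-unit setting, its
#'   `probability`, `depth` (erosion depth in grid steps) and `zone`.
#' @export
select_working_point <- function(modr) {
  stopifnot(inherits(modr, "modr_result"))
  if (!any(modr$in_modr)) {
    abort("The MODR is empty at this threshold; no feasible working point.")
  }
  axes <- attr(modr, "axes")
  mask <- array(modr$in_modr, dim = lengths(axes))

  depth <- array(0L, dim = dim(mask))
  cur <- mask
  d <- 0L
  while (any(cur)) {
    d <- d + 1L
    depth[cur] <- d
    eroded <- cur
    for (ax in 1:3) {
      eroded <- eroded &
        shift_pad(cur, ax, +1, FALSE) & shift_pad(cur, ax, -1, FALSE)
    }
    if (identical(eroded, cur)) break  # stable core (mask fills the grid)
    cur <- eroded
  }

  out <- tibble::as_tibble(modr)
  out$depth <- as.vector(depth)
  cand <- out[out$depth == max(out$depth), , drop = FALSE]
  ord <- do.call(order, c(list(-cand$probability),
                          lapply(names(axes), function(nm) cand[[nm]])))
  res <- cand[ord[1], c(names(axes), "probability", "depth", "zone"), drop = FALSE]
  tibble::as_tibble(lapply(as.list(res), unname))
}

#' Snap a natural-unit setting to its nearest grid point
#'
#' @param grid A [build_grid()] table (or anything carrying its `"axes"`
#'   attribute).
#' @param point Named list or one-row data frame of natural-unit coordinates.
#' @return One-row tibble with the nearest grid coordinates (ties resolve to
#'   the lower value).
#' @export
nearest_grid_point <- function(grid, point) {
  axes <- attr(grid, "axes")
  if (is.null(axes)) abort("`grid` lacks the axes attribute from `build_grid()`.")
  out <- lapply(names(axes), function(nm) {
    v <- axes[[nm]]
    v[which.min(abs(v - point[[nm]]))]
  })
  names(out) <- names(axes)
  tibble::as_tibble(out)
}

#' Probability-map slices of a MODR result
#'
#' Heat maps of the joint-satisfaction probability over the first two grid
#' axes, one facet per level of the third (for the packaged study: flow by
#' gradient time, faceted by column temperature), with the MODR boundary drawn
#' at the threshold.
#'
#' @param object A `modr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modr_result <- function(object, ...) {
  axes <- attr(object, "axes")
  nms <- names(axes)
  d <- tibble::as_tibble(object)
  d$.facet <- factor(d[[nms[3]]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[nms[1]]], y = .data[[nms[2]]])) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$probability)) +
    ggplot2::geom_tile(
      data = d[d$in_modr, , drop = FALSE],
      fill = NA, colour = "white", linewidth = 0.1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$.facet)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(fill = "P(all criteria)",
                  title = sprintf("MODR at probability >= %.2f",
                                  attr(object, "threshold")))
}
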