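#' Define a critical method parameter (design factor)
#'
#' A factor is described by its natural-unit range and, optionally, the step
#' used when the factor space is discretized for MODR computation. Coding maps
#' the range linearly onto \[-1, +1\], the convention used both for design
#' construction and for all fitted model coefficients.
#'
#' @param name Column name used for this factor in design and grid tables.
#' @param low,high Natural-unit range limits (`low < high`).
#' @param units Unit label, e.g. `"mL/min"`, `"min"`, `"degC"`.
#' @param grid_step Natural-unit step for [build_grid()]. Must divide
#'   `high - low` exactly (to within 1e-9) so the inclusive grid is well
#'   formed. May be `NA` for factors never gridded.
#' @return An object of class `factor_spec`.
#' @seealso [code_value()], [build_ccd()], [build_grid()]
#' @examples
#' factor_spec("flow", 0.5, 0.7, "mL/min", grid_step = 0.01)
#' @export
factor_spec <- function(name, low, high, units = "", grid_step = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    abort("`low` must be strictly less than `high`.")
  }
  if (!is.na(grid_step)) {
    if (grid_step <= 0) abort("`grid_step` must be positive.")
    k <- (high - low) / grid_step
    if (abs(k - round(k)) > 1e-9) {
      abort(sprintf("`grid_step` (%g) does not divide the range of '%s' (%g).",
                    grid_step, name, high - low))
    }
  }
  structure(
    list(name = name, low = as.numeric(low), high = as.numeric(high),
         units = units, grid_step = as.numeric(grid_step)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: [%g, %g] %s (grid step %s)\n",
              x$name, x$low, x$high, x$units,
              ifelse(is.na(x$grid_step), "-", format(x$grid_step))))
  invisible(x)
}

#' Convert between natural and coded factor units
#'
#' `code_value()` maps a natural-unit value onto the coded scale where the
#' factor range midpoint is 0 and the range limits are -1 and +1;
#' `decode_value()` is its exact inverse. Values outside the range are allowed
#' (coded magnitude then exceeds 1), which is what makes extrapolation checks
#' possible downstream.
#'
#' @param value Numeric vector in natural units (`code_value`) or coded units
#'   (`decode_value`).
#' @param factor A [factor_spec()].
#' @return Numeric vector of the same length.
#' @examples
#' flow <- factor_spec("flow", 0.5, 0.7, "mL/min")
#' code_value(0.575, flow)   # -0.25
#' decode_value(-0.25, flow) # 0.575
#' @export
code_value <- function(value, factor) {
  stopifnot(inherits(factor, "factor_spec"))
  centre <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  (value - centre) / half
}

#' @rdname code_value
#' @export
decode_value <- function(value, factor) {
  stopifnot(inherits(factor, "factor_spec"))
  centre <- (factor$low + factor$high) / 2
  half <- (factor$high - factor$low) / 2
  value * half + centre
}

# Coded matrix (columns x1..xk) from a data frame holding natural columns.
coded_matrix <- function(data, factors) {
  stopifnot(is.list(factors), all(vapply(factors, inherits, TRUE, "factor_spec")))
  miss <- setdiff(vapply(factors, `[[`, "", "name"), names(data))
  if (length(miss)) {
    abort(paste0("Missing factor column(s): ", paste(miss, collapse = ", ")))
  }
  out <- vapply(seq_along(factors),
                function(i) code_value(data[[factors[[i]]$name]], factors[[i]]),
                numeric(nrow(data)))
  out <- matrix(out, nrow = nrow(data))
  colnames(out) <- paste0("x", seq_along(factors))
  out
}

#' Construct a face-centered central composite design
#'
#' Builds the canonical three-factor face-centered CCD: the 8 factorial corners
#' (first factor varying fastest), the 6 axial face points (one per factor
#' face, low before high, in factor order), then `n_center` center replicates.
#' Coded levels are stored alongside natural values so tests and fixtures can
#' compare them without float drift.
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param n_center Number of center-point replicates (>= 1).
#' @param shuffle_seed If non-`NULL`, an integer seed used to randomize the run
#'   order (run order is irrelevant to OLS fitting but matters on the
#'   instrument). Default keeps the canonical systematic order.
#' @return A tibble with columns `run_id`, `<name>_coded` for each factor and
#'   the natural-unit `<name>` columns, carrying the factor list as the
#'   `"factors"` attribute.
#' @examples
#' ccd <- build_ccd(fa_factors(), n_center = 4)
#' nrow(ccd) # 18
#' @export
build_ccd <- function(factors, n_center = 4, shuffle_seed = NULL) {
  if (length(factors) != 3L) {
    abort("Face-centered CCD construction supports exactly 3 factors.")
  }
  stopifnot(all(vapply(factors, inherits, TRUE, "factor_spec")))
  if (n_center < 1) abort("`n_center` must be at least 1.")

  factorial <- as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1)))
  axial <- matrix(0, nrow = 6, ncol = 3)
  for (i in 1:3) axial[2 * i - 1, i] <- -1
  for (i in 1:3) axial[2 * i, i] <- 1
  centre <- matrix(0, nrow = n_center, ncol = 3)
  coded <- rbind(factorial, axial, centre)
  dimnames(coded) <- NULL

  if (!is.null(shuffle_seed)) {
    ord <- withr_seed(shuffle_seed, sample.int(nrow(coded)))
    coded <- coded[ord, , drop = FALSE]
  }

  nms <- vapply(factors, `[[`, "", "name")
  out <- tibble::tibble(run_id = seq_len(nrow(coded)))
  for (i in 1:3) out[[paste0(nms[i], "_coded")]] <- coded[, i]
  for (i in 1:3) out[[nms[i]]] <- decode_value(coded[, i], factors[[i]])
  attr(out, "factors") <- factors
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
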