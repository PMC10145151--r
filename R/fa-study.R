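#' The packaged fatty-acid gradient LC study
#'
#' An 18-run face-centered central composite design over three critical method
#' parameters of a gradient LC separation of eight non-volatile fatty acids
#' (charged aerosol detection), with the measured critical method attributes:
#' the peak-boundary times of the two critical pairs (end of the alpha-linolenic
#' peak / start of the myristic peak; end of the oleic peak / start of the
#' petroselinic peak) and the retention factor of the last-eluting analyte,
#' stearic acid. Runs 15-18 are center replicates.
#'
#' @return Tibble with columns `run_id`, factor settings `flow` (mL/min),
#'   `tgrad` (min), `temp` (degrees C), coded levels `<factor>_coded`, and
#'   responses `t1_end`, `t2_start`, `t6_end`, `t7_start` (min), `k_last`
#'   (dimensionless). The `"factors"` attribute holds the [fa_factors()] list.
#' @examples
#' fa_ccd_data()
#' @export
fa_ccd_data <- function() {
  d <- tibble::tribble(
    ~flow, ~tgrad, ~temp, ~t1_end, ~t2_start, ~t6_end, ~t7_start, ~k_last,
    0.50,  8.0, 30, 4.84, 4.94, 8.99,  9.01, 15.80,
    0.70,  8.0, 30, 3.53, 3.60, 6.85,  6.85, 16.99,
    0.50, 15.0, 30, 4.95, 5.07, 9.98, 10.02, 18.78,
    0.70, 15.0, 30, 3.61, 3.67, 7.47,  7.49, 19.86,
    0.50,  8.0, 40, 4.31, 4.31, 7.82,  7.82, 13.73,
    0.70,  8.0, 40, 3.12, 3.12, 5.86,  5.86, 14.64,
    0.50, 15.0, 40, 4.37, 4.37, 8.47,  8.47, 15.86,
    0.70, 15.0, 40, 3.15, 3.15, 6.27,  6.27, 16.59,
    0.50, 11.5, 35, 4.56, 4.61, 8.83,  8.84, 16.41,
    0.70, 11.5, 35, 3.33, 3.38, 6.66,  6.66, 17.32,
    0.60,  8.0, 35, 3.84, 3.87, 7.21,  7.21, 15.45,
    0.60, 15.0, 35, 3.90, 3.95, 7.85,  7.87, 17.88,
    0.60, 11.5, 30, 4.11, 4.19, 8.22,  8.23, 18.44,
    0.60, 11.5, 40, 3.62, 3.62, 7.00,  7.00, 15.48,
    0.60, 11.5, 35, 3.89, 3.93, 7.63,  7.64, 16.65,
    0.60, 11.5, 35, 3.86, 3.90, 7.57,  7.58, 16.71,
    0.60, 11.5, 35, 3.85, 3.89, 7.55,  7.57, 17.26,
    0.60, 11.5, 35, 3.85, 3.91, 7.57,  7.60, 16.87
  )
  factors <- fa_factors()
  out <- tibble::tibble(run_id = seq_len(nrow(d)))
  for (f in factors) {
    out[[paste0(f$name, "_coded")]] <- code_value(d[[f$name]], f)
  }
  out <- dplyr::bind_cols(out, d)
  attr(out, "factors") <- factors
  out
}

#' Critical method parameters of the packaged study
#'
#' Flow rate 0.5-0.7 mL/min (grid step 0.01), gradient time 8-15 min (step
#' 0.35) and column temperature 30-40 degrees C (step 1), giving the
#' 21 x 21 x 11 = 4851-point MODR grid.
#'
#' @return List of three [factor_spec()] objects, in `x1`, `x2`, `x3` order.
#' @export
fa_factors <- function() {
  list(
    factor_spec("flow", 0.5, 0.7, "mL/min", grid_step = 0.01),
    factor_spec("tgrad", 8, 15, "min", grid_step = 0.35),
    factor_spec("temp", 30, 40, "degC", grid_step = 1)
  )
}

#' Model structures of the packaged study
#'
#' The transform and reduced term set of each response-surface model, as
#' selected in the original study from Box-Cox profiles and term exclusion:
#' reciprocal surfaces for the first critical pair's boundary times, base-10
#' log surfaces for the second pair, and an untransformed surface for the
#' stearic-acid retention factor.
#'
#' @return Named list: per response, a list with `transform` and `terms`.
#' @export
fa_model_specs <- function() {
  list(
    t1_end = list(transform = "reciprocal",
                  terms = c("1", "x1", "x2", "x3", "x1:x3")),
    t2_start = list(transform = "reciprocal",
                    terms = c("1", "x1", "x2", "x3", "x1:x3")),
    t6_end = list(transform = "log10",
                  terms = c("1", "x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                            "x1^2", "x2^2")),
    t7_start = list(transform = "log10",
                    terms = c("1", "x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
                              "x1^2", "x2^2")),
    k_last = list(transform = "identity",
                  terms = c("1", "x1", "x2", "x3", "x2:x3", "x2^2"))
  )
}

#' Published coefficients of the packaged study's models
#'
#' The coefficient values as printed in the original study report (coded
#' basis, transformed-response scale, rounded to the reported precision).
#' They serve as the reference for reproduction checks and as the generative
#' truth of [fa_truth()]; refitting the packaged data with
#' [fit_fa_models()] recovers them at printed precision.
#'
#' @return Named list: per response, a list with `transform` and a named
#'   `coefficients` vector.
#' @export
fa_reference_models <- function() {
  specs <- fa_model_specs()
  coefs <- list(
    t1_end = c(0.26, 0.041, -2.111e-3, 0.016, 3.182e-3),
    t2_start = c(0.26, 0.041, -2.196e-3, 0.019, 3.317e-3),
    t6_end = c(0.88, -0.062, 0.018, -0.035, -1.631e-3, -1.506e-3, -2.369e-3,
               4.776e-3, -3.539e-3),
    t7_start = c(0.88, -0.062, 0.019, -0.035, -1.582e-3, -1.313e-3, -2.611e-3,
                 4.493e-3, -3.515e-3),
    k_last = c(16.89, 0.48, 1.24, -1.36, -0.22, -0.33)
  )
  out <- lapply(names(specs), function(nm) {
    list(transform = specs[[nm]]$transform,
         coefficients = setNames(coefs[[nm]], specs[[nm]]$terms))
  })
  setNames(out, names(specs))
}

#' CMA acceptance rules of the packaged study
#'
#' Both critical pairs must be baseline separated (`s12 > 0`, `s67 > 0`) and
#' the last peak's retention factor must stay below 18.8 (bounding the run
#' time), jointly with probability at least 0.90.
#'
#' @return A [cma_rules()] table.
#' @export
fa_cma_rules <- function() {
  cma_rules(cma = c("s12", "s67", "k_last"),
            comparator = c(">", ">", "<"),
            bound = c(0, 0, 18.8),
            probability_threshold = 0.90)
}

#' Fit the five response-surface models of the packaged study
#'
#' @param data Study data, defaulting to [fa_ccd_data()]; any table with the
#'   same columns works (e.g. a synthetic one from [generate_responses()]
#'   joined to its design).
#' @param factors Factor list, defaulting to [fa_factors()].
#' @return Named list of five [fit_rsm()] objects.
#' @examples
#' models <- fit_fa_models()
#' glance(models$k_last)
#' @export
fit_fa_models <- function(data = fa_ccd_data(), factors = fa_factors()) {
  specs <- fa_model_specs()
  miss <- setdiff(names(specs), names(data))
  if (length(miss)) {
    abort(paste0("Data lacks response column(s): ", paste(miss, collapse = ", ")))
  }
  out <- lapply(names(specs), function(nm) {
    fit_rsm(data, nm, factors, terms = specs[[nm]]$terms,
            transform = specs[[nm]]$transform)
  })
  setNames(out, names(specs))
}

#' Run the full design-to-working-point study
#'
#' Executes the whole pipeline on one table: fit the five response-surface
#' models, collect coefficient and diagnostic summaries (compared, at printed
#' precision, against the published reference when available), map the joint
#' criterion probability over the factor grid by Monte Carlo, extract the
#' MODR and select a working point from its center. With fixed `seed` the
#' report is fully reproducible.
#'
#' @inheritParams fit_fa_models
#' @param rules A [cma_rules()] table.
#' @param n_draws Monte Carlo iterations.
#' @param seed Integer seed for the Monte Carlo stage.
#' @param method Coefficient perturbation, see [modr_probability()].
#' @param reference Optional published-model list in the shape of
#'   [fa_reference_models()], used for the coefficient comparison table; pass
#'   `NULL` to skip.
#' @return A `study_report` list: `models`, `coefficients` (tidy table, with
#'   reference comparison when available), `diagnostics`, `grid_size`, `modr`
#'   (a [extract_modr()] result), and `working_point`.
#' @examples
#' \donttest{
#' rep <- run_study(n_draws = 200, seed = 1)
#' rep$working_point
#' }
#' @export
run_study <- function(data = fa_ccd_data(), factors = fa_factors(),
                      rules = fa_cma_rules(), n_draws = 5000, seed = 1,
                      method = c("covariance", "independent"),
                      reference = fa_reference_models()) {
  method <- match.arg(method)
  models <- fit_fa_models(data, factors)

  coefs <- purrr::map_dfr(names(models),
                          function(nm) dplyr::mutate(tidy(models[[nm]]),
                                                     response = nm, .before = 1))
  if (!is.null(reference)) {
    ref_tbl <- purrr::map_dfr(names(reference), function(nm) {
      tibble::tibble(response = nm,
                     term = names(reference[[nm]]$coefficients),
                     published = unname(reference[[nm]]$coefficients))
    })
    coefs <- dplyr::left_join(coefs, ref_tbl, by = c("response", "term"))
    dec <- decimals_printed(coefs$published)
    coefs$matches_published <- round(coefs$estimate, dec) == coefs$published
  }
  diags <- purrr::map_dfr(names(models),
                          function(nm) dplyr::mutate(glance(models[[nm]]),
                                                     response = nm, .before = 1))

  grid <- build_grid(factors)
  prob <- modr_probability(grid, models, rules, n_draws = n_draws, seed = seed,
                           method = method)
  modr <- extract_modr(prob)
  wp <- select_working_point(modr)

  structure(
    list(models = models, coefficients = coefs, diagnostics = diags,
         grid_size = nrow(grid), modr = modr, working_point = wp,
         rules = rules, seed = seed, n_draws = n_draws, method = method),
    class = "study_report"
  )
}

# number of decimals a printed value carries (vectorized)
decimals_printed <- function(x) {
  s <- vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE),
              character(1))
  nchar(sub("^[^.]*\\.?", "", s))
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Study report ==\n")
  cat(sprintf("Models fitted: %d | grid points: %d | MC draws: %d (%s, seed %d)\n",
              length(x$models), x$grid_size, x$n_draws, x$method, x$seed))
  if ("matches_published" %in% names(x$coefficients)) {
    cat(sprintf("Coefficients matching published values at printed precision: %d/%d\n",
                sum(x$coefficients$matches_published),
                nrow(x$coefficients)))
  }
  s <- summary(x$modr)
  cat(sprintf("MODR (threshold %.2f): %d/%d grid points (%.1f%%), %d interior\n",
              s$threshold, s$n_in_modr, s$n_grid, 100 * s$volume_fraction,
              s$n_interior))
  cat("Working point:\n")
  print(x$working_point)
  invisible(x)
}
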