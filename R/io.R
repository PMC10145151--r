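#' Read and write design tables as CSV
#'
#' The on-disk layout is one row per run with `run_id`, the coded
#' `<factor>_coded` columns and the natural-unit factor columns, decimal
#' point, header row mandatory. `read_design_csv()` re-attaches the factor
#' definitions so the result feeds straight into fitting and gridding.
#'
#' @param design A design table from [build_ccd()] (or [fa_ccd_data()]).
#' @param path File path.
#' @param factors Factor list to re-attach on read.
#' @return `write_design_csv()` returns `path` invisibly; `read_design_csv()`
#'   returns the design tibble.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, factors) {
  out <- tibble::as_tibble(utils::read.csv(path))
  attr(out, "factors") <- factors
  out
}

#' Serialize fitted response-surface models to JSON
#'
#' Stores, per model: response, transform, terms, coefficients, standard
#' errors, the full coefficient covariance, residual scale and degrees of
#' freedom, diagnostics and the factor definitions — everything the Monte
#' Carlo MODR stage needs. `read_models_json()` reconstructs working
#' `rsm_fit` objects (prediction and simulation work; run-level quantities
#' such as residuals are not round-tripped).
#'
#' @param models Named list of [fit_rsm()] objects.
#' @param path File path.
#' @return `write_models_json()` returns `path` invisibly;
#'   `read_models_json()` returns the named model list.
#' @export
write_models_json <- function(models, path) {
  stopifnot(!is.null(names(models)), all(vapply(models, inherits, TRUE, "rsm_fit")))
  payload <- lapply(models, function(m) {
    list(
      response = m$response, transform = m$transform, terms = m$terms,
      coefficients = unname(m$coefficients),
      std_errors = unname(m$std_errors),
      vcov = m$vcov, sigma = m$sigma, df_residual = m$df_residual, n = m$n,
      diagnostics = as.list(m$diagnostics),
      factors = lapply(m$factors, unclass)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(m) {
    fl <- m$factors
    if (is.data.frame(fl)) fl <- split(fl, seq_len(nrow(fl)))
    factors <- unname(lapply(fl, function(f) {
      gs <- f$grid_step
      if (is.null(gs) || is.na(gs)) gs <- NA_real_
      factor_spec(f$name, f$low, f$high, f$units, grid_step = gs)
    }))
    vc <- matrix(unlist(m$vcov), nrow = length(m$terms),
                 dimnames = list(m$terms, m$terms))
    structure(
      list(response = m$response, transform = m$transform, terms = m$terms,
           coefficients = setNames(m$coefficients, m$terms),
           std_errors = setNames(m$std_errors, m$terms),
           vcov = vc, sigma = m$sigma, df_residual = m$df_residual, n = m$n,
           diagnostics = tibble::as_tibble(m$diagnostics),
           factors = factors),
      class = "rsm_fit"
    )
  })
  setNames(out, names(payload))
}

#' Write a MODR probability map as long-format CSV
#'
#' One row per grid point: the natural-unit factor columns, `probability` and
#' (for [extract_modr()] results) `in_modr` and `zone`.
#'
#' @param modr A probability table or `modr_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_modr_csv <- function(modr, path) {
  utils::write.csv(as.data.frame(modr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
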