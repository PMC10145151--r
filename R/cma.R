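#' Baseline-separation criterion between two consecutive peaks
#'
#' The separation criterion is the start time of the later peak minus the end
#' time of the earlier one: positive values mean baseline separation, zero a
#' touching pair and negative values overlap. It avoids the peak-shape
#' assumptions baked into resolution or peak-capacity measures, which is why
#' it is the preferred attribute for gradient separations of homologous
#' analytes.
#'
#' @param t1_end End time of the earlier peak (minutes).
#' @param t2_start Start time of the later peak (minutes). Vectors recycle as
#'   usual.
#' @return `t2_start - t1_end` in minutes.
#' @examples
#' separation_criterion(4.84, 4.94) # 0.10
#' @export
separation_criterion <- function(t1_end, t2_start) {
  t2_start - t1_end
}

#' Mobile-phase composition at elution under a linear gradient
#'
#' For a linear gradient running from `phi_i` to `phi_f` percent organic over
#' `t_grad` minutes, delayed by the dwell time `t_dwell`, the organic content
#' experienced by an analyte eluting at `t_r` is
#' `phi_i + (phi_f - phi_i) / t_grad * (t_r - t_dwell)`.
#' Retention times outside the gradient window are an error, never clamped:
#' the calculation is only meaningful for within-gradient elution.
#'
#' @param t_r Retention time(s), minutes.
#' @param phi_i,phi_f Organic percentage at gradient start and end
#'   (`phi_f >= phi_i`).
#' @param t_grad Gradient duration, minutes (> 0).
#' @param t_dwell Dwell time, minutes (>= 0): the delay between gradient
#'   formation at the pump and its arrival at the column head.
#' @return Organic percentage at elution, same length as `t_r`.
#' @examples
#' gradient_composition(4.94, phi_i = 65, phi_f = 85, t_grad = 15, t_dwell = 1.37)
#' @export
gradient_composition <- function(t_r, phi_i, phi_f, t_grad, t_dwell = 0) {
  if (t_grad <= 0) abort("`t_grad` must be positive.")
  if (t_dwell < 0) abort("`t_dwell` must be non-negative.")
  if (phi_f < phi_i) abort("`phi_f` must be at least `phi_i`.")
  bad <- t_r < t_dwell | t_r > t_dwell + t_grad
  if (any(bad)) {
    abort(sprintf(
      "Retention time(s) %s fall outside the gradient window [%g, %g] min.",
      paste(format(t_r[bad]), collapse = ", "), t_dwell, t_dwell + t_grad))
  }
  phi_i + (phi_f - phi_i) / t_grad * (t_r - t_dwell)
}

#' Rescale a dwell time to a different flow rate
#'
#' The dwell volume is a property of the instrument plumbing, so the dwell
#' time scales inversely with flow rate. Provided as a helper for transferring
#' gradient calculations between flow settings; the packaged study quotes its
#' dwell time at a single flow and uses it as a constant.
#'
#' @param t_dwell Dwell time (minutes) measured at `flow_ref`.
#' @param flow_ref,flow Reference and target flow rates (same units).
#' @return Dwell time at `flow`, minutes.
#' @export
rescale_dwell_time <- function(t_dwell, flow_ref, flow) {
  stopifnot(flow_ref > 0, flow > 0)
  t_dwell * flow_ref / flow
}

#' Acceptance rules on critical method attributes
#'
#' A rule set is a table of one-sided requirements on named CMAs, plus the
#' probability with which they must jointly hold for a factor setting to
#' belong to the MODR.
#'
#' @param cma Character vector of CMA names. `"s12"` and `"s67"` are derived
#'   separation criteria (later-peak start minus earlier-peak end for the two
#'   critical pairs); any other name must match a fitted model's response.
#' @param comparator `"<"` or `">"` per rule.
#' @param bound Numeric bound per rule.
#' @param probability_threshold Joint-satisfaction probability defining the
#'   MODR, in (0, 1).
#' @return A tibble of rules with the threshold stored as an attribute.
#' @examples
#' fa_cma_rules()
#' @export
cma_rules <- function(cma, comparator, bound, probability_threshold = 0.90) {
  stopifnot(length(cma) >= 1, length(cma) == length(comparator),
            length(cma) == length(bound))
  if (!all(comparator %in% c("<", ">"))) abort("Comparators must be '<' or '>'.")
  if (probability_threshold <= 0 || probability_threshold >= 1) {
    abort("`probability_threshold` must lie strictly between 0 and 1.")
  }
  out <- tibble::tibble(cma = cma, comparator = comparator, bound = as.numeric(bound))
  attr(out, "probability_threshold") <- probability_threshold
  class(out) <- c("cma_rules", class(out))
  out
}

# CMA matrices from back-transformed model predictions. `preds` is a named
# list of numeric matrices/vectors on the measurement scale.
derive_cmas <- function(preds, cma_names) {
  need_pair <- function(a, b, label) {
    if (is.null(preds[[a]]) || is.null(preds[[b]])) {
      abort(sprintf("CMA '%s' needs models '%s' and '%s'.", label, a, b))
    }
  }
  out <- list()
  for (nm in cma_names) {
    out[[nm]] <- switch(nm,
      s12 = { need_pair("t1_end", "t2_start", "s12"); preds$t2_start - preds$t1_end },
      s67 = { need_pair("t6_end", "t7_start", "s67"); preds$t7_start - preds$t6_end },
      {
        if (is.null(preds[[nm]])) {
          abort(sprintf("CMA '%s' matches no fitted model response.", nm))
        }
        preds[[nm]]
      })
  }
  out
}

#' Predict critical method attributes at factor settings
#'
#' Evaluates each fitted model at the given natural-unit settings,
#' back-transforms onto the measurement scale and derives the separation
#' criteria from the predicted peak-boundary times. A warning is raised when
#' any coded coordinate exceeds 1.5 in magnitude (extrapolation well outside
#' the design region).
#'
#' @param newdata Data frame with the natural-unit factor columns.
#' @param models Named list of [fit_rsm()] objects. Separation criteria
#'   `s12`/`s67` are derived when the `t1_end`/`t2_start` and
#'   `t6_end`/`t7_start` models are present.
#' @return `newdata` with one prediction column per model plus any derivable
#'   `s12`/`s67` columns.
#' @examples
#' models <- fit_fa_models()
#' predict_cmas(tibble::tibble(flow = 0.575, tgrad = 14.2, temp = 33), models)
#' @export
predict_cmas <- function(newdata, models) {
  stopifnot(length(models) >= 1, !is.null(names(models)),
            all(vapply(models, inherits, TRUE, "rsm_fit")))
  factors <- models[[1]]$factors
  coded <- coded_matrix(newdata, factors)
  if (any(abs(coded) > 1.5)) {
    warn("Some settings are far outside the design region (|coded| > 1.5); predictions are extrapolations.")
  }
  preds <- lapply(models, predict, newdata = newdata)
  out <- tibble::as_tibble(newdata)
  for (nm in names(preds)) out[[nm]] <- preds[[nm]]
  if (all(c("t1_end", "t2_start") %in% names(preds))) {
    out$s12 <- separation_criterion(preds$t1_end, preds$t2_start)
  }
  if (all(c("t6_end", "t7_start") %in% names(preds))) {
    out$s67 <- separation_criterion(preds$t6_end, preds$t7_start)
  }
  out
}
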