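#' Model-term vocabulary for response-surface polynomials
#'
#' Terms are written in a small coded-factor language: `"1"` (intercept),
#' `"x1"`, `"x2"`, ... (linear), `"x1:x3"` (two-factor interaction, lower
#' index first) and `"x2^2"` (pure quadratic). Index `i` in `xi` refers to the
#' i-th entry of the `factors` list passed alongside the data.
#'
#' @param k Number of factors.
#' @return Character vector of terms.
#' @examples
#' full_quadratic_terms(3)
#' @export
full_quadratic_terms <- function(k = 3) {
  lin <- paste0("x", seq_len(k))
  inter <- if (k >= 2) {
    cmb <- utils::combn(k, 2)
    paste0("x", cmb[1, ], ":x", cmb[2, ])
  } else character()
  quad <- paste0("x", seq_len(k), "^2")
  c("1", lin, inter, quad)
}

# Build the model matrix for a coded matrix (columns x1..xk) and a term set.
rsm_model_matrix <- function(coded, terms) {
  k <- ncol(coded)
  cols <- lapply(terms, function(tm) {
    if (tm == "1") return(rep(1, nrow(coded)))
    if (grepl("^x[0-9]+$", tm)) {
      i <- as.integer(sub("x", "", tm))
      if (i > k) abort(sprintf("Term '%s' refers to a missing factor.", tm))
      return(coded[, i])
    }
    if (grepl("^x[0-9]+:x[0-9]+$", tm)) {
      ij <- as.integer(strsplit(gsub("x", "", tm), ":")[[1]])
      if (any(ij > k)) abort(sprintf("Term '%s' refers to a missing factor.", tm))
      return(coded[, ij[1]] * coded[, ij[2]])
    }
    if (grepl("^x[0-9]+\\^2$", tm)) {
      i <- as.integer(sub("\\^2$", "", sub("x", "", tm)))
      if (i > k) abort(sprintf("Term '%s' refers to a missing factor.", tm))
      return(coded[, i]^2)
    }
    abort(sprintf("Unknown model term '%s'.", tm))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Fit a transformed reduced polynomial response-surface model
#'
#' Ordinary least squares of the transformed response on the coded-factor
#' model matrix. Coefficients live on the coded basis: prediction at natural
#' settings always goes through the factor coding, so the fitted surface is
#' invariant to the units the factors are recorded in. Standard errors come
#' from the residual variance times the diagonal of the inverse normal matrix,
#' and the full coefficient covariance is retained for Monte Carlo error
#' propagation.
#'
#' Diagnostics are computed at fit time: R-squared, adjusted and
#' PRESS-predicted R-squared (leave-one-out residuals `e_i / (1 - h_ii)`), and
#' the lack-of-fit F-test against pure error from replicated runs (runs are
#' replicates iff their coded settings are identical; without replicates the
#' lack-of-fit p-value is `NA`).
#'
#' @param data Data frame holding the natural-unit factor columns and the
#'   response column.
#' @param response Name of the response column.
#' @param factors List of [factor_spec()] (order defines `x1`, `x2`, ...).
#' @param terms Character vector of model terms, see [full_quadratic_terms()].
#'   The intercept `"1"` is added if absent.
#' @param transform Response transform, see [apply_transform()].
#' @return An object of class `rsm_fit`. Use [tidy()] for the coefficient
#'   table, [glance()] for diagnostics and [predict()][predict.rsm_fit] for
#'   new settings.
#' @examples
#' fit <- fit_rsm(fa_ccd_data(), "k_last", fa_factors(),
#'                terms = c("1", "x1", "x2", "x3", "x2:x3", "x2^2"))
#' tidy(fit)
#' glance(fit)
#' @export
fit_rsm <- function(data, response, factors,
                    terms = full_quadratic_terms(length(factors)),
                    transform = "identity") {
  y <- data[[response]]
  if (is.null(y)) abort(sprintf("Response column '%s' not found.", response))
  if (!"1" %in% terms) terms <- c("1", terms)
  coded <- coded_matrix(data, factors)
  X <- rsm_model_matrix(coded, terms)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1) abort("Need at least one more run than model terms.")

  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, p)]]
    abort(paste0("Model matrix is rank deficient; collinear term(s): ",
                 paste(bad, collapse = ", ")))
  }

  z <- apply_transform(y, transform)
  b <- qr.coef(qx, z)
  res <- z - drop(X %*% b)
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  XtXi <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  vc <- sigma2 * XtXi
  dimnames(vc) <- list(terms, terms)
  se <- sqrt(diag(vc))
  h <- rowSums((X %*% XtXi) * X)

  fit <- structure(
    list(response = response, transform = transform, terms = terms,
         coefficients = setNames(as.numeric(b), terms),
         std_errors = setNames(se, terms), vcov = vc,
         sigma = sqrt(sigma2), df_residual = df_res, n = n,
         fitted_transformed = drop(X %*% b), residuals = res, leverage = h,
         factors = factors, coded = coded, y = y),
    class = "rsm_fit"
  )
  fit$diagnostics <- rsm_diagnostics(fit)
  fit
}

#' Model-quality diagnostics of a fitted response surface
#'
#' @param fit An [fit_rsm()] object.
#' @return A one-row tibble with `r_squared`, `adj_r_squared`,
#'   `pred_r_squared`, `press`, `lack_of_fit_p`, `sigma`, `df_residual` and
#'   `nobs`. `lack_of_fit_p` is `NA` when the design has no replicated runs.
#' @export
rsm_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  z <- apply_transform(fit$y, fit$transform)
  n <- fit$n; p <- length(fit$terms)
  ss_tot <- sum((z - mean(z))^2)
  ss_res <- sum(fit$residuals^2)
  press <- sum((fit$residuals / (1 - fit$leverage))^2)

  # pure error from replicate groups: identical coded settings
  grp <- apply(fit$coded, 1, paste, collapse = "/")
  has_reps <- anyDuplicated(grp) > 0
  lof_p <- NA_real_
  if (has_reps && n - p > 0) {
    ss_pe <- sum(tapply(z, grp, function(v) sum((v - mean(v))^2)))
    df_pe <- n - length(unique(grp))
    df_lof <- (n - p) - df_pe
    if (df_lof > 0 && ss_pe > 0) {
      f_lof <- ((ss_res - ss_pe) / df_lof) / (ss_pe / df_pe)
      lof_p <- pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    }
  }

  tibble::tibble(
    r_squared = 1 - ss_res / ss_tot,
    adj_r_squared = 1 - (ss_res / (n - p)) / (ss_tot / (n - 1)),
    pred_r_squared = 1 - press / ss_tot,
    press = press,
    lack_of_fit_p = lof_p,
    sigma = fit$sigma,
    df_residual = fit$df_residual,
    nobs = n
  )
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("<rsm_fit> %s (%s transform), %d terms, %d runs\n",
              x$response, x$transform, length(x$terms), x$n))
  print(tidy(x))
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' Tidy the coefficient table of a response-surface fit
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`; estimates are on the transformed-response, coded-factor scale.
#' @export
tidy.rsm_fit <- function(x, ...) {
  stat <- x$coefficients / x$std_errors
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(stat),
    p.value = unname(2 * pt(-abs(stat), x$df_residual))
  )
}

#' One-row model summary of a response-surface fit
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return The diagnostics tibble of [rsm_diagnostics()].
#' @export
glance.rsm_fit <- function(x, ...) x$diagnostics

#' Predict from a response-surface fit at new factor settings
#'
#' @param object An `rsm_fit`.
#' @param newdata Data frame with the natural-unit factor columns.
#' @param type `"response"` back-transforms onto the measurement scale;
#'   `"transformed"` stays on the modeling scale.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata,
                            type = c("response", "transformed"), ...) {
  type <- match.arg(type)
  X <- rsm_model_matrix(coded_matrix(newdata, object$factors), object$terms)
  z <- as.vector(X %*% object$coefficients)
  if (type == "transformed") z else inverse_transform(z, object$transform)
}

#' Observed-versus-fitted display for a response-surface fit
#'
#' @param object An `rsm_fit`.
#' @param ... Unused.
#' @return A ggplot object on the transformed-response scale.
#' @export
autoplot.rsm_fit <- function(object, ...) {
  d <- tibble::tibble(
    fitted = object$fitted_transformed,
    observed = apply_transform(object$y, object$transform)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("Fitted (%s scale)", object$transform),
      y = sprintf("Observed (%s scale)", object$transform),
      title = sprintf("Response surface fit: %s", object$response)
    )
}

#' Backward elimination of uninformative polynomial terms
#'
#' Starting from the full quadratic, repeatedly drops the non-intercept term
#' with the largest coefficient p-value above `alpha`, honoring model
#' hierarchy: a linear term is retained while any surviving interaction or
#' quadratic involves its factor. This is a convenience for new studies; the
#' packaged study reproduction uses the fixed published term sets.
#'
#' @inheritParams fit_rsm
#' @param alpha Retention threshold on coefficient p-values.
#' @return Character vector of surviving terms (including `"1"`).
#' @export
backward_eliminate <- function(data, response, factors, transform = "identity",
                               alpha = 0.05,
                               terms = full_quadratic_terms(length(factors))) {
  terms <- unique(c("1", terms))
  repeat {
    fit <- fit_rsm(data, response, factors, terms = terms, transform = transform)
    tt <- tidy(fit)
    tt <- tt[tt$term != "1", , drop = FALSE]

    removable <- vapply(tt$term, function(tm) {
      if (grepl("^x[0-9]+$", tm)) {
        i <- sub("x", "", tm)
        higher <- grepl(paste0("(^|:)x", i, "(:|\\^2|$)"), setdiff(terms, c("1", tm)))
        !any(higher & grepl("[:^]", setdiff(terms, c("1", tm))))
      } else TRUE
    }, logical(1))

    cand <- tt[removable & tt$p.value > alpha, , drop = FALSE]
    if (nrow(cand) == 0) return(terms)
    drop_term <- cand$term[which.max(cand$p.value)]
    terms <- setdiff(terms, drop_term)
  }
}
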