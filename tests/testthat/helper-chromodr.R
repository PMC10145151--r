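# Shared fixtures and independent oracles for the test suite.

toy_factors <- function() {
  list(
    factor_spec("a", 0, 10, "u", grid_step = 1),
    factor_spec("b", -1, 1, "u", grid_step = 0.5),
    factor_spec("c", 100, 200, "u", grid_step = 25)
  )
}

# Brute-force normal-equations OLS, independent of the package's QR path.
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# Evaluate a coded-term polynomial by hand (term language mirror).
eval_terms_by_hand <- function(coefs, x) {
  tot <- 0
  for (nm in names(coefs)) {
    v <- if (nm == "1") 1
    else if (grepl("\\^2$", nm)) x[as.integer(sub("x([0-9]+)\\^2", "\\1", nm))]^2
    else if (grepl(":", nm)) {
      ij <- as.integer(strsplit(gsub("x", "", nm), ":")[[1]])
      x[ij[1]] * x[ij[2]]
    } else x[as.integer(sub("x", "", nm))]
    tot <- tot + coefs[[nm]] * v
  }
  tot
}

# Published diagnostics of the retention-factor model, at printed precision.
published_k_last_diagnostics <- function() {
  c(r_squared = 0.9902, adj_r_squared = 0.9861,
    pred_r_squared = 0.9805, lack_of_fit_p = 0.9718)
}
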