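#' Fit a first-level GLM with AR(1) prewhitening
#'
#' Ordinary least squares, followed by estimation of a single global AR(1)
#' coefficient per signal from the lag-1 autocorrelation of the OLS
#' residuals (computed within runs), prewhitening of both sides of the
#' model, and one refit (a single Cochrane-Orcutt iteration). Rank
#' deficiency is reported with the names of the collinear columns.
#'
#' @param design a `design_matrix`.
#' @param series a `bold_series`, or a numeric matrix (volumes x signals).
#' @param prewhiten apply the AR(1) correction (default TRUE).
#' @return an object of class `glm_fit`: `coefficients` (regressors x
#'   signals), `se`, `vcov` (list per signal), `sigma2`, `ar1`,
#'   `df_residual`, and the design's `col_info`.
#' @export
fit_glm <- function(design, series, prewhiten = TRUE) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- if (inherits(series, "bold_series")) series$data else as.matrix(series)
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop_rtbold("series has ", nrow(Y), " volumes but design has ",
                nrow(X), class = "rtbold_design_error")
  qrx <- qr(X, LAPACK = FALSE)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_rtbold("design is rank deficient; collinear columns: ",
                paste(bad, collapse = ", "),
                class = "rtbold_design_error")
  }
  runs <- design$run
  n <- nrow(X); p <- ncol(X)
  fit_one <- function(y) {
    beta0 <- qr.coef(qrx, y)
    resid0 <- y - X %*% beta0
    # lag-1 autocorrelation pooled within runs
    num <- 0; den <- sum(resid0^2)
    for (r in unique(runs)) {
      e <- resid0[runs == r]
      if (length(e) > 1) num <- num + sum(e[-1] * e[-length(e)])
    }
    rho <- if (den > 0) num / den else 0
    rho <- max(min(rho, 0.99), -0.99)
    if (!prewhiten || rho == 0) {
      Xw <- X; yw <- y
    } else {
      Xw <- X; yw <- y
      for (r in unique(runs)) {
        rows <- which(runs == r)
        first <- rows[1]
        if (length(rows) > 1) {
          lag <- rows[-length(rows)]
          cur <- rows[-1]
          Xw[cur, ] <- X[cur, ] - rho * X[lag, ]
          yw[cur] <- y[cur] - rho * y[lag]
        }
        Xw[first, ] <- sqrt(1 - rho^2) * X[first, ]
        yw[first] <- sqrt(1 - rho^2) * y[first]
      }
    }
    qw <- qr(Xw)
    beta <- qr.coef(qw, yw)
    rw <- yw - Xw %*% beta
    df <- n - p
    sigma2 <- sum(rw^2) / df
    XtXinv <- chol2inv(qr.R(qw))
    piv <- order(qw$pivot)
    XtXinv <- XtXinv[piv, piv, drop = FALSE]
    list(beta = beta, vcov = sigma2 * XtXinv, sigma2 = sigma2, ar1 = rho)
  }
  fits <- lapply(seq_len(ncol(Y)), function(s) fit_one(Y[, s]))
  coefs <- vapply(fits, function(f) as.numeric(f$beta), numeric(p))
  coefs <- matrix(coefs, nrow = p,
                  dimnames = list(colnames(X), colnames(Y)))
  ses <- vapply(fits, function(f) sqrt(pmax(diag(f$vcov), 0)), numeric(p))
  ses <- matrix(ses, nrow = p, dimnames = dimnames(coefs))
  vcovs <- lapply(fits, function(f) {
    v <- f$vcov; dimnames(v) <- list(colnames(X), colnames(X)); v
  })
  structure(list(coefficients = coefs, se = ses, vcov = vcovs,
                 sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
                 ar1 = vapply(fits, `[[`, numeric(1), "ar1"),
                 df_residual = n - p, col_info = design$col_info),
            class = "glm_fit")
}

#' Extract a named coefficient from a GLM fit
#' @param fit a `glm_fit`.
#' @param name regressor name.
#' @param signal signal column (index or name), default 1.
#' @return the coefficient estimate.
#' @export
coef_of <- function(fit, name, signal = 1) {
  if (!name %in% rownames(fit$coefficients))
    stop_rtbold("no coefficient named '", name, "' in fit",
                class = "rtbold_contrast_error")
  fit$coefficients[name, signal]
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("First-level GLM fit:", nrow(x$coefficients), "regressors x",
      ncol(x$coefficients), "signal(s)\n")
  cat("  AR(1) estimate(s):", paste(round(x$ar1, 3), collapse = ", "), "\n")
  cat("  residual df:", x$df_residual, "\n")
  invisible(x)
}
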