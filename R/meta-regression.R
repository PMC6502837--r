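# Random-effects meta-regression of quantile effects on q and q^2 -----------
#
# Second stage of CQR-MR: the per-quantile effect estimates y_q with
# sampling variances se_q^2 are modelled as
#     y_q = beta0 + beta1 * q + beta2 * q^2 + u_q + e_q,
# u_q ~ N(0, tau2) between-quantile heterogeneity, e_q ~ N(0, se_q^2).
# tau2 is estimated by REML (Fisher scoring); fixed effects by weighted
# least squares with weights 1/(se_q^2 + tau2); Wald z tests per
# coefficient.  Estimates at different quantiles of the same sample are
# treated as independent (deliberately -- the resulting type-I inflation is
# corrected empirically by genomic control, see the calibration module).

# restricted log-likelihood for given tau2 (used internally and by tests)
reml_loglik <- function(tau2, y, X, v) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, X * w)
  b <- solve(XtWX, crossprod(X, y * w))
  r <- y - X %*% b
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX)$modulus[1] +
            sum(w * r^2))
}

# DerSimonian-Laird moment estimator (fallback when REML fails to converge)
tau2_dl <- function(y, X, v) {
  w <- 1 / v
  XtWX <- crossprod(X, X * w)
  b <- solve(XtWX, crossprod(X, y * w))
  Q <- sum(w * (y - X %*% b)^2)
  P_trace <- sum(w) - sum(diag(solve(XtWX, crossprod(X * w, X * w))))
  max(0, (Q - (length(y) - ncol(X))) / P_trace)
}

# REML estimate of tau2 by Fisher scoring on the restricted likelihood
tau2_reml <- function(y, X, v, max_iter = 100L, tol = 1e-8) {
  k <- length(y); p <- ncol(X)
  tau2 <- max(0, var(as.numeric(y)) - mean(v))
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    Xw <- X * w
    XtWX_inv <- solve(crossprod(X, Xw))
    # P = W - W X (X'WX)^-1 X'W  (k x k; k is the grid size, tiny)
    P <- diag(w, k) - Xw %*% XtWX_inv %*% t(Xw)
    Py <- P %*% y
    score <- -0.5 * sum(diag(P)) + 0.5 * sum(Py^2)
    info <- 0.5 * sum(P * P)
    step <- score / info
    tau2_new <- max(0, tau2 + step)
    if (abs(tau2_new - tau2) <= tol * (1 + tau2)) {
      return(list(tau2 = tau2_new, converged = TRUE, iterations = i))
    }
    tau2 <- tau2_new
  }
  list(tau2 = tau2, converged = FALSE, iterations = max_iter)
}

#' Meta-regression of quantile effects on quantile and quantile-squared
#'
#' @param effects A `quantile_effects` table from [fit_cqr()] (columns `q`,
#'   `beta`, `se`), or any data frame with those columns.
#' @param method `"REML"` (default; DerSimonian-Laird fallback on
#'   non-convergence) or `"FE"` (tau2 fixed at 0).
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `metareg_result` with fields `variant_id`,
#'   `coef` (beta0/beta1/beta2), `se`, `ci_low`, `ci_high`, `z`, `p`,
#'   `vcov`, `tau2`, `tau2_method`, `corrected` (genomic-control flag,
#'   `FALSE` here), `lambda` (`NULL` until corrected).  `beta0` is the
#'   extrapolated effect at q = 0, not the marginal (OLS) effect.
#' @export
fit_meta_regression <- function(effects, method = c("REML", "FE"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  if (!all(c("q", "beta", "se") %in% names(effects)))
    stop_cqrmr("effects must have columns q, beta, se",
               "cqrmr_validation_error")
  q <- as.numeric(effects$q); y <- as.numeric(effects$beta)
  v <- as.numeric(effects$se)^2
  if (length(q) < 4L)
    stop_cqrmr("need at least 4 quantile records (3 coefficients + tau2)",
               "cqrmr_validation_error")
  if (any(!is.finite(v)) || any(v <= 0))
    stop_cqrmr("all se must be positive and finite", "cqrmr_validation_error")
  X <- cbind(1, q, q^2)
  colnames(X) <- c("beta0", "beta1", "beta2")

  if (method == "FE") {
    tau2 <- 0; tau2_method <- "FE"
  } else {
    fit <- tau2_reml(y, X, v)
    if (fit$converged) {
      tau2 <- fit$tau2; tau2_method <- "REML"
    } else {
      tau2 <- tau2_dl(y, X, v); tau2_method <- "DL"
    }
  }
  w <- 1 / (v + tau2)
  V <- solve(crossprod(X, X * w))
  b <- drop(V %*% crossprod(X, y * w))
  se <- sqrt(diag(V))
  z <- b / se
  crit <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    variant_id = attr(effects, "variant_id") %||%
      (if ("variant_id" %in% names(effects)) effects$variant_id[1] else NA),
    coef = setNames(b, colnames(X)),
    se = setNames(se, colnames(X)),
    ci_low = setNames(b - crit * se, colnames(X)),
    ci_high = setNames(b + crit * se, colnames(X)),
    z = setNames(z, colnames(X)),
    p = setNames(2 * pnorm(-abs(z)), colnames(X)),
    vcov = V, tau2 = tau2, tau2_method = tau2_method,
    conf_level = conf_level, k = length(q),
    corrected = FALSE, lambda = NULL), class = "metareg_result")
}

#' @export
print.metareg_result <- function(x, ...) {
  cat(sprintf("CQR meta-regression (%s, tau2 = %.4g%s)\n", x$tau2_method,
              x$tau2, if (x$corrected) ", genomic-control corrected" else ""))
  tab <- data.frame(beta = x$coef, se = x$se, ci_low = x$ci_low,
                    ci_high = x$ci_high, z = x$z, p = signif(x$p, 3))
  print(tab, ...)
  invisible(x)
}

#' Predicted effect-size profile with delta-method confidence band
#'
#' @param res A `metareg_result`.
#' @param grid A [quantile_grid()] (or numeric quantiles) to predict at.
#' @return `data.frame` with `q`, `fit`, `se`, `ci_low`, `ci_high`.
#' @export
predict_profile <- function(res, grid = quantile_grid()) {
  stopifnot(inherits(res, "metareg_result"))
  q <- as.numeric(grid)
  X0 <- cbind(1, q, q^2)
  fit <- drop(X0 %*% res$coef)
  se <- sqrt(rowSums((X0 %*% res$vcov) * X0))
  crit <- qnorm(1 - (1 - res$conf_level) / 2)
  data.frame(q = q, fit = fit, se = se,
             ci_low = fit - crit * se, ci_high = fit + crit * se)
}

#' Family-wise Bonferroni threshold for non-uniformity tests
#'
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param n_variants Number of variants tested.
#' @param n_coef Coefficients tested per variant (default 3).
#' @return The per-test threshold `alpha_family / (n_coef * n_variants)`.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_variants,
                                 n_coef = 3L) {
  stopifnot(alpha_family > 0, n_variants >= 1, n_coef >= 1)
  alpha_family / (n_coef * n_variants)
}

#' Classify a variant's quantile-effect profile
#'
#' Non-uniformity is carried by the linear and quadratic coefficients:
#' `bonferroni_significant` if min(p1, p2) clears the family-wise threshold
#' `alpha_family / (n_coef * n_variants)`, `nominal` if min(p1, p2) < 0.05,
#' else `uniform`.
#'
#' @param res A `metareg_result` (corrected p-values expected when genomic
#'   control is in use).
#' @param alpha_family Family-wise alpha.
#' @param n_variants Number of variants in the family.
#' @param n_coef Bonferroni divisor per variant (default 3, counting all
#'   three coefficients).
#' @return One of `"bonferroni_significant"`, `"nominal"`, `"uniform"`.
#' @export
classify_uniformity <- function(res, alpha_family = 0.05, n_variants,
                                n_coef = 3L) {
  stopifnot(inherits(res, "metareg_result"))
  p12 <- res$p[c("beta1", "beta2")]
  if (any(is.na(p12)))
    stop_cqrmr("missing p-values for beta1/beta2", "cqrmr_validation_error")
  thr <- bonferroni_threshold(alpha_family, n_variants, n_coef)
  if (min(p12) < thr) "bonferroni_significant"
  else if (min(p12) < 0.05) "nominal"
  else "uniform"
}

#' Tabulate meta-regression results across variants
#'
#' One row per variant mirroring the summary-table schema: per-coefficient
#' estimate, CI and p, plus tau2 and the correction flag.
#'
#' @param results List of `metareg_result` objects.
#' @return A `data.frame`.
#' @export
metareg_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(variant_id = r$variant_id,
               beta0 = r$coef[1], ci0_low = r$ci_low[1],
               ci0_high = r$ci_high[1], p0 = r$p[1],
               beta1 = r$coef[2], ci1_low = r$ci_low[2],
               ci1_high = r$ci_high[2], p1 = r$p[2],
               beta2 = r$coef[3], ci2_low = r$ci_low[3],
               ci2_high = r$ci_high[3], p2 = r$p[3],
               tau2 = r$tau2, corrected = r$corrected,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
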