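#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d species; lambda = %.4g%s; AICc = %.4g; R^2 = %.4g\n",
              x$n, x$lambda, if (x$lambda_ml) " (ML)" else " (fixed)",
              x$aicc, x$r_squared))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summarize a fitted phylogenetic regression
#'
#' @param object A [pgls()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.pgls"` carrying the coefficient
#'   table (estimate, s.e., t value, two-sided p), lambda, sigma2, logLik,
#'   AICc and R^2.
#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `s.e.` = object$se,
               `t value` = object$t_value,
               `Pr(>|t|)` = object$p_value)
  structure(list(call = object$call, formula = object$formula,
                 coefficients = tab, lambda = object$lambda,
                 lambda_ml = object$lambda_ml, sigma2 = object$sigma2,
                 logLik = object$logLik, aicc = object$aicc,
                 r_squared = object$r_squared, n = object$n, k = object$k),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nlambda = %.4g%s   sigma2 (ML) = %.4g\n",
              x$lambda, if (x$lambda_ml) " (ML)" else " (fixed)", x$sigma2))
  cat(sprintf("n = %d   logLik = %.4f   AICc = %.4f   R^2 = %.4f\n",
              x$n, x$logLik, x$aicc, x$r_squared))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' Residuals of a phylogenetic regression
#'
#' Response-scale residuals `y - X beta` named by species. For the null
#' bone-scaling model these are the bone thickness index (see
#' [compute_bti()]).
#'
#' @param object A [pgls()] fit.
#' @param ... Unused.
#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' Predict from a phylogenetic regression
#'
#' Population-level predictions `X_new beta` (no phylogenetic conditioning
#' on observed residuals).
#'
#' @param object A [pgls()] fit.
#' @param newdata Data frame with the model's predictor columns; omitted,
#'   the fitted values are returned.
#' @param ... Unused.
#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- delete.response(object$terms)
  mf <- model.frame(tt, data = as.data.frame(newdata), na.action = na.omit)
  X <- model.matrix(tt, mf)
  colnames(X) <- sub("TRUE$", "_TRUE", colnames(X))
  drop(X %*% object$coefficients)
}

#' Simulate responses from a fitted phylogenetic regression
#'
#' Draws `X beta + e` with `e ~ N(0, sigma2 * C(lambda))` on the fitted
#' tree, using the ML `sigma2` and the fitted `lambda`.
#'
#' @param object A [pgls()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame (`n` rows, `nsim` columns), rows named by species.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_covariance(object$tree, object$species)
  L <- chol(object$sigma2 * lambda_transform(C, object$lambda))
  n <- object$n
  out <- vapply(seq_len(nsim),
                function(i) object$fitted + drop(t(L) %*% rnorm(n)),
                numeric(n))
  out <- as.data.frame(out, row.names = object$species)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plot for a phylogenetic regression
#'
#' Observed versus fitted response with the 1:1 line; point symbols can be
#' mapped to a logical grouping column (e.g. diving) via `group`.
#'
#' @param x A [pgls()] fit.
#' @param group Optional logical vector (length `n`, in species order)
#'   controlling plotting symbols.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pgls <- function(x, group = NULL, ...) {
  pch <- if (is.null(group)) 19 else ifelse(group, 17, 19)
  graphics::plot(x$fitted, x$fitted + x$residuals, pch = pch,
                 xlab = "fitted", ylab = "observed",
                 main = deparse(x$formula), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
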