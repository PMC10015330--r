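#' Read a phylogeny and restrict it to a set of taxa
#'
#' Reads newick (from a file or a literal string), normalizes tip labels
#' (spaces become underscores), optionally prunes the tree to a required
#' taxon set, and validates ultrametricity. Missing taxa are a hard error
#' naming the offenders; a tree that is non-ultrametric beyond tolerance is
#' kept but flagged with a warning and the attribute `ultrametric = FALSE`.
#'
#' @param x Path to a newick file, or a newick string.
#' @param taxa Character vector of required tip labels, or `NULL` to keep
#'   all tips.
#' @param tol Relative ultrametricity tolerance, as a fraction of tree depth.
#' @return An `ape::phylo` tree.
#' @examples
#' tr <- read_phylogeny("((A:1,B:1):1,C:2);", taxa = c("A", "C"))
#' @export
read_phylogeny <- function(x, taxa = NULL, tol = 1e-6) {
  tr <- if (length(x) == 1L && !grepl("\\(", x) && file.exists(x)) {
    ape::read.tree(x)
  } else {
    ape::read.tree(text = x)
  }
  if (is.null(tr)) stop("could not parse newick input", call. = FALSE)
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  tr$tip.label <- gsub(" ", "_", tr$tip.label)
  if (!is.null(taxa)) {
    taxa <- gsub(" ", "_", taxa)
    missing <- setdiff(taxa, tr$tip.label)
    if (length(missing)) {
      stop("taxa missing from tree: ", paste(sort(missing), collapse = ", "),
           call. = FALSE)
    }
    tr <- ape::keep.tip(tr, taxa)
  }
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  ok <- diff(range(depths)) <= tol * max(depths)
  if (!ok) {
    warning("tree is not ultrametric within tolerance; PGLS assumes a ",
            "time-scaled ultrametric tree", call. = FALSE)
  }
  attr(tr, "ultrametric") <- ok
  tr
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`;
#' the diagonal holds root-to-tip depths. Rows/columns follow the requested
#' taxon order.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param taxa Tip ordering (default: the tree's own order). Must be a
#'   subset of the tips; the tree is pruned to it.
#' @return A symmetric positive semi-definite matrix with dimnames `taxa`.
#' @export
phylo_covariance <- function(tree, taxa = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(sort(missing), collapse = ", "),
         call. = FALSE)
  }
  if (length(taxa) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, taxa)
  }
  C <- ape::vcv.phylo(tree)
  C[taxa, taxa, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal untouched. `lambda = 1` returns `C` (pure Brownian motion);
#' `lambda = 0` gives a diagonal matrix (a star phylogeny, i.e. no
#' phylogenetic signal).
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Value in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single value in [0, 1]", call. = FALSE)
  }
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Core GLS solve against a fixed covariance matrix.
# beta = (X' C^-1 X)^-1 X' C^-1 y ; sigma2_ML = e' C^-1 e / n ;
# logLik = -(n/2) log(2 pi sigma2_ML) - log|C|/2 - n/2.
# Standard errors use the small-sample variance correction n/(n - p).
.gls_fit_core <- function(y, X, C) {
  n <- length(y)
  p <- ncol(X)
  U <- tryCatch(chol(C), error = function(e) {
    stop("covariance matrix is not positive definite: ", conditionMessage(e),
         call. = FALSE)
  })
  # whiten: C = U'U so solving t(U) z = v gives z = U^-T v
  yw <- forwardsolve(t(U), y)
  Xw <- forwardsolve(t(U), X)
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, yw)
  ew <- yw - Xw %*% beta
  rss <- sum(ew^2)
  sigma2_ml <- rss / n
  logdetC <- 2 * sum(log(diag(U)))
  loglik <- if (sigma2_ml < 1e-20) {
    Inf  # perfect fit: density degenerates
  } else {
    -0.5 * (n * log(2 * pi * sigma2_ml) + logdetC + n)
  }
  R <- qr.R(qrX)
  piv <- qrX$pivot
  XtX_inv <- matrix(0, p, p)
  XtX_inv[piv, piv] <- chol2inv(R)
  vcov_beta <- sigma2_ml * n / (n - p) * XtX_inv
  se <- sqrt(diag(vcov_beta))
  tval <- as.vector(beta) / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  resid <- as.vector(y - X %*% beta)
  list(coefficients = setNames(as.vector(beta), colnames(X)),
       se = setNames(se, colnames(X)),
       t_value = setNames(tval, colnames(X)),
       p_value = setNames(pval, colnames(X)),
       sigma2 = sigma2_ml, logLik = loglik, rss_gls = rss,
       residuals = resid, fitted = as.vector(X %*% beta),
       vcov = structure(vcov_beta, dimnames = list(colnames(X), colnames(X))),
       n = n, p = p)
}

#' Generalized least squares against an explicit covariance matrix
#'
#' Low-level fitting routine used by [pgls()]; exposed for direct use on a
#' response vector, design matrix and covariance matrix. Coefficients are
#' the GLS estimator; the residual variance is the maximum-likelihood
#' estimate, while standard errors, t and p values carry the `n/(n - p)`
#' small-sample variance correction with `n - p` degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (with intercept column if wanted).
#' @param C Positive-definite covariance matrix, `length(y)` square.
#' @return A list with coefficients, `se`, `t_value`, `p_value`, `sigma2`
#'   (ML), `logLik` (`Inf` for a perfect fit), residuals, fitted values and
#'   the coefficient covariance matrix.
#' @export
gls_fit <- function(y, X, C) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), nrow(C) == length(y), ncol(C) == length(y))
  .gls_fit_core(as.numeric(y), X, as.matrix(C))
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model whose errors are correlated according to shared
#' phylogenetic history: `e ~ N(0, sigma2 * C(lambda))`, where `C` is the
#' Brownian-motion covariance of the tree ([phylo_covariance()]) and
#' `lambda` scales its off-diagonal ([lambda_transform()]). `lambda` is
#' either fixed or estimated by maximizing the profile log-likelihood over
#' `[0, 1]` (21-point grid, then bounded optimization to 1e-8, with both
#' endpoints evaluated explicitly since boundary estimates are common).
#'
#' Continuous volume and mass variables are expected on the log10 scale
#' (transform upstream). Logical predictors are coded 0/1 and their
#' coefficients named `<var>_TRUE`.
#'
#' AICc uses `k =` number of coefficients + 1 (for `sigma2`) + 1 if
#' `lambda` was estimated. R^2 is `1 - e'C^-1 e / e0'C^-1 e0` with `e0`
#' the residuals of the intercept-only GLS under the same `lambda`.
#'
#' @param formula Model formula, e.g. `bone ~ internal + mass + diving`.
#' @param data Data frame with a `species` column matching tree tip labels
#'   (spaces/underscores normalized) and the model variables.
#' @param tree An `ape::phylo` ultrametric tree containing all species.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return An object of class `"pgls"`; see [summary.pgls()],
#'   [coef.pgls()], [residuals.pgls()], [predict.pgls()],
#'   [simulate.pgls()], [plot.pgls()].
#' @examples
#' tr <- simulate_tree(40, seed = 2)
#' sim <- simulate_traits(tr, trait_gen_params(seed = 2))
#' fit <- pgls(bone ~ internal + mass, data = sim$traits, tree = tr)
#' summary(fit)
#' @export
pgls <- function(formula, data, tree, lambda = "ML") {
  stopifnot(inherits(tree, "phylo"))
  if (!"species" %in% names(data)) {
    stop("`data` must contain a `species` column", call. = FALSE)
  }
  data <- as.data.frame(data)
  rownames(data) <- NULL
  data$species <- gsub(" ", "_", as.character(data$species))
  tree$tip.label <- gsub(" ", "_", tree$tip.label)
  if (anyDuplicated(data$species)) {
    stop("duplicated species in `data`", call. = FALSE)
  }
  missing <- setdiff(data$species, tree$tip.label)
  if (length(missing)) {
    stop("species absent from tree: ", paste(sort(missing), collapse = ", "),
         call. = FALSE)
  }

  mf <- model.frame(formula, data = data, na.action = na.omit)
  used <- as.integer(rownames(mf))
  species <- data$species[used]
  y <- as.numeric(model.response(mf))
  X <- model.matrix(formula, mf)
  colnames(X) <- sub("TRUE$", "_TRUE", colnames(X))
  n <- length(y)
  if (n < ncol(X) + 2L) {
    stop("too few species (", n, ") for ", ncol(X), " coefficients",
         call. = FALSE)
  }

  C <- phylo_covariance(tree, species)
  profile <- function(lam) .gls_fit_core(y, X, lambda_transform(C, lam))$logLik

  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, by = 0.05)
    ll_grid <- vapply(grid, profile, numeric(1))
    i <- which.max(ll_grid)
    if (is.infinite(ll_grid[i])) {
      # perfect fit: likelihood degenerates for every lambda
      lambda_hat <- grid[i]
      lambda_ml <- TRUE
      return(.pgls_finish(y, X, C, lambda_hat, lambda_ml, species, formula,
                          mf, match.call(), tree))
    }
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- optimize(profile, interval = c(lo, hi), maximum = TRUE,
                    tol = 1e-8)
    cand <- rbind(c(opt$maximum, opt$objective),
                  c(0, ll_grid[1]), c(1, ll_grid[length(grid)]),
                  c(grid[i], ll_grid[i]))
    best <- cand[which.max(cand[, 2]), ]
    lambda_hat <- best[1]
    lambda_ml <- TRUE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("`lambda` must be \"ML\" or a value in [0, 1]", call. = FALSE)
    }
    lambda_hat <- lambda
    lambda_ml <- FALSE
  }

  .pgls_finish(y, X, C, lambda_hat, lambda_ml, species, formula, mf,
               match.call(), tree)
}

.pgls_finish <- function(y, X, C, lambda_hat, lambda_ml, species, formula,
                         mf, call, tree) {
  n <- length(y)
  Cl <- lambda_transform(C, lambda_hat)
  core <- .gls_fit_core(y, X, Cl)
  k <- core$p + 1L + as.integer(lambda_ml)
  aicc_val <- if (n - k - 1 > 0) aicc(core$logLik, k, n) else NA_real_

  # null (intercept-only) fit under the same lambda for R^2
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  core0 <- .gls_fit_core(y, X0, Cl)
  r2 <- 1 - core$rss_gls / core0$rss_gls

  structure(
    list(coefficients = core$coefficients, se = core$se,
         t_value = core$t_value, p_value = core$p_value,
         lambda = lambda_hat, lambda_ml = lambda_ml,
         sigma2 = core$sigma2, logLik = core$logLik,
         aicc = aicc_val, r_squared = r2,
         residuals = setNames(core$residuals, species),
         fitted = setNames(core$fitted, species),
         vcov = core$vcov, n = n, k = k,
         species = species, formula = formula,
         terms = terms(mf), call = call,
         tree = ape::keep.tip(tree, species)),
    class = "pgls"
  )
}

#' Finite-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`; undefined unless
#' `n - k - 1 > 0`.
#'
#' @param loglik Log-likelihood at the maximum.
#' @param k Number of estimated parameters (including the residual variance
#'   and, if estimated, lambda).
#' @param n Sample size.
#' @return The AICc value.
#' @examples
#' aicc(0, 2, 10)  # 4 + 12/7
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    stop("AICc undefined: need n - k - 1 > 0", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param x Vector of finite AICc values.
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(-58.94, -57.36))
#' @export
akaike_weights <- function(x) {
  if (!length(x) || !all(is.finite(x))) {
    stop("AICc values must be non-empty and finite", call. = FALSE)
  }
  d <- x - min(x)
  w <- exp(-d / 2)
  w / sum(w)
}
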