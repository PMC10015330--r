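#' Fit and rank a family of phylogenetic regressions by AICc
#'
#' All models are fitted on the identical species subset -- the complete
#' cases across the union of every variable used by any model in the
#' family -- so their AICc values are comparable. Each model is fitted by
#' [pgls()] with lambda estimated by ML (or fixed). Models whose Akaike
#' weight falls below 1/8 of the best model's weight are flagged
#' `negligible`.
#'
#' @param formulas List of model formulas (or formula strings) sharing one
#'   response.
#' @param data Trait data frame with a `species` column.
#' @param tree An `ape::phylo` tree.
#' @param lambda `"ML"` or a fixed value in `[0, 1]`, passed to [pgls()].
#' @return An object of class `"pgls_modeltable"`: a data frame with one
#'   row per model (`model`, `n`, `lambda`, `logLik`, `k`, `AICc`,
#'   `delta_AICc`, `weight`, `R2`, `negligible`) sorted by AICc, with the
#'   fitted `"pgls"` objects in `attr(, "fits")` (in table order).
#' @examples
#' tr <- simulate_tree(40, seed = 5)
#' sim <- simulate_traits(tr, trait_gen_params(seed = 5))
#' compare_models(list(bone ~ internal, bone ~ internal + mass),
#'                sim$traits, tr)
#' @export
compare_models <- function(formulas, data, tree, lambda = "ML") {
  formulas <- lapply(formulas, stats::as.formula)
  if (!length(formulas)) stop("empty model family", call. = FALSE)
  vars <- unique(unlist(lapply(formulas, all.vars)))
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop("variables missing from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- complete.cases(data[vars])
  sub <- as.data.frame(data)[keep, , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 complete-case species", call. = FALSE)

  fits <- lapply(formulas, pgls, data = sub, tree = tree, lambda = lambda)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) {
    stop("species sets differ across models despite complete-case filtering",
         call. = FALSE)
  }
  av <- vapply(fits, `[[`, numeric(1), "aicc")
  w <- akaike_weights(av)
  tab <- data.frame(
    model = vapply(formulas, function(f) paste(deparse(f), collapse = " "),
                   character(1)),
    n = ns,
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AICc = av,
    delta_AICc = av - min(av),
    weight = w,
    R2 = vapply(fits, `[[`, numeric(1), "r_squared"),
    negligible = w < max(w) / 8,
    stringsAsFactors = FALSE
  )
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("pgls_modeltable", "data.frame"))
}

#' @export
print.pgls_modeltable <- function(x, digits = 4, ...) {
  cat("PGLS model comparison (", nrow(x), " models, n = ", x$n[1],
      " species)\n\n", sep = "")
  df <- as.data.frame(x)
  df$logLik <- round(df$logLik, digits)
  df$AICc <- round(df$AICc, digits)
  df$delta_AICc <- round(df$delta_AICc, digits)
  df$weight <- round(df$weight, digits)
  df$R2 <- round(df$R2, digits)
  df$lambda <- round(df$lambda, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Long-format coefficient table for a fitted model family
#'
#' One row per (model, term): model syntax, n, AICc, weight, R^2, lambda,
#' term name, estimate, s.e., t and p -- the layout of a published PGLS
#' model-selection table.
#'
#' @param mt A [compare_models()] result.
#' @return A data frame.
#' @export
model_table_terms <- function(mt) {
  stopifnot(inherits(mt, "pgls_modeltable"))
  fits <- attr(mt, "fits")
  do.call(rbind, lapply(seq_len(nrow(mt)), function(i) {
    f <- fits[[i]]
    data.frame(model = mt$model[i], n = f$n, AICc = mt$AICc[i],
               AICc_wt = mt$weight[i], R2 = f$r_squared, lambda = f$lambda,
               term = names(f$coefficients),
               estimate = unname(f$coefficients), se = unname(f$se),
               t = unname(f$t_value), p = unname(f$p_value),
               stringsAsFactors = FALSE)
  }))
}

#' Bone thickness index (BTI)
#'
#' Residuals of the null bone-scaling PGLS, `bone ~ internal` (log10 bone
#' volume on log10 internal cavity volume, lambda by ML). Because both
#' volumes scale with element size, a positive residual marks a species
#' with relatively thicker cortical bone than its size predicts, a negative
#' one relatively thinner bone.
#'
#' @param data Trait data frame with `species`, `bone` and `internal`
#'   columns (log10 mm^3).
#' @param tree An `ape::phylo` tree.
#' @param formula The null scaling model (default `bone ~ internal`).
#' @param lambda Passed to [pgls()].
#' @return Named numeric vector of BTI values (one per species), with the
#'   underlying `"pgls"` fit in `attr(, "fit")`.
#' @export
compute_bti <- function(data, tree, formula = bone ~ internal,
                        lambda = "ML") {
  fit <- pgls(formula, data = data, tree = tree, lambda = lambda)
  structure(residuals(fit), fit = fit)
}
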