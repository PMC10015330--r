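test_that("phylogenetic covariance holds shared path lengths", {
  two <- read_phylogeny("(A:1,B:1);")
  C2 <- phylo_covariance(two, c("A", "B"))
  expect_equal(unname(C2), diag(2))

  C3 <- phylo_covariance(three_tip_tree(), c("A", "B", "C"))
  expect_equal(unname(diag(C3)), c(2, 2, 2))  # ultrametric: constant diagonal
  expect_equal(C3["A", "B"], 1)
  expect_equal(C3["A", "C"], 0)
  expect_equal(C3, t(C3))
})

test_that("lambda transform scales only the off-diagonal", {
  C <- phylo_covariance(three_tip_tree())
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  expect_equal(lambda_transform(C, 0.5)["A", "B"], 0.5)
  expect_equal(diag(lambda_transform(C, 0.5)), diag(C))
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(C, -0.1), "\\[0, 1\\]")
})

test_that("newick reading normalizes labels, prunes and validates", {
  tr <- read_phylogeny("(A:1,B:1);")
  expect_equal(ape::node.depth.edgelength(tr)[1:2], c(1, 1))

  pruned <- read_phylogeny("((A:1,B:1):1,C:2);", taxa = c("A", "C"))
  expect_setequal(pruned$tip.label, c("A", "C"))
  expect_equal(ape::node.depth.edgelength(pruned)[1:2], c(2, 2))

  expect_error(read_phylogeny("((A:1,B:1):1,C:2);", taxa = c("A", "D")), "D")
  sp <- read_phylogeny("(Anas_crecca:1,Apus_apus:1);", taxa = "Anas crecca")
  expect_equal(sp$tip.label, "Anas_crecca")
  expect_warning(read_phylogeny("(A:1,B:3);"), "ultrametric")
})

test_that("GLS with identity covariance equals ordinary least squares", {
  for (s in 1:5) {
    inst <- random_instance(25, seed = 300 + s)
    X <- model.matrix(inst$formula, inst$data)
    ols <- lm(inst$formula, data = inst$data)
    g <- gls_fit(inst$data$y, X, diag(25))
    expect_equal(unname(g$coefficients), unname(coef(ols)), tolerance = 1e-8)
    expect_equal(unname(g$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
  }
})

test_that("perfect fits and rank-deficient designs are handled explicitly", {
  tr <- simulate_tree(10, seed = 12)
  C <- phylo_covariance(tr)
  x <- rnorm(10)
  X <- cbind(1, x)
  y <- 2 + 3 * x
  g <- gls_fit(y, X, C)
  expect_equal(g$residuals, rep(0, 10))
  expect_identical(g$logLik, Inf)

  expect_error(gls_fit(rnorm(10), cbind(a = 1, b = x, b2 = x), C),
               "rank deficient.*b2")
})

test_that("GLS residuals are orthogonal to the design in the C-inverse inner product", {
  inst <- random_instance(30, seed = 44)
  C <- phylo_covariance(inst$tree)
  X <- model.matrix(inst$formula, inst$data)
  g <- gls_fit(inst$data$y, X, C)
  expect_lt(max(abs(t(X) %*% solve(C, g$residuals))), 1e-8)
})

test_that("pgls at lambda 1 reproduces the independent-contrasts slope", {
  for (s in 1:4) {
    n <- 8 + 4 * s
    tr <- simulate_tree(n, seed = 600 + s)
    set.seed(700 + s)
    x <- rnorm(n)
    y <- 1.5 * x + rnorm(n)
    d <- data.frame(species = tr$tip.label, x = x, y = y)
    fit <- pgls(y ~ x, d, tr, lambda = 1)
    px <- ape::pic(setNames(x, tr$tip.label), tr)
    py <- ape::pic(setNames(y, tr$tip.label), tr)
    slope_pic <- unname(coef(lm(py ~ px - 1)))
    expect_equal(unname(coef(fit)["x"]), slope_pic, tolerance = 1e-6)
  }
})

test_that("ML lambda and coefficients agree with an independent GLS implementation", {
  tr <- simulate_tree(80, seed = 9)
  sim <- simulate_traits(tr, trait_gen_params(lambda_true = 0.6, noise_sd = 0.2,
                                              seed = 9))
  d <- sim$traits
  rownames(d) <- d$species
  ref <- nlme::gls(bone ~ internal + mass, data = d,
                   correlation = ape::corPagel(0.5, phy = tr, form = ~species),
                   method = "ML")
  fit <- pgls(bone ~ internal + mass, d, tr)
  expect_equal(fit$lambda, unname(coef(ref$modelStruct$corStruct)),
               tolerance = 1e-4)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("profile likelihood is maximized at the reported lambda", {
  tr <- simulate_tree(50, seed = 13)
  sim <- simulate_traits(tr, trait_gen_params(lambda_true = 0.5, noise_sd = 0.1,
                                              seed = 13))
  fit <- pgls(bone ~ internal + mass, sim$traits, tr)
  refit <- function(lam) pgls(bone ~ internal + mass, sim$traits, tr,
                              lambda = lam)$logLik
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_gte(fit$logLik, refit(lam) - 1e-7)
  }
})

test_that("AICc follows the finite-sample formula and its domain", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-10, 3, 1e7), 26, tolerance = 1e-5)  # tends to AIC
  expect_error(aicc(0, 9, 10), "n - k - 1")
  tr <- simulate_tree(20, seed = 15)
  sim <- simulate_traits(tr, trait_gen_params(n_tips = 20, seed = 15))
  fit <- pgls(bone ~ internal, sim$traits, tr)
  expect_equal(fit$aicc, aicc(fit$logLik, fit$k, fit$n))
  expect_equal(fit$k, 2 + 1 + 1)  # two betas, sigma2, ML lambda
  expect_equal(pgls(bone ~ internal, sim$traits, tr, lambda = 0)$k, 3)
})

test_that("Akaike weights normalize and are shift invariant", {
  w <- akaike_weights(c(-58.94, -57.36))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(akaike_weights(5), 1)
  x <- c(10, 12, 15.5)
  expect_equal(akaike_weights(x), akaike_weights(x + 100))
  expect_error(akaike_weights(c(1, Inf)), "finite")
})

test_that("model frame errors are informative", {
  tr <- simulate_tree(10, seed = 18)
  d <- data.frame(species = c(tr$tip.label[-1], "not_in_tree"), y = rnorm(10),
                  x = rnorm(10))
  expect_error(pgls(y ~ x, d, tr), "not_in_tree")
  d2 <- data.frame(species = rep(tr$tip.label[1], 10), y = rnorm(10),
                   x = rnorm(10))
  expect_error(pgls(y ~ x, d2, tr), "duplicated")
})

test_that("pgls methods expose the fit consistently", {
  tr <- simulate_tree(30, seed = 19)
  sim <- simulate_traits(tr, trait_gen_params(n_tips = 30, seed = 19))
  fit <- pgls(bone ~ internal + mass + pneumatic, sim$traits, tr)
  expect_named(coef(fit),
               c("(Intercept)", "internal", "mass", "pneumatic_TRUE"))
  expect_equal(fitted(fit) + residuals(fit),
               setNames(sim$traits$bone, sim$traits$species))
  expect_equal(unname(predict(fit, sim$traits)), unname(fitted(fit)))
  s <- summary(fit)
  expect_s3_class(s, "summary.pgls")
  expect_equal(unname(s$coefficients[, "Estimate"]), unname(coef(fit)))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), fit$k)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30, 3))
  expect_identical(simulate(fit, nsim = 2, seed = 5),
                   simulate(fit, nsim = 2, seed = 5))
})
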