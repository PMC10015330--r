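test_that("simulated trees are ultrametric, bifurcating and seed-reproducible", {
  for (case in list(c(2, 1), c(10, 3), c(50, 7), c(100, 11))) {
    n <- case[1]
    tr <- simulate_tree(n, seed = case[2])
    expect_s3_class(tr, "phylo")
    expect_length(tr$tip.label, n)
    expect_equal(tr$Nnode, n - 1)  # bifurcating rooted tree
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(diff(range(depths)) / max(depths), 1e-9)
    expect_equal(max(depths), 100)  # fixed calibration depth
  }
  expect_identical(ape::write.tree(simulate_tree(100, seed = 7)),
                   ape::write.tree(simulate_tree(100, seed = 7)))
  expect_error(simulate_tree(1), "n_tips")
  expect_error(simulate_tree(10, birth_rate = 0), "birth_rate")
})

test_that("zero residual noise makes air volume an exact function of internal volume", {
  tr <- simulate_tree(25, seed = 4)
  p <- trait_gen_params(noise_sd = 0, air_slope = 1, air_intercept = 0,
                        p_pneumatic = 1, seed = 4)
  sim <- simulate_traits(tr, p)
  expect_equal(sim$traits$air, sim$traits$internal)
})

test_that("trait generator rejects invalid lambda and probabilities", {
  expect_error(trait_gen_params(lambda_true = 1.5), "lambda_true")
  expect_error(trait_gen_params(lambda_true = -0.1), "lambda_true")
  expect_error(trait_gen_params(p_diving = 2), "probabilities")
  expect_error(trait_gen_params(sigma2 = -1), "sigma2")
})

test_that("residual noise has the stated tip-level scale and lambda-controlled correlation", {
  tr <- simulate_tree(8, seed = 21)
  n_rep <- 300
  # lambda_true = 0: residuals of distinct tips are uncorrelated
  r0 <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_traits(tr, trait_gen_params(n_tips = 8, lambda_true = 0,
                                                noise_sd = 1, seed = 1000 + r))
    sim$truth$residual_bone[1:2]
  }, numeric(2))
  expect_lt(abs(cor(r0[1, ], r0[2, ])), 0.15)
  expect_equal(sd(r0[1, ]), 1, tolerance = 0.15)  # tip s.d. = noise_sd

  # lambda_true = 1: sister-tip residual correlation equals shared-path fraction
  C <- ape::vcv.phylo(tr)
  pair <- which(C == max(C[upper.tri(C)]), arr.ind = TRUE)[1, ]
  rho_true <- C[pair[1], pair[2]] / max(diag(C))
  r1 <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_traits(tr, trait_gen_params(n_tips = 8, lambda_true = 1,
                                                noise_sd = 1, seed = 5000 + r))
    sim$truth$residual_bone[pair]
  }, numeric(2))
  expect_equal(cor(r1[1, ], r1[2, ]), rho_true, tolerance = 0.15)
})

test_that("Brownian predictor traits have variance sigma2 times tree depth", {
  tr <- simulate_tree(6, seed = 31)
  sigma2 <- 0.004
  vals <- vapply(seq_len(400), function(r) {
    sim <- simulate_traits(tr, trait_gen_params(n_tips = 6, sigma2 = sigma2,
                                                seed = 20000 + r))
    sim$traits$internal[1]
  }, numeric(1))
  expect_equal(var(vals), sigma2 * 100, tolerance = 0.15 * sigma2 * 100)
})

test_that("phantom true volumes follow closed-form cylinder geometry", {
  base <- phantom_spec(outer_radius = 5, cortical_thickness = 1,
                       shaft_length = 20, voxel_size = 0.25)
  ph <- make_phantom(base)
  expect_equal(ph$truth$v_total, pi * 25 * 20)
  expect_equal(ph$truth$v_bone + ph$truth$v_marrow + ph$truth$v_air,
               ph$truth$v_total)

  ph0 <- make_phantom(phantom_spec(air_fill_fraction = 0, voxel_size = 0.25))
  expect_equal(ph0$truth$v_air, 0)
  ph1 <- make_phantom(phantom_spec(air_fill_fraction = 1, voxel_size = 0.25))
  expect_equal(ph1$truth$v_marrow, 0)
})

test_that("phantom spec enforces its invariants", {
  expect_error(phantom_spec(outer_radius = 1, cortical_thickness = 1),
               "cortical_thickness")
  expect_error(phantom_spec(grey_levels = c(100, 50, 220)), "increasing")
  expect_error(phantom_spec(air_fill_fraction = 1.2), "air_fill_fraction")
  # fewer than 5 voxels across the diameter is a degenerate scan
  expect_error(make_phantom(phantom_spec(outer_radius = 1, cortical_thickness = 0.4,
                                         voxel_size = 0.5)),
               "degenerate resolution")
})

test_that("clustered flag mode flips whole clades", {
  tr <- simulate_tree(40, seed = 6)
  sim <- simulate_traits(tr, trait_gen_params(n_tips = 40, p_diving = 0.3,
                                              seed = 6),
                         clustered_flags = TRUE)
  dv <- sim$traits$diving
  expect_gte(mean(dv), 0.3)  # clades flip until the target is reached
  # flagged tips form whole clades: the smallest clade containing any two
  # flagged sister tips is fully flagged
  expect_true(any(dv) && any(!dv))
})
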