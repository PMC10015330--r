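test_that("air space proportions match hand-computed fractions", {
  expect_equal(asp_internal(tissue_volumes(0, 50, 50)), 0.5)
  expect_equal(asp_internal(tissue_volumes(0, 120, 0)), 0)
  expect_equal(asp_internal(tissue_volumes(0, 25, 75)), 0.75)
  expect_equal(asp_total(tissue_volumes(50, 10, 40)), 0.4)
  expect_equal(asp_total(tissue_volumes(10, 20, 0)), 0)
  # same volumes, both measures: ASP_t < ASP_i because bone pads the denominator
  tv <- tissue_volumes(100, 50, 50)
  expect_equal(asp_internal(tv), 0.5)
  expect_equal(asp_total(tv), 0.25)
})

test_that("solid elements have undefined ASP_i and cannot be classified", {
  solid <- tissue_volumes(100, 0, 0)
  expect_true(is.na(asp_internal(solid)))
  expect_error(classify_pneumatic(solid), "solid")
  expect_error(asp_total(tissue_volumes(0, 0, 0)), "total volume is zero")
})

test_that("mass and bulk density follow the assumed tissue densities", {
  pure_bone <- mass_and_density(tissue_volumes(100, 0, 0))
  expect_equal(pure_bone$bulk_density_g_cm3, 2.05)
  expect_equal(pure_bone$bone_fraction, 1)
  pure_marrow <- mass_and_density(tissue_volumes(0, 100, 0))
  expect_equal(pure_marrow$bulk_density_g_cm3, 1.0)

  mixed <- mass_and_density(tissue_volumes(25, 25, 50))
  expect_equal(mixed$mass_g, 0.07625)
  expect_equal(mixed$bulk_density_g_cm3, 0.7625)
  expect_equal(mixed$bone_fraction, 0.25)

  custom <- mass_and_density(tissue_volumes(100, 0, 0),
                             density_assumptions(rho_bone = 1.8))
  expect_equal(custom$bulk_density_g_cm3, 1.8)
})

test_that("pneumatic classification uses a strict epsilon threshold", {
  expect_false(classify_pneumatic(tissue_volumes(0, 100, 0)))
  expect_true(classify_pneumatic(tissue_volumes(0, 2, 98)))
  # ASP_i exactly at epsilon is apneumatic (strict inequality)
  eps <- 0.001
  tv <- tissue_volumes(0, 1 - eps, eps)  # ASP_i == eps
  expect_false(classify_pneumatic(tv, epsilon = eps))
  expect_true(classify_pneumatic(tv, epsilon = eps / 2))
})

test_that("species aggregation is nested: humeri to specimens, specimens to species", {
  rec <- data.frame(
    specimen_id = c("s1", "s1", "s2"),
    species = "Anas_crecca",
    side = c("left", "right", "left"),
    v_bone_mm3 = c(100, 100, 100),
    v_marrow_mm3 = c(0, 0, 0),
    v_air_mm3 = c(10, 20, 25)
  )
  side <- data.frame(species = "Anas_crecca", body_mass_g = 300, diving = FALSE)
  sp <- aggregate_species(rec, side)
  # specimen means are (15, 25); species mean 20, not the flat 18.33
  expect_equal(sp$v_air_mm3, 20)
  expect_equal(sp$body_mass_g, 300)
  expect_true(sp$pneumatic)

  # single humerus passes straight through
  one <- aggregate_species(rec[1, ], side)
  expect_equal(one$v_air_mm3, 10)

  # permutation invariance
  shuffled <- aggregate_species(rec[c(3, 1, 2), ], side)
  expect_equal(shuffled, sp)
})

test_that("aggregation fails loudly on species missing from the side table", {
  rec <- data.frame(specimen_id = "s1", species = "Apus_apus", side = "left",
                    v_bone_mm3 = 1, v_marrow_mm3 = 1, v_air_mm3 = 0)
  side <- data.frame(species = "Anas_crecca", body_mass_g = 300, diving = FALSE)
  expect_error(aggregate_species(rec, side), "Apus_apus")
  expect_error(aggregate_species(transform(rec, side = "dorsal"), side),
               "side")
})

test_that("metrics can be computed on averaged volumes or averaged per element", {
  rec <- data.frame(
    specimen_id = c("s1", "s2"),
    species = "sp",
    side = "left",
    v_bone_mm3 = c(100, 100),
    v_marrow_mm3 = c(90, 10),
    v_air_mm3 = c(10, 90)
  )
  side <- data.frame(species = "sp", body_mass_g = 100, diving = FALSE)
  on_vol <- aggregate_species(rec, side, metrics_on = "volumes")
  on_el <- aggregate_species(rec, side, metrics_on = "elements")
  expect_equal(on_vol$asp_i, 0.5)          # 50 / 100 on mean volumes
  expect_equal(on_el$asp_i, 0.5)           # (0.1 + 0.9) / 2
  expect_equal(on_el$asp_t, (10 / 200 + 90 / 200) / 2)
})

test_that("ASP and density invariants hold across random volume triples", {
  vols <- random_volumes(200, seed = 77)
  rho_bone <- 2.05
  for (i in seq_len(nrow(vols))) {
    tv <- tissue_volumes(vols$v_bone[i], vols$v_marrow[i], vols$v_air[i])
    a_i <- asp_internal(tv)
    a_t <- asp_total(tv)
    if (!is.na(a_i)) expect_lte(a_t, a_i + 1e-12)
    d <- mass_and_density(tv)$bulk_density_g_cm3
    expect_lte(d, rho_bone + 1e-12)
  }
  # density strictly decreases as air replaces marrow at fixed bone and total
  dens <- vapply(seq(0, 100, by = 20), function(v_air) {
    mass_and_density(tissue_volumes(50, 100 - v_air, v_air))$bulk_density_g_cm3
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
})
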