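#' Assumed tissue densities for bulk-density estimation
#'
#' Bulk (whole-element) density treats air as massless, bone at the mean
#' avian humeral bone density and marrow at the density of water.
#'
#' @param rho_bone Bone density, g cm^-3 (default 2.05).
#' @param rho_marrow Marrow density, g cm^-3 (default 1.0, i.e. water).
#' @return An object of class `"density_assumptions"`. The g cm^-3 to
#'   g mm^-3 conversion constant (0.001) is carried along.
#' @export
density_assumptions <- function(rho_bone = 2.05, rho_marrow = 1.0) {
  stopifnot(is.numeric(rho_bone), rho_bone > 0,
            is.numeric(rho_marrow), rho_marrow > 0)
  structure(list(rho_bone = rho_bone, rho_marrow = rho_marrow,
                 g_per_mm3_per_g_per_cm3 = 0.001),
            class = "density_assumptions")
}

#' Air space proportion of the internal cavity (ASP_i)
#'
#' `ASP_i = v_air / (v_air + v_marrow)`: the fraction of the internal bone
#' cavity occupied by air rather than marrow. Undefined for a solid element
#' (no internal cavity); such elements return `NA` and are excluded from
#' ASP summaries downstream.
#'
#' @param tv A [tissue_volumes()].
#' @return A fraction in `[0, 1]`, or `NA_real_` when `v_internal == 0`.
#' @examples
#' asp_internal(tissue_volumes(100, 50, 50))  # 0.5
#' @export
asp_internal <- function(tv) {
  tv <- .as_tissue_volumes(tv)
  if (tv$v_internal == 0) return(NA_real_)
  tv$v_air / tv$v_internal
}

#' Air space proportion of the whole element (ASP_t)
#'
#' `ASP_t = v_air / (v_air + v_marrow + v_bone)`: the fraction of the total
#' element volume occupied by air. Always no greater than [asp_internal()]
#' because its denominator additionally includes bone.
#'
#' @param tv A [tissue_volumes()].
#' @return A fraction in `[0, 1]`.
#' @examples
#' asp_total(tissue_volumes(50, 10, 40))  # 0.4
#' @export
asp_total <- function(tv) {
  tv <- .as_tissue_volumes(tv)
  if (tv$v_total == 0) {
    stop("ASP_t undefined: total volume is zero", call. = FALSE)
  }
  tv$v_air / tv$v_total
}

#' Element mass, bulk density and bone fraction under assumed densities
#'
#' Element mass is bone mass plus marrow mass (air is massless):
#' `mass = 0.001 * (rho_bone * v_bone + rho_marrow * v_marrow)` grams, with
#' volumes in mm^3 and densities in g cm^-3. Bulk density is that mass
#' divided by the total element volume, back in g cm^-3. A pure-bone element
#' therefore has bulk density `rho_bone` and a pure-marrow one `rho_marrow`.
#'
#' @param tv A [tissue_volumes()].
#' @param d A [density_assumptions()].
#' @return A list with `mass_g`, `bulk_density_g_cm3` and `bone_fraction`
#'   (`v_bone / v_total`).
#' @examples
#' mass_and_density(tissue_volumes(25, 25, 50))  # mass 0.07625 g, density 0.7625
#' @export
mass_and_density <- function(tv, d = density_assumptions()) {
  tv <- .as_tissue_volumes(tv)
  stopifnot(inherits(d, "density_assumptions"))
  if (tv$v_total == 0) {
    stop("density undefined: total volume is zero", call. = FALSE)
  }
  k <- d$g_per_mm3_per_g_per_cm3
  mass <- k * (d$rho_bone * tv$v_bone + d$rho_marrow * tv$v_marrow)
  list(mass_g = mass,
       bulk_density_g_cm3 = mass / (tv$v_total * k),
       bone_fraction = tv$v_bone / tv$v_total)
}

#' Classify an element as pneumatic
#'
#' An element is pneumatic when its internal air space proportion strictly
#' exceeds `epsilon`. The small positive default absorbs segmentation
#' speckle in real scans, so a genuinely marrow-filled element with a few
#' misclassified voxels is still scored apneumatic.
#'
#' @param tv A [tissue_volumes()]; must have a non-empty internal cavity.
#' @param epsilon Threshold on ASP_i (default 0.001); strict inequality.
#' @return `TRUE` or `FALSE`.
#' @export
classify_pneumatic <- function(tv, epsilon = 0.001) {
  a <- asp_internal(tv)
  if (is.na(a)) {
    stop("pneumaticity undefined for a solid element (no internal cavity)",
         call. = FALSE)
  }
  a > epsilon
}

#' Aggregate per-humerus volumes to species-level traits
#'
#' Averaging is nested and unweighted: left/right humeri are averaged within
#' a specimen first, then specimen means are averaged within a species. A
#' species sampled by one specimen with two humeri and one with a single
#' humerus therefore weights the two specimens equally, not the three
#' humeri. Derived metrics (ASP_i, ASP_t, bone fraction, bulk density,
#' pneumatic flag) are computed on the species-mean volumes by default; set
#' `metrics_on = "elements"` to instead average per-element metrics.
#'
#' @param records Data frame of per-humerus measurements with columns
#'   `specimen_id`, `species`, `side` (`"left"`/`"right"`), `v_bone_mm3`,
#'   `v_marrow_mm3`, `v_air_mm3`.
#' @param side_table Data frame with one row per species: `species`,
#'   `body_mass_g`, `diving` (logical). Every species in `records` must
#'   appear here.
#' @param d A [density_assumptions()].
#' @param epsilon Pneumaticity threshold passed to [classify_pneumatic()].
#' @param metrics_on `"volumes"` (default; metrics on species-mean volumes)
#'   or `"elements"` (mean of per-humerus metrics, nested like the volumes).
#' @return Data frame with one row per species: mean volumes, body mass,
#'   diving flag, `asp_i`, `asp_t`, `bone_fraction`, `bulk_density_g_cm3`
#'   and `pneumatic`. `asp_i` is `NA` for solid elements.
#' @export
aggregate_species <- function(records, side_table, d = density_assumptions(),
                              epsilon = 0.001,
                              metrics_on = c("volumes", "elements")) {
  metrics_on <- match.arg(metrics_on)
  need <- c("specimen_id", "species", "side",
            "v_bone_mm3", "v_marrow_mm3", "v_air_mm3")
  if (!all(need %in% names(records))) {
    stop("`records` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$side %in% c("left", "right"))) {
    stop("`side` must be 'left' or 'right'", call. = FALSE)
  }
  unknown <- setdiff(unique(records$species), side_table$species)
  if (length(unknown)) {
    stop("species missing from the side table: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }

  vol_cols <- c("v_bone_mm3", "v_marrow_mm3", "v_air_mm3")
  if (metrics_on == "elements") {
    records$asp_i_el <- records$v_air_mm3 /
      ifelse(records$v_air_mm3 + records$v_marrow_mm3 > 0,
             records$v_air_mm3 + records$v_marrow_mm3, NA_real_)
    records$asp_t_el <- records$v_air_mm3 /
      (records$v_air_mm3 + records$v_marrow_mm3 + records$v_bone_mm3)
  }
  num_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                      c("specimen_id"))

  # humeri -> specimen means
  spec_means <- aggregate(records[num_cols],
                          by = list(specimen_id = records$specimen_id,
                                    species = records$species),
                          FUN = mean)
  # specimen -> species means (unweighted)
  sp <- aggregate(spec_means[num_cols],
                  by = list(species = spec_means$species),
                  FUN = mean)
  sp <- sp[order(sp$species), , drop = FALSE]

  tvs <- lapply(seq_len(nrow(sp)), function(i) {
    tissue_volumes(sp$v_bone_mm3[i], sp$v_marrow_mm3[i], sp$v_air_mm3[i])
  })
  if (metrics_on == "volumes") {
    sp$asp_i <- vapply(tvs, asp_internal, numeric(1))
    sp$asp_t <- vapply(tvs, asp_total, numeric(1))
  } else {
    sp$asp_i <- sp$asp_i_el
    sp$asp_t <- sp$asp_t_el
    sp$asp_i_el <- sp$asp_t_el <- NULL
  }
  md <- lapply(tvs, mass_and_density, d = d)
  sp$bone_fraction <- vapply(md, `[[`, numeric(1), "bone_fraction")
  sp$bulk_density_g_cm3 <- vapply(md, `[[`, numeric(1), "bulk_density_g_cm3")
  sp$pneumatic <- vapply(seq_along(tvs), function(i) {
    if (tvs[[i]]$v_internal == 0) return(FALSE)  # solid bone: apneumatic
    classify_pneumatic(tvs[[i]], epsilon)
  }, logical(1))

  idx <- match(sp$species, side_table$species)
  sp$body_mass_g <- side_table$body_mass_g[idx]
  sp$diving <- side_table$diving[idx]
  rownames(sp) <- NULL
  sp
}
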