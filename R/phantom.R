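#' Specification of a digital bone phantom
#'
#' A phantom is a hollow cylinder standing in for a long-bone diaphysis: a
#' cortical bone shell of given thickness whose internal cavity is filled
#' with air over a proximal fraction of its length and with marrow over the
#' remainder. Because the geometry is analytic, the true tissue volumes are
#' known in closed form, which makes the phantom an exact oracle for the
#' segmentation and voxel-counting stages.
#'
#' @param outer_radius Outer radius of the shaft, mm.
#' @param cortical_thickness Bone shell thickness, mm; must be smaller than
#'   `outer_radius`.
#' @param shaft_length Shaft length, mm.
#' @param air_fill_fraction Fraction in `[0, 1]` of the internal cavity length
#'   (proximal side) occupied by air; the rest is marrow.
#' @param grey_levels Mean grey values for air, marrow and bone, strictly
#'   increasing in that order (air is least dense, bone most dense).
#' @param noise_sd Standard deviation of additive Gaussian grey noise.
#' @param voxel_size Isotropic voxel edge length, mm.
#' @param seed Integer seed for the grey-noise draw.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(outer_radius = 5, cortical_thickness = 1,
                         shaft_length = 20, air_fill_fraction = 0.5,
                         grey_levels = c(air = 50, marrow = 120, bone = 220),
                         noise_sd = 0, voxel_size = 0.1, seed = 1L) {
  stopifnot(is.numeric(outer_radius), outer_radius > 0,
            is.numeric(cortical_thickness), cortical_thickness > 0,
            is.numeric(shaft_length), shaft_length > 0,
            is.numeric(voxel_size), voxel_size > 0,
            is.numeric(noise_sd), noise_sd >= 0,
            length(grey_levels) == 3L)
  if (cortical_thickness >= outer_radius) {
    stop("`cortical_thickness` must be smaller than `outer_radius`", call. = FALSE)
  }
  if (air_fill_fraction < 0 || air_fill_fraction > 1) {
    stop("`air_fill_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!(grey_levels[1] < grey_levels[2] && grey_levels[2] < grey_levels[3])) {
    stop("`grey_levels` must be strictly increasing (air < marrow < bone)",
         call. = FALSE)
  }
  structure(
    list(outer_radius = outer_radius, cortical_thickness = cortical_thickness,
         shaft_length = shaft_length, air_fill_fraction = air_fill_fraction,
         grey_levels = setNames(as.numeric(grey_levels),
                                c("air", "marrow", "bone")),
         noise_sd = noise_sd, voxel_size = voxel_size,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Build a digital bone phantom with analytically known tissue volumes
#'
#' Rasterizes the hollow-cylinder geometry of a [phantom_spec()] onto an
#' isotropic voxel grid. Each voxel is classified by its centre point:
#' inside the cortical shell it is bone; inside the cavity it is air over
#' the proximal `air_fill_fraction` of the shaft length and marrow beyond.
#' Grey values are the per-tissue means plus Gaussian noise. The returned
#' true volumes come from closed-form cylinder geometry, not from voxel
#' counts, so they are an independent oracle for [measure_volumes()].
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom"` with elements:
#'   \describe{
#'     \item{grid}{a [voxel_grid()] of noisy grey values,}
#'     \item{labels}{a [label_grid()] holding the true geometric labels,}
#'     \item{mask}{logical array, `TRUE` inside the cylinder,}
#'     \item{truth}{a [tissue_volumes()] from the analytic geometry,}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' ph <- make_phantom(phantom_spec(voxel_size = 0.25))
#' ph$truth$v_total                       # pi * 25 * 20
#' measure_volumes(segment_grid(ph$grid, threshold_set(85, 170), ph$mask))
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vx <- spec$voxel_size
  if (2 * spec$outer_radius / vx < 5) {
    stop("degenerate resolution: fewer than 5 voxels span the phantom diameter",
         call. = FALSE)
  }
  r_out <- spec$outer_radius
  r_in <- spec$outer_radius - spec$cortical_thickness
  len <- spec$shaft_length

  # one voxel of margin of background on every side
  n_xy <- ceiling(2 * r_out / vx) + 2L
  n_z <- ceiling(len / vx) + 2L
  cxy <- ((seq_len(n_xy) - 0.5) - n_xy / 2) * vx   # centred transverse coords
  cz <- ((seq_len(n_z) - 0.5) - 1) * vx            # axial coord, shaft in [0, len)

  r2 <- outer(cxy^2, cxy^2, "+")                   # squared radius per (x, y)
  in_out <- r2 <= r_out^2
  in_cav <- r2 <= r_in^2
  z_in <- cz >= 0 & cz < len
  z_air <- z_in & cz < spec$air_fill_fraction * len

  labs <- array(0L, dim = c(n_xy, n_xy, n_z))      # 0 = background
  for (k in seq_len(n_z)) {
    if (!z_in[k]) next
    sl <- matrix(0L, n_xy, n_xy)
    sl[in_out] <- 3L                               # bone shell
    sl[in_cav] <- if (z_air[k]) 1L else 2L         # air or marrow cavity
    labs[, , k] <- sl
  }

  set.seed(spec$seed)
  grey <- array(0, dim = dim(labs))
  grey[labs == 1L] <- spec$grey_levels[["air"]]
  grey[labs == 2L] <- spec$grey_levels[["marrow"]]
  grey[labs == 3L] <- spec$grey_levels[["bone"]]
  if (spec$noise_sd > 0) {
    grey <- grey + rnorm(length(grey), sd = spec$noise_sd)
  }

  v_int <- pi * r_in^2 * len
  truth <- tissue_volumes(
    v_bone = pi * (r_out^2 - r_in^2) * len,
    v_marrow = (1 - spec$air_fill_fraction) * v_int,
    v_air = spec$air_fill_fraction * v_int
  )

  structure(
    list(grid = voxel_grid(grey, vx),
         labels = label_grid(labs, vx),
         mask = labs != 0L,
         truth = truth,
         spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$grid$values)
  cat(sprintf("Digital bone phantom: %d x %d x %d voxels at %.4g mm\n",
              d[1], d[2], d[3], x$grid$voxel_size))
  cat(sprintf("  analytic volumes (mm^3): bone %.4g, marrow %.4g, air %.4g\n",
              x$truth$v_bone, x$truth$v_marrow, x$truth$v_air))
  invisible(x)
}

#' Write / read a phantom as a multi-page TIFF with a JSON sidecar
#'
#' The grey volume is stored one z-slice per TIFF page (16-bit, grey values
#' affinely rescaled to `[0, 1]` by the recorded `grey_offset`/`grey_scale`),
#' and the voxel size, grey calibration and analytic true volumes travel in
#' a JSON sidecar next to it.
#'
#' @param phantom A [make_phantom()] result.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_phantom()` returns `path` invisibly; `read_phantom_grid()`
#'   returns a list with a `grid` ([voxel_grid()]) and the sidecar metadata.
#' @export
write_phantom <- function(phantom, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to write phantoms", call. = FALSE)
  }
  stopifnot(inherits(phantom, "phantom"))
  g <- phantom$grid$values
  grey_offset <- min(g)
  grey_scale <- max(max(g) - grey_offset, 1e-12)
  pages <- lapply(seq_len(dim(g)[3]),
                  function(k) (g[, , k] - grey_offset) / grey_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    voxel_size_mm = phantom$grid$voxel_size,
    grey_offset = grey_offset,
    grey_scale = grey_scale,
    true_volumes_mm3 = list(v_bone = phantom$truth$v_bone,
                            v_marrow = phantom$truth$v_marrow,
                            v_air = phantom$truth$v_air)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @param tiff_path Path to a TIFF written by [write_phantom()].
#' @export
read_phantom_grid <- function(tiff_path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to read phantoms", call. = FALSE)
  }
  meta <- jsonlite::read_json(paste0(tiff_path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    arr[, , k] <- pages[[k]] * meta$grey_scale + meta$grey_offset
  }
  list(grid = voxel_grid(arr, meta$voxel_size_mm), meta = meta)
}
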