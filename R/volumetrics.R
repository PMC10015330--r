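#' Voxel grid of CT grey values
#'
#' @param values Non-empty 3-D numeric array of grey values.
#' @param voxel_size Isotropic voxel edge length in mm. Anisotropic voxels
#'   are not supported: supplying more than one value is an error.
#' @return An object of class `"voxel_grid"`.
#' @export
voxel_grid <- function(values, voxel_size) {
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L) {
    stop("`values` must be a non-empty 3-D array", call. = FALSE)
  }
  if (length(voxel_size) != 1L || !is.numeric(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive length (isotropic voxels only)",
         call. = FALSE)
  }
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Voxel grid: %d x %d x %d at %.4g mm (grey range %.4g..%.4g)\n",
              d[1], d[2], d[3], x$voxel_size, min(x$values), max(x$values)))
  invisible(x)
}

#' Grey-value thresholds separating air, marrow and bone
#'
#' @param t_air_marrow Grey value separating air (below) from marrow.
#' @param t_marrow_bone Grey value separating marrow (below) from bone;
#'   must exceed `t_air_marrow`.
#' @return An object of class `"threshold_set"`.
#' @export
threshold_set <- function(t_air_marrow, t_marrow_bone) {
  stopifnot(is.numeric(t_air_marrow), is.numeric(t_marrow_bone))
  if (!(t_air_marrow < t_marrow_bone)) {
    stop("threshold ordering violated: need t_air_marrow < t_marrow_bone",
         call. = FALSE)
  }
  structure(list(t_air_marrow = t_air_marrow, t_marrow_bone = t_marrow_bone),
            class = "threshold_set")
}

#' Labelled voxel grid
#'
#' Integer label codes: 0 background, 1 air, 2 marrow, 3 bone.
#'
#' @param labels 3-D integer array over `{0, 1, 2, 3}`.
#' @param voxel_size Isotropic voxel edge length, mm.
#' @return An object of class `"label_grid"`.
#' @export
label_grid <- function(labels, voxel_size) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3-D array", call. = FALSE)
  }
  if (!all(labels %in% 0:3)) {
    stop("labels must be integers in {0 (background), 1 (air), 2 (marrow), 3 (bone)}",
         call. = FALSE)
  }
  if (length(voxel_size) != 1L || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive length", call. = FALSE)
  }
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "label_grid")
}

#' Segment a grey-value grid into air, marrow and bone by thresholding
#'
#' Inside the mask, a voxel with grey value `g` is labelled air if
#' `g < t_air_marrow`, marrow if `t_air_marrow <= g < t_marrow_bone`, and
#' bone if `g >= t_marrow_bone` (half-open intervals, the denser tissue wins
#' at a boundary). Voxels outside the mask are background. This mirrors
#' density-ordered grey values in CT: air darkest, bone brightest.
#'
#' @param grid A [voxel_grid()].
#' @param thresholds A [threshold_set()].
#' @param mask Logical array of the same shape as the grid; `NULL` means all
#'   voxels are inside. Mask construction is the caller's responsibility
#'   (phantoms carry their own).
#' @param median_filter If `TRUE`, a 7-point (face-neighbour) median filter
#'   is applied to the grey values before thresholding. Off by default:
#'   plain grey-value thresholding is the reference behaviour.
#' @return A [label_grid()].
#' @export
segment_grid <- function(grid, thresholds, mask = NULL, median_filter = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(thresholds, "threshold_set"))
  vals <- grid$values
  if (is.null(mask)) {
    mask <- array(TRUE, dim = dim(vals))
  }
  if (!identical(dim(mask), dim(vals))) {
    stop("`mask` must have the same shape as the grid", call. = FALSE)
  }
  if (isTRUE(median_filter)) {
    vals <- .median_filter7(vals)
  }
  labs <- array(0L, dim = dim(vals))
  labs[mask & vals < thresholds$t_air_marrow] <- 1L
  labs[mask & vals >= thresholds$t_air_marrow &
         vals < thresholds$t_marrow_bone] <- 2L
  labs[mask & vals >= thresholds$t_marrow_bone] <- 3L
  label_grid(labs, grid$voxel_size)
}

# median over the 6 face neighbours plus the centre; edges replicate
.median_filter7 <- function(a) {
  d <- dim(a)
  shift <- function(axis, by) {
    idx <- lapply(d, seq_len)
    i <- idx[[axis]] - by
    idx[[axis]] <- pmin(pmax(i, 1L), d[axis])
    do.call(`[`, c(list(a), idx))
  }
  stack <- c(list(a),
             lapply(1:3, shift, by = 1L),
             lapply(1:3, shift, by = -1L))
  m <- array(0, dim = d)
  flat <- vapply(stack, as.numeric, numeric(length(a)))
  m[] <- apply(flat, 1L, median)
  m
}

#' Convert label counts to physical tissue volumes
#'
#' Each tissue volume is its voxel count multiplied by the voxel volume
#' (`voxel_size^3`), in mm^3.
#'
#' @param labels A [label_grid()].
#' @return A [tissue_volumes()].
#' @examples
#' lg <- label_grid(array(c(rep(1L, 10), rep(0L, 17)), dim = c(3, 3, 3)), 0.1)
#' measure_volumes(lg)$v_air  # 10 voxels x 0.001 mm^3
#' @export
measure_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_grid"))
  vv <- labels$voxel_size^3
  tab <- tabulate(labels$labels + 1L, nbins = 4L)  # background, air, marrow, bone
  tissue_volumes(v_bone = tab[4] * vv, v_marrow = tab[3] * vv, v_air = tab[2] * vv)
}

#' Scan-resolution quality check
#'
#' Computes the ratio of element diameter to scan resolution (voxel size).
#' In practice ratios of roughly 22 to 121 are typical of whole-specimen
#' microCT of bird humeri; the quality flag passes when the ratio meets the
#' lower end of that range.
#'
#' @param diameter Element diameter (dorsoventral), mm.
#' @param voxel_size Scan resolution, mm.
#' @param min_ratio Minimum acceptable ratio (default 22).
#' @return A list with `ratio` and logical `pass`.
#' @examples
#' resolution_ratio(2.2, 0.1)   # ratio 22, pass
#' resolution_ratio(1.0, 0.1)   # ratio 10, fail
#' @export
resolution_ratio <- function(diameter, voxel_size, min_ratio = 22) {
  if (!is.numeric(diameter) || !is.numeric(voxel_size) ||
      diameter <= 0 || voxel_size <= 0) {
    stop("`diameter` and `voxel_size` must be positive", call. = FALSE)
  }
  r <- diameter / voxel_size
  list(ratio = r, pass = r >= min_ratio)
}
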