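#' Tissue volume triple for a single skeletal element
#'
#' Bundles the bone, marrow and air volumes (in mm^3) measured for one
#' element, together with the derived internal-cavity volume
#' (`v_internal = v_air + v_marrow`) and total element volume
#' (`v_total = v_air + v_marrow + v_bone`).
#'
#' @param v_bone,v_marrow,v_air Non-negative volumes in mm^3.
#' @return An object of class `"tissue_volumes"`: a list with elements
#'   `v_bone`, `v_marrow`, `v_air`, `v_internal`, `v_total`.
#' @examples
#' tv <- tissue_volumes(v_bone = 100, v_marrow = 40, v_air = 60)
#' tv$v_internal  # 100
#' tv$v_total     # 200
#' @export
tissue_volumes <- function(v_bone, v_marrow, v_air) {
  vals <- c(v_bone = v_bone, v_marrow = v_marrow, v_air = v_air)
  if (!is.numeric(vals) || length(vals) != 3L || anyNA(vals)) {
    stop("volumes must be three non-missing numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("tissue volumes must be non-negative", call. = FALSE)
  }
  structure(
    list(
      v_bone = unname(v_bone),
      v_marrow = unname(v_marrow),
      v_air = unname(v_air),
      v_internal = unname(v_air + v_marrow),
      v_total = unname(v_air + v_marrow + v_bone)
    ),
    class = "tissue_volumes"
  )
}

#' @export
print.tissue_volumes <- function(x, ...) {
  cat(sprintf(
    "Tissue volumes (mm^3): bone %.4g, marrow %.4g, air %.4g (internal %.4g, total %.4g)\n",
    x$v_bone, x$v_marrow, x$v_air, x$v_internal, x$v_total
  ))
  invisible(x)
}

.as_tissue_volumes <- function(x) {
  if (inherits(x, "tissue_volumes")) return(x)
  if (is.list(x) && all(c("v_bone", "v_marrow", "v_air") %in% names(x))) {
    return(tissue_volumes(x$v_bone, x$v_marrow, x$v_air))
  }
  stop("expected a 'tissue_volumes' object", call. = FALSE)
}
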