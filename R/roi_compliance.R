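# Flow-territory ROIs from the TI = 750 ms mean difference image, the
# compliance map from diastolic/systolic aBV and cuff pressures, and
# territory summaries.

#' Brachial blood pressures
#'
#' Averages repeated cuff readings (one per scan series in the intended
#' protocol) into systolic and diastolic pressures and the pulse pressure.
#'
#' @param sys Systolic readings (mm Hg); scalar or vector, averaged.
#' @param dia Diastolic readings (mm Hg); scalar or vector, averaged.
#' @return An object of class `blood_pressures` with fields `bp_sys`,
#'   `bp_dia`, `pp`.
#' @export
blood_pressures <- function(sys, dia) {
  bp_sys <- mean(sys)
  bp_dia <- mean(dia)
  if (!(bp_sys > bp_dia && bp_dia > 0))
    stop("invalid pressures: need systolic > diastolic > 0")
  structure(list(bp_sys = bp_sys, bp_dia = bp_dia, pp = bp_sys - bp_dia),
            class = "blood_pressures")
}

#' Per-slice percentile intensity mask
#'
#' Keeps, independently for each slice, the voxels strictly above that
#' slice's `pct`-th intensity percentile — by default the brightest 5% of
#' the mean difference image, which at short TI are the large-artery voxels.
#' A constant slice yields an empty slice mask with a warning.
#'
#' @param image 3D numeric array (the TI = 750 ms mean difference image in
#'   the intended pipeline).
#' @param pct Percentile threshold (default 95).
#' @return Logical array of the same dimensions.
#' @export
percentile_mask <- function(image, pct = 95) {
  stopifnot(length(dim(image)) == 3, pct > 0, pct < 100)
  d <- dim(image)
  mask <- array(FALSE, d)
  for (s in seq_len(d[3])) {
    slice <- image[, , s]
    if (diff(range(slice, na.rm = TRUE)) == 0) {
      warning(sprintf("percentile_mask: slice %d is constant; empty mask", s))
      next
    }
    thr <- stats::quantile(slice, pct / 100, na.rm = TRUE, names = FALSE)
    mask[, , s] <- !is.na(slice) & slice > thr
  }
  mask
}

#' Flow-territory ROIs
#'
#' Intersects the thresholded difference mask with broad, manually drawn (or
#' phantom) territory label masks: `ROI_k = mask & (labels == k)`. Empty
#' territories are retained with a warning.
#'
#' @param mask Logical 3D array from [percentile_mask()].
#' @param broad_labels Integer 3D array of disjoint territory labels
#'   (0 = background).
#' @param label_names Optional named integer vector mapping names to label
#'   values, e.g. `c(RMCA = 1, LMCA = 2, ACA = 3, RPCA = 4, LPCA = 5)`.
#' @return An object of class `roi_set`: integer `labels` array restricted
#'   to the mask, plus the `label_names` table.
#' @export
territory_rois <- function(mask, broad_labels, label_names = NULL) {
  stopifnot(all(dim(mask) == dim(broad_labels)))
  vals <- sort(setdiff(unique(as.integer(broad_labels)), 0L))
  if (is.null(label_names)) {
    label_names <- stats::setNames(vals, paste0("territory", vals))
  }
  labels <- array(0L, dim(mask))
  labels[mask] <- as.integer(broad_labels[mask])
  for (v in vals) {
    if (!any(labels == v))
      warning(sprintf("territory_rois: territory %s is empty after masking",
                      names(label_names)[label_names == v]))
  }
  structure(list(labels = labels, label_names = label_names),
            class = "roi_set")
}

#' Arterial compliance map
#'
#' Percentage change in aBV from diastole to systole per mm Hg of pulse
#' pressure (arterial distensibility):
#' \deqn{AC = 100\,\frac{aBV_{sys} - aBV_{dia}}{aBV_{dia}\cdot PP}.}
#' Voxels with non-positive or missing diastolic aBV get `NA`, never
#' infinity.
#'
#' @param abv_dia,abv_sys 3D aBV maps (%v) for the diastolic and systolic
#'   bins.
#' @param bp A [blood_pressures()] object (its `pp` is used).
#' @return 3D AC map in %/mm Hg.
#' @export
compliance_map <- function(abv_dia, abv_sys, bp) {
  stopifnot(inherits(bp, "blood_pressures"), all(dim(abv_dia) == dim(abv_sys)))
  if (bp$pp <= 0) stop("invalid pressures: pulse pressure must be positive")
  ac <- 100 * (abv_sys - abv_dia) / (abv_dia * bp$pp)
  ac[!is.finite(ac) | is.na(abv_dia) | abv_dia <= 0] <- NA_real_
  ac
}

#' Territory summary of a map
#'
#' Median (not mean) of a voxel map over each territory ROI, optionally
#' restricted to one slice (the slice just above the circle of Willis in the
#' intended protocol). Empty territories yield `NA`.
#'
#' @param map 3D numeric array.
#' @param rois A [territory_rois()] result.
#' @param slice Optional 1-based slice index restriction.
#' @return A data.frame with columns `territory`, `value`, `n_voxels`.
#' @export
territory_summary <- function(map, rois, slice = NULL) {
  stopifnot(inherits(rois, "roi_set"), all(dim(map) == dim(rois$labels)))
  sel <- array(TRUE, dim(map))
  if (!is.null(slice)) {
    sel[] <- FALSE
    sel[, , slice] <- TRUE
  }
  rows <- lapply(seq_along(rois$label_names), function(k) {
    v <- rois$label_names[k]
    idx <- rois$labels == v & sel
    vals <- map[idx]
    vals <- vals[is.finite(vals)]
    data.frame(territory = names(rois$label_names)[k],
               value = if (length(vals)) stats::median(vals) else NA_real_,
               n_voxels = length(vals))
  })
  do.call(rbind, rows)
}

#' aBV change over the cardiac cycle
#'
#' Multiplying compliance by the pulse pressure gives the total percentage
#' change in aBV between diastole and systole.
#'
#' @param ac Compliance (%/mm Hg); scalar, vector or map.
#' @param pp Pulse pressure (mm Hg), positive.
#' @return Percent aBV change over the cardiac cycle, same shape as `ac`.
#' @export
cycle_change <- function(ac, pp) {
  stopifnot(pp > 0)
  ac * pp
}
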