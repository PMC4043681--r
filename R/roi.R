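# Region-of-interest definition: axial slice segments (metaphysis,
# diaphysis) and the cortical/trabecular compartment split.

#' Number of axial slices spanning a physical length
#'
#' Converts a segment length in millimetres to a slice count at the given
#' isotropic voxel size, rounding up so the segment always covers at least
#' the requested length (2.48 mm at 12 um gives 207 slices).
#'
#' @param length_mm Segment length in millimetres (> 0).
#' @param voxel_size Voxel edge in micrometres (> 0).
#' @return Integer slice count.
#' @examples
#' slices_for_length(2.48, 12) # 207
#' @export
slices_for_length <- function(length_mm, voxel_size) {
  if (!(is.numeric(length_mm) && length_mm > 0))
    stop("`length_mm` must be positive", call. = FALSE)
  if (!(is.numeric(voxel_size) && voxel_size > 0))
    stop("`voxel_size` must be positive", call. = FALSE)
  # guard against floating-point excess just above an exact multiple
  as.integer(ceiling(length_mm * 1000 / voxel_size - 1e-9))
}

#' Axial region specification
#'
#' @param name Region label (`"metaphysis"`, `"diaphysis"`, or custom).
#' @param start_slice 0-based index of the first slice along the long axis.
#' @param length_mm Segment length in millimetres.
#' @param compartment_mode `"trabecular_only"` (used for BV/TV and Conn.D,
#'   where cortical bone is excluded) or `"whole_bone"` (used for the degree
#'   of anisotropy, where cortical and trabecular bone are both included).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, start_slice, length_mm,
                        compartment_mode = c("trabecular_only", "whole_bone")) {
  compartment_mode <- match.arg(compartment_mode)
  stopifnot(is.character(name), length(name) == 1L,
            start_slice >= 0, start_slice == round(start_slice),
            length_mm > 0)
  structure(list(name = name, start_slice = as.integer(start_slice),
                 length_mm = length_mm, compartment_mode = compartment_mode),
            class = "region_spec")
}

#' Extract an axial segment from a volume or mask
#'
#' Crops a contiguous run of axial slices. Slice indexing is 0-based and the
#' segment is the half-open interval `[start, start + n)`, so adjacent
#' segments partition their union without overlap. The 0-based offset is
#' recorded in the result's `roi_offset` attribute.
#'
#' @param x A [density_volume] or [binary_volume].
#' @param spec A [region_spec].
#' @return The same type as `x`, cropped.
#' @export
extract_segment <- function(x, spec) {
  stopifnot(inherits(spec, "region_spec"))
  d <- dim(x)
  vs <- x$voxel_size
  n <- slices_for_length(spec$length_mm, vs)
  lo <- spec$start_slice + 1L          # 1-based first slice
  hi <- spec$start_slice + n           # 1-based last slice
  if (lo < 1L || hi > d[1])
    stop(sprintf("segment [%d, %d) out of bounds for %d slices",
                 spec$start_slice, spec$start_slice + n, d[1]), call. = FALSE)
  out <- if (inherits(x, "density_volume")) {
    density_volume(x$values[lo:hi, , , drop = FALSE], vs)
  } else if (inherits(x, "binary_volume")) {
    binary_volume(x$mask[lo:hi, , , drop = FALSE], vs, x$provenance)
  } else stop("expected a density_volume or binary_volume", call. = FALSE)
  attr(out, "roi_offset") <- spec$start_slice
  attr(out, "roi_name") <- spec$name
  out
}

# morphological closing with zero padding so dilation is never clipped at
# the slice border (border clipping would inflate the closed set)
closing_padded <- function(M, radius) {
  pr <- as.integer(radius) + 1L
  P <- matrix(0, nrow(M) + 2L * pr, ncol(M) + 2L * pr)
  P[pr + seq_len(nrow(M)), pr + seq_len(ncol(M))] <- M
  C <- EBImage::closing(P, EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc"))
  C[pr + seq_len(nrow(M)), pr + seq_len(ncol(M))] > 0
}

# per-slice compartment split; returns cortical/trabecular bone masks plus
# the medullary (endosteal-envelope) region mask
split_slice <- function(S, close_radius, marrow_close_radius, solid_fraction) {
  if (!any(S)) {
    z <- S & FALSE
    return(list(cortical = z, trabecular = z, medullary = z, fallback = FALSE))
  }
  storage.mode(S) <- "double"
  # background connected to the slice border = exterior; the rest is
  # enclosed marrow (the medullary + inter-trabecular space)
  lab <- EBImage::bwlabel(1 - S)
  border_labs <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                                  lab[, ncol(lab)])), 0)
  interior_bg <- lab > 0 & !(lab %in% border_labs)
  dim(interior_bg) <- dim(S)
  Sl <- S > 0
  if (!any(interior_bg)) {
    # no enclosed cavity: either a solid structure (all cortical) or an
    # open lattice with no closed cortex (fallback: all trabecular)
    closed <- closing_padded(S, close_radius)
    storage.mode(closed) <- "double"
    sil <- EBImage::fillHull(closed) > 0
    frac <- if (any(sil)) sum(Sl & sil) / sum(sil) else 0
    if (frac >= solid_fraction)
      return(list(cortical = Sl, trabecular = Sl & FALSE, medullary = Sl & FALSE,
                  fallback = FALSE))
    return(list(cortical = Sl & FALSE, trabecular = Sl,
                medullary = Sl | TRUE, fallback = TRUE))
  }
  # close the enclosed marrow over the thin trabecular elements it surrounds;
  # the closed medullary region delimits the endosteal envelope
  ib <- interior_bg
  storage.mode(ib) <- "double"
  med <- closing_padded(ib, marrow_close_radius) | interior_bg
  list(cortical = Sl & !med, trabecular = Sl & med, medullary = med,
       fallback = FALSE)
}

#' Split a bone mask into cortical and trabecular compartments
#'
#' Slice-by-slice morphological procedure: background connected to the slice
#' border is exterior; enclosed background is marrow. Closing the marrow with
#' a small disk bridges it across thin trabecular elements, yielding the
#' endosteal (medullary) envelope; bone inside that envelope is trabecular
#' and the remaining bone -- the shell between endosteum and periosteum,
#' plus any periosteal deposits -- is cortical. Slices with no closed cortex
#' fall back to all-trabecular with a warning; solid cross-sections with no
#' cavity are all cortical. The two masks are always disjoint and cover
#' every bone voxel.
#'
#' @param mask A non-empty [binary_volume].
#' @param close_radius Disk radius (voxels) for the silhouette closing used
#'   to decide whether a cavity-free slice is solid. Default 10.
#' @param marrow_close_radius Disk radius (voxels) for closing the marrow
#'   over trabeculae; should exceed half the trabecular thickness. Default 3.
#' @param solid_fraction Minimum bone fraction of the closed silhouette for
#'   a cavity-free slice to count as solid cortex. Default 0.75.
#' @return An object of class `compartment_masks`: logical arrays
#'   `cortical` and `trabecular` (bone), `medullary` (the endosteal-envelope
#'   region, bone plus marrow, used as the total volume for trabecular
#'   indices), and the integer vector `fallback_slices`.
#' @export
split_compartments <- function(mask, close_radius = 10, marrow_close_radius = 3,
                               solid_fraction = 0.75) {
  A <- as_mask_array(mask)
  if (!any(A)) stop("empty bone mask: nothing to split", call. = FALSE)
  d <- dim(A)
  cortical <- array(FALSE, d)
  trabecular <- array(FALSE, d)
  medullary <- array(FALSE, d)
  fallback <- integer(0)
  for (i in seq_len(d[1])) {
    res <- split_slice(A[i, , ], close_radius, marrow_close_radius,
                       solid_fraction)
    cortical[i, , ] <- res$cortical
    trabecular[i, , ] <- res$trabecular
    medullary[i, , ] <- res$medullary
    if (res$fallback) fallback <- c(fallback, i)
  }
  if (length(fallback))
    warning(sprintf("%d slice(s) had no closed cortex; fell back to all-trabecular",
                    length(fallback)), call. = FALSE)
  structure(list(cortical = cortical, trabecular = trabecular,
                 medullary = medullary, fallback_slices = fallback,
                 voxel_size = if (inherits(mask, "binary_volume")) mask$voxel_size else NA_real_),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf("<compartment_masks> cortical %d voxels, trabecular %d voxels, %d fallback slice(s)\n",
              sum(x$cortical), sum(x$trabecular), length(x$fallback_slices)))
  invisible(x)
}
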