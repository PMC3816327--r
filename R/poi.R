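#' Benjamini-Hochberg false-discovery-rate thresholding
#'
#' Step-up FDR rule: with ordered p-values p(1) <= ... <= p(m), reject the k
#' smallest where k = max{ i : p(i) <= i q / m }.  Returns the indices of
#' rejected hypotheses and the realized critical p-value.
#'
#' @param p Vector of p-values in [0, 1].
#' @param q FDR level, default 0.01.
#' @return A list: `rejected` (integer indices into `p`), `critical_p`
#'   (largest rejected p, 0 if none), `q`.
#' @export
fdr_threshold <- function(p, q = 0.01) {
  stopifnot(q > 0, q <= 1)
  if (!length(p))
    return(list(rejected = integer(0), critical_p = 0, q = q))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  rejected <- which(stats::p.adjust(p, method = "BH") <= q)
  list(rejected = rejected,
       critical_p = if (length(rejected)) max(p[rejected]) else 0,
       q = q)
}

#' Construct a patch of interest
#'
#' @param name Region name.
#' @param voxels Integer voxel indices (deduplicated, sorted).
#' @param threshold Defining t threshold.
#' @param contrast Label of the defining contrast.
#' @return An object of class `fd_poi`.
#' @export
poi <- function(name, voxels, threshold = NA_real_, contrast = "") {
  structure(list(name = name, voxels = sort(unique(as.integer(voxels))),
                 threshold = threshold, contrast = contrast),
            class = "fd_poi")
}

#' @export
print.fd_poi <- function(x, ...) {
  cat("POI", x$name, ":", length(x$voxels), "voxels (contrast ",
      x$contrast, ", threshold", x$threshold, ")\n")
  invisible(x)
}

#' Define eye and mouth patches from the feature-mapping contrast
#'
#' Splits the eye-minus-mouth t map at a symmetric threshold: voxels with
#' t >= +threshold form the eye patch, voxels with t <= -threshold the
#' mouth patch.  The two patches are disjoint by construction.  An empty
#' patch triggers a warning, not an error (thresholds may then be lowered
#' by the caller).
#'
#' @param tmap An `fd_tmap` for the eye-minus-mouth contrast.
#' @param threshold Positive t threshold (kept above 3.2 by default).
#' @return A list with `eye` and `mouth` `fd_poi` objects.
#' @export
define_feature_pois <- function(tmap, threshold = 3.2) {
  if (threshold <= 0) stop("'threshold' must be positive")
  eye <- which(tmap$t >= threshold)
  mouth <- which(tmap$t <= -threshold)
  if (!length(eye) || !length(mouth))
    warning("empty feature patch at threshold ", threshold)
  list(eye = poi("eye", eye, threshold, "eye-mouth"),
       mouth = poi("mouth", mouth, -threshold, "eye-mouth"))
}

#' Set of stimulus-responsive voxels
#'
#' Voxels whose all-faces-versus-baseline activation survives a corrected
#' threshold (Bonferroni over voxels by default, alpha 0.0001), used to
#' restrict region definitions to voxels actually sampled by the main
#' experiment.
#'
#' @param tmap An `fd_tmap` for the faces-minus-baseline contrast.
#' @param alpha Corrected significance level.
#' @param method Multiple-comparison correction passed to
#'   [stats::p.adjust()].
#' @return Integer voxel indices.
#' @export
responsive_map <- function(tmap, alpha = 1e-4, method = "bonferroni") {
  p <- tmap_p(tmap, "greater")
  which(stats::p.adjust(p, method = method) <= alpha)
}

#' Rest-of-V1 patch via the dilation-subtraction rule
#'
#' Grows the eye and mouth patches by re-thresholding the feature contrast
#' at a lowered threshold, subtracts the grown patches from the V1 mask (so
#' the rest region is not immediately adjacent to the feature patches), and
#' intersects the remainder with the responsive-voxel map.
#'
#' @param v1_mask Integer voxel indices of the V1 mask.
#' @param tmap An `fd_tmap` for the eye-minus-mouth contrast.
#' @param strict_threshold Threshold used for the feature patches.
#' @param lowered_threshold Lowered threshold used for dilation; must be
#'   smaller than `strict_threshold`.
#' @param responsive Integer voxel indices from [responsive_map()].
#' @return An `fd_poi` named `rest_v1`.
#' @export
rest_of_v1 <- function(v1_mask, tmap, strict_threshold = 3.2,
                       lowered_threshold = 1.5, responsive) {
  if (lowered_threshold >= strict_threshold)
    stop("'lowered_threshold' must be below 'strict_threshold'")
  dilated <- which(abs(tmap$t) >= lowered_threshold)
  rest <- setdiff(intersect(v1_mask, responsive), dilated)
  poi("rest_v1", rest, lowered_threshold, "v1 - dilated(eye,mouth)")
}
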