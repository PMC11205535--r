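## Nucleoid morphometry from fluorescence images.

# side lengths of the bounding rectangle of a rasterised rod, estimated
# from second moments: a uniform rectangle of sides L x W has axis
# variances L^2/12 and W^2/12, and a pixel contributes 1/12 of within-
# pixel variance per axis, so sqrt(12 * (eigenvalue + 1/12)) recovers the
# sides exactly for an axis-aligned block and within a pixel for rotated
# rods (extent-of-hull measures are biased by up to ~1.4 px on jagged
# rasters).  Returns c(length, width), length >= width.
.rectDims <- function(centers) {
    if (nrow(centers) == 1L) return(c(1, 1))
    S <- stats::cov(centers) * (nrow(centers) - 1) / nrow(centers) +
        diag(1 / 12, 2)
    lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    dims <- sqrt(12 * pmax(lam, 0))
    c(max(dims), min(dims))
}

#' Segment nucleoids in a single-channel fluorescence image
#'
#' Thresholds the image (Otsu's method by default, as appropriate for a
#' DAPI channel), labels connected components, drops components below
#' `minArea` pixels and measures each remaining region's bounding
#' rectangle along its own principal axes (a moment estimator, exact for
#' rectangular rods): the long side is the nucleoid length, the short
#' side the width.
#'
#' @param image numeric matrix of pixel intensities (rows = y, cols = x).
#' @param threshold absolute intensity threshold; `NULL` (default) selects
#'   it automatically by Otsu's method.
#' @param minArea minimum component area in pixels (default 20).
#' @return a `data.frame` with one row per region: `region`, `area`
#'   (pixels), `length`, `width` (pixels, length >= width), `cx`, `cy`
#'   (centroid).  Zero rows when nothing is detected.
#' @export
segmentNucleoids <- function(image, threshold = NULL, minArea = 20) {
    if (!is.matrix(image) || !is.numeric(image))
        stop("image must be a numeric 2D matrix", call. = FALSE)
    rng <- range(image)
    if (diff(rng) == 0) {
        mask <- matrix(FALSE, nrow(image), ncol(image))
    } else if (is.null(threshold)) {
        norm <- (image - rng[1L]) / diff(rng)
        th <- EBImage::otsu(EBImage::Image(norm))
        mask <- norm > th
    } else {
        mask <- image > threshold
    }
    empty <- data.frame(region = integer(0), area = integer(0),
                        length = numeric(0), width = numeric(0),
                        cx = numeric(0), cy = numeric(0))
    if (!any(mask)) return(empty)
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(lab)
    regions <- sort(setdiff(unique(as.vector(lab)), 0))
    out <- lapply(regions, function(r) {
        idx <- which(lab == r, arr.ind = TRUE)
        if (nrow(idx) < minArea) return(NULL)
        y <- idx[, 1L]; x <- idx[, 2L]
        centers <- cbind(x, y)
        dims <- .rectDims(centers)
        len <- dims[1L]; wid <- dims[2L]
        data.frame(region = r, area = nrow(idx),
                   length = max(len, wid), width = min(len, wid),
                   cx = mean(x), cy = mean(y))
    })
    out <- do.call(rbind, out)
    if (is.null(out)) return(empty)
    out$region <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

#' Convert region measurements to physical units
#'
#' @param regions a `data.frame` from [segmentNucleoids()].
#' @param pixelSize physical pixel size in micrometres per pixel.
#' @return the same `data.frame` with `length`, `width` (and `cx`, `cy`)
#'   scaled to micrometres.
#' @export
measureMorphometry <- function(regions, pixelSize) {
    stopifnot(pixelSize > 0)
    regions$length <- regions$length * pixelSize
    regions$width <- regions$width * pixelSize
    if ("cx" %in% names(regions)) {
        regions$cx <- regions$cx * pixelSize
        regions$cy <- regions$cy * pixelSize
    }
    regions
}

#' Compare two morphometric samples
#'
#' Two-sided rank-based comparison (Mann-Whitney U / Wilcoxon rank-sum,
#' the default) or Welch's t-test, with the conventional significance
#' code: `ns` for p > 0.05 down to `****` for p <= 0.0001.
#'
#' @param a,b numeric samples (each `n >= 3`).
#' @param method `"wilcox"` (default) or `"welch"`.
#' @return a list with `statistic`, `p`, `code` and `method`.
#' @export
compareGroups <- function(a, b, method = c("wilcox", "welch")) {
    method <- match.arg(method)
    if (length(a) < 3 || length(b) < 3)
        stop("each sample needs n >= 3", call. = FALSE)
    if (length(unique(c(a, b))) == 1L)
        stop("degenerate samples: all values identical", call. = FALSE)
    ht <- if (method == "wilcox")
        suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = FALSE, correct = TRUE))
    else t.test(a, b, alternative = "two.sided", var.equal = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         code = significanceCode(ht$p.value), method = method)
}
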