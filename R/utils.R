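#' Circular genomic distance between bins
#'
#' Distance in bins between bin indices `i` and `j` on a binning with `n`
#' bins; wraps around the origin when the binning is circular.
#'
#' @param i,j 1-based bin indices (vectorised).
#' @param n number of bins.
#' @param circular wrap around the origin (default `TRUE`).
#' @return integer distances in bins.
#' @examples
#' circularBinDistance(1, 928, 928)  # 1, not 927
#' @export
circularBinDistance <- function(i, j, n, circular = TRUE) {
    d <- abs(i - j)
    if (circular) pmin(d, n - d) else d
}

# wrap a 1-based bin index onto 1..n
.wrap <- function(i, n) ((i - 1L) %% n) + 1L

# stop unless the two objects share an identical binning
.checkSameBinning <- function(a, b) {
    ba <- binning(a); bb <- binning(b)
    if (ba@nBins != bb@nBins || ba@binSize != bb@binSize ||
        ba@circular != bb@circular)
        stop("binning mismatch between inputs", call. = FALSE)
    invisible(TRUE)
}

# significance code used in figure annotations
#' Map a p-value to a significance code
#'
#' `ns` for p > 0.05, then `*`, `**`, `***`, `****` at the conventional
#' 0.05 / 0.01 / 0.001 / 0.0001 thresholds (boundaries inclusive).
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of codes.
#' @examples
#' significanceCode(c(0.2, 0.05, 0.0001))
#' @export
significanceCode <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
        labels = c("****", "***", "**", "*", "ns"),
        right = TRUE) |> as.character()
}
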