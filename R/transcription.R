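## Binned transcription tracks and structure-expression correlation.

#' Allocate per-gene expression into genome bins
#'
#' Each gene's expression value (e.g. FPKM) is distributed over the bins it
#' overlaps, proportionally to the overlap length (or entirely to its start
#' bin with `method = "start"`).  The binned totals are log2(1 + x)
#' transformed — the +1 keeps empty bins at level 0 — and Z-scored.
#'
#' @param genes a `data.frame` with columns `start`, `end` (1-based closed
#'   coordinates) and `fpkm` (>= 0), or a `GRanges` with an `fpkm`
#'   metadata column.
#' @param binning a [GenomeBinning].
#' @param method `"proportional"` (default) or `"start"`.
#' @param source provenance label.
#' @return a [TranscriptionTrack].
#' @examples
#' b <- GenomeBinning(10 * 5000, 5000)
#' g <- data.frame(start = 1, end = 5000, fpkm = 8)
#' trackLevel(binTranscription(g, b))[1]   # log2(9)
#' @export
binTranscription <- function(genes, binning,
                             method = c("proportional", "start"),
                             source = "") {
    method <- match.arg(method)
    if (is(genes, "GRanges")) {
        genes <- data.frame(start = GenomicRanges::start(genes),
                            end = GenomicRanges::end(genes),
                            fpkm = genes$fpkm)
    }
    n <- binning@nBins
    bs <- binning@binSize
    level <- numeric(n)
    if (nrow(genes)) {
        if (any(genes$end < genes$start))
            stop("gene end < start", call. = FALSE)
        if (any(genes$start < 1) || any(genes$end > binning@genomeLength))
            stop("gene coordinates beyond genome length", call. = FALSE)
        if (any(genes$fpkm < 0)) stop("negative FPKM", call. = FALSE)
        for (k in seq_len(nrow(genes))) {
            gs <- genes$start[k]; ge <- genes$end[k]; x <- genes$fpkm[k]
            if (method == "start") {
                b1 <- floor((gs - 1) / bs) + 1L
                level[b1] <- level[b1] + x
            } else {
                bins <- .binsInInterval(binning, gs, ge)
                binStart <- (bins - 1) * bs + 1
                binEnd <- pmin(bins * bs, binning@genomeLength)
                ov <- pmin(ge, binEnd) - pmax(gs, binStart) + 1
                level[bins] <- level[bins] + x * ov / (ge - gs + 1)
            }
        }
    }
    level <- log2(1 + level)
    z <- if (sd(level) == 0) rep(NA_real_, n) else zscoreTrack(level)
    new("TranscriptionTrack", binning = binning, level = level,
        zscore = z, source = as.character(source))
}

#' Read a gene expression table
#'
#' TSV with columns `gene_id`, `start`, `end`, `strand`, `fpkm` (header
#' required; extra columns ignored).
#'
#' @param path file path.
#' @return a `data.frame` suitable for [binTranscription()].
#' @export
readExpressionTable <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("start", "end", "fpkm")
    if (!all(need %in% names(tab)))
        stop("expression table needs columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    tab
}

#' Near-diagonal contact frequency per bin
#'
#' Mean contact frequency of each bin with its neighbourhood within
#' `halfWidth` base pairs up- and downstream (diagonal included); with
#' `halfWidth = 0` this is exactly the matrix diagonal.  This is the
#' per-bin interaction signal correlated with transcription.
#'
#' @param M a [ContactMatrix].
#' @param halfWidth half-width in base pairs (default 10 kb).
#' @return numeric vector, one value per bin.
#' @export
diagBandFrequency <- function(M, halfWidth = 1e4) {
    v <- contactValues(M)
    n <- nrow(v)
    h <- as.integer(floor(halfWidth / binSize(M)))
    i <- seq_len(n)
    acc <- v[cbind(i, i)]
    if (h > 0) for (d in seq_len(h)) {
        acc <- acc + v[cbind(i, .wrap(i + d, n))] +
                     v[cbind(i, .wrap(i - d, n))]
    }
    acc / (2 * h + 1)
}

#' Z-score of a per-bin track
#'
#' `(x - mean) / SD` over non-missing bins, using the sample SD (n-1
#' denominator).  Missing entries stay missing.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
zscoreTrack <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("need at least 2 non-missing bins", call. = FALSE)
    s <- sd(x[ok])
    if (s == 0) stop("zero standard deviation: Z-score undefined",
                     call. = FALSE)
    (x - mean(x[ok])) / s
}

#' Pearson correlation between two per-bin tracks
#'
#' Pairs with a missing value in either track are dropped; the two-sided
#' p-value comes from the t distribution (`stats::cor.test`).
#'
#' @param a,b numeric vectors of equal length, or [TranscriptionTrack]
#'   objects (their Z-scores are used).
#' @return a list with `r`, `p` and `nPairs`.
#' @export
correlateTracks <- function(a, b) {
    if (is(a, "TranscriptionTrack")) a <- trackZscore(a)
    if (is(b, "TranscriptionTrack")) b <- trackZscore(b)
    if (length(a) != length(b))
        stop("tracks must have the same length", call. = FALSE)
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
    ct <- cor.test(a[ok], b[ok], method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, nPairs = sum(ok))
}
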