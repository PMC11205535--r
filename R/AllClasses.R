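#' @import methods
#' @importFrom stats quantile sd cor.test cmdscale rnorm rpois runif uniroot
#'   wilcox.test t.test complete.cases dist
#' @importFrom utils head read.table write.table
#' @importFrom graphics hist
#' @importFrom grDevices chull
NULL

## ---- GenomeBinning -------------------------------------------------------

#' Fixed-width binning of a (circular) genome
#'
#' Describes how a genome of `genomeLength` base pairs is partitioned into
#' consecutive bins of `binSize` base pairs.  Bacterial chromosomes are
#' circular, so genomic distances wrap around the origin by default.
#'
#' @slot genomeLength genome length in base pairs.
#' @slot binSize bin width in base pairs.
#' @slot nBins number of bins, `ceiling(genomeLength / binSize)`.
#' @slot circular logical; if `TRUE` distances wrap around the origin.
#'
#' @examples
#' GenomeBinning(4641652)           # E. coli MG1655 at 5 kb -> 929 bins
#' GenomeBinning(4640000)           # idealised 4.64 Mb genome -> 928 bins
#' @export
setClass("GenomeBinning",
    representation(genomeLength = "numeric", binSize = "numeric",
                   nBins = "integer", circular = "logical"),
    validity = function(object) {
        msg <- character()
        if (length(object@genomeLength) != 1L || object@genomeLength <= 0)
            msg <- c(msg, "genomeLength must be a single positive number")
        if (length(object@binSize) != 1L || object@binSize <= 0)
            msg <- c(msg, "binSize must be a single positive number")
        if (length(object@nBins) == 1L &&
            object@nBins != as.integer(ceiling(object@genomeLength / object@binSize)))
            msg <- c(msg, "nBins must equal ceiling(genomeLength / binSize)")
        if (length(msg)) msg else TRUE
    })

#' @param genomeLength genome length in base pairs.
#' @param binSize bin width in base pairs (default 5000).
#' @param circular logical; whether the genome is circular (default `TRUE`).
#' @rdname GenomeBinning-class
#' @export
GenomeBinning <- function(genomeLength, binSize = 5000, circular = TRUE) {
    new("GenomeBinning", genomeLength = as.numeric(genomeLength),
        binSize = as.numeric(binSize),
        nBins = as.integer(ceiling(genomeLength / binSize)),
        circular = isTRUE(circular))
}

setMethod("show", "GenomeBinning", function(object) {
    cat("GenomeBinning: ", object@nBins, " bins of ", object@binSize,
        " bp over ", object@genomeLength, " bp (",
        if (object@circular) "circular" else "linear", ")\n", sep = "")
})

#' Accessors for binning geometry
#'
#' `nBins()`, `binSize()`, `genomeLength()` and `isCircular()` work on a
#' [GenomeBinning] or on any object carrying one (contact matrices,
#' structures, tracks).
#'
#' @param x an object with a binning.
#' @return a scalar.
#' @name binning-accessors
NULL

#' @rdname binning-accessors
#' @export
setGeneric("binning", function(x) standardGeneric("binning"))
#' @rdname binning-accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @rdname binning-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname binning-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname binning-accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

setMethod("binning", "GenomeBinning", function(x) x)
setMethod("nBins", "ANY", function(x) binning(x)@nBins)
setMethod("binSize", "ANY", function(x) binning(x)@binSize)
setMethod("genomeLength", "ANY", function(x) binning(x)@genomeLength)
setMethod("isCircular", "ANY", function(x) binning(x)@circular)

## ---- ContactMatrix -------------------------------------------------------

#' Symmetric bin-by-bin chromosome contact matrix
#'
#' The central object of the pipeline: an `n x n` symmetric, non-negative
#' matrix of contact frequencies between genome bins, together with its
#' binning, a set of masked (low-coverage) bins and a normalisation flag.
#' Masked rows and columns are kept in place but forced to zero so that bin
#' indices always correspond to genomic position.
#'
#' @slot binning a [GenomeBinning].
#' @slot values numeric `n x n` matrix, symmetric and `>= 0`.
#' @slot mask integer vector of masked bin indices (1-based), possibly empty.
#' @slot normalized logical; `TRUE` after [scnNormalize()].
#'
#' @seealso [readContactMatrix()], [scnNormalize()], [distanceDecay()]
#' @export
setClass("ContactMatrix",
    representation(binning = "GenomeBinning", values = "matrix",
                   mask = "integer", normalized = "logical"),
    validity = function(object) {
        v <- object@values
        n <- object@binning@nBins
        msg <- character()
        if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
        if (nrow(v) != n)
            msg <- c(msg, sprintf("values is %dx%d but binning has %d bins",
                                  nrow(v), ncol(v), n))
        if (!all(is.finite(v))) msg <- c(msg, "values must be finite")
        else {
            if (any(v < 0)) msg <- c(msg, "values must be non-negative")
            if (max(abs(v - t(v))) > 1e-9)
                msg <- c(msg, "values must be symmetric (tolerance 1e-9)")
        }
        if (length(object@mask) &&
            (any(object@mask < 1L) || any(object@mask > n)))
            msg <- c(msg, "mask indices out of range")
        if (length(object@mask) && all(is.finite(v)) &&
            any(v[object@mask, ] != 0))
            msg <- c(msg, "masked rows/columns must be all-zero")
        if (length(msg)) msg else TRUE
    })

#' @param values numeric square matrix of contact frequencies.
#' @param binning a [GenomeBinning] matching `nrow(values)`.
#' @param mask integer vector of masked bin indices (1-based).
#' @param normalized logical normalisation flag.
#' @rdname ContactMatrix-class
#' @export
ContactMatrix <- function(values, binning, mask = integer(0),
                          normalized = FALSE) {
    mask <- sort(unique(as.integer(mask)))
    if (length(mask)) {
        values[mask, ] <- 0
        values[, mask] <- 0
    }
    new("ContactMatrix", binning = binning, values = values, mask = mask,
        normalized = isTRUE(normalized))
}

#' Accessors for ContactMatrix
#'
#' @param x a [ContactMatrix].
#' @return `contactValues()` the numeric matrix; `maskedBins()` the 1-based
#'   indices of masked bins; `isNormalized()` a logical flag.
#' @name ContactMatrix-accessors
NULL

#' @rdname ContactMatrix-accessors
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))
#' @rdname ContactMatrix-accessors
#' @export
setGeneric("maskedBins", function(x) standardGeneric("maskedBins"))
#' @rdname ContactMatrix-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

setMethod("contactValues", "ContactMatrix", function(x) x@values)
setMethod("maskedBins", "ContactMatrix", function(x) x@mask)
setMethod("isNormalized", "ContactMatrix", function(x) x@normalized)
setMethod("binning", "ContactMatrix", function(x) x@binning)

setMethod("show", "ContactMatrix", function(object) {
    n <- object@binning@nBins
    cat("ContactMatrix: ", n, " x ", n, " bins (",
        object@binning@binSize, " bp), ",
        if (object@normalized) "SCN-normalized" else "raw", ", ",
        length(object@mask), " masked bin(s)\n", sep = "")
    cat("  total contacts: ", format(sum(object@values), digits = 6), "\n",
        sep = "")
})

## ---- Structure3D ---------------------------------------------------------

#' 3D chromosome model: one point per genome bin
#'
#' Coordinates of a polymer model of the chromosome, one 3D point per bin in
#' genomic order, in arbitrary model units.  Rows that are entirely `NA`
#' denote bins missing from the model (e.g. masked bins); they are skipped
#' by all distance computations.
#'
#' @slot binning a [GenomeBinning].
#' @slot coords numeric `n x 3` matrix.
#' @slot label free-text condition label.
#'
#' @seealso [readStructure()], [globalCompactness()], [localCompactness()]
#' @export
setClass("Structure3D",
    representation(binning = "GenomeBinning", coords = "matrix",
                   label = "character"),
    validity = function(object) {
        msg <- character()
        if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
        if (nrow(object@coords) != object@binning@nBins)
            msg <- c(msg, "coords must have one row per bin")
        ok <- is.finite(object@coords) | is.na(object@coords)
        if (!all(ok)) msg <- c(msg, "coords must be finite or NA")
        if (length(msg)) msg else TRUE
    })

#' @param coords numeric `n x 3` coordinate matrix.
#' @param binning a [GenomeBinning].
#' @param label condition label (default `""`).
#' @rdname Structure3D-class
#' @export
Structure3D <- function(coords, binning, label = "") {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    new("Structure3D", binning = binning, coords = coords,
        label = as.character(label))
}

#' @rdname Structure3D-class
#' @param x a `Structure3D`.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
setMethod("coords", "Structure3D", function(x) x@coords)
setMethod("binning", "Structure3D", function(x) x@binning)

setMethod("show", "Structure3D", function(object) {
    pres <- sum(stats::complete.cases(object@coords))
    cat("Structure3D", if (nzchar(object@label))
        paste0(" [", object@label, "]"), ": ", pres, "/",
        object@binning@nBins, " bins with coordinates\n", sep = "")
})

## ---- DIProfile -----------------------------------------------------------

#' Per-bin directionality index
#'
#' The directionality index (DI) quantifies, for each bin, the bias between
#' its upstream and downstream contact sums within a genomic window; sign
#' alternations of the DI mark CID boundaries.  Upstream (`A`) and
#' downstream (`B`) sums are retained for audit.
#'
#' @slot binning a [GenomeBinning].
#' @slot di numeric DI per bin.
#' @slot upstream,downstream the window contact sums A and B per bin.
#' @slot window window size in base pairs.
#' @seealso [directionalityIndex()], [callCidBoundaries()]
#' @export
setClass("DIProfile",
    representation(binning = "GenomeBinning", di = "numeric",
                   upstream = "numeric", downstream = "numeric",
                   window = "numeric"),
    validity = function(object) {
        n <- object@binning@nBins
        msg <- character()
        if (length(object@di) != n) msg <- c(msg, "di must have one value per bin")
        if (!all(is.finite(object@di))) msg <- c(msg, "di must be finite")
        if (any(object@di[object@upstream == object@downstream] != 0))
            msg <- c(msg, "di must be 0 where upstream == downstream")
        if (length(msg)) msg else TRUE
    })

#' @rdname DIProfile-class
#' @param x a `DIProfile`.
#' @export
setGeneric("diValues", function(x) standardGeneric("diValues"))
setMethod("diValues", "DIProfile", function(x) x@di)
setMethod("binning", "DIProfile", function(x) x@binning)

setMethod("show", "DIProfile", function(object) {
    cat("DIProfile: ", object@binning@nBins, " bins, window ",
        object@window, " bp; ", sum(object@di > 0), " positive / ",
        sum(object@di < 0), " negative / ", sum(object@di == 0),
        " zero bins\n", sep = "")
})

## ---- BoundarySet ---------------------------------------------------------

#' CID boundaries for one condition
#'
#' Ordered bin indices (1-based) at which a chromosome interaction domain
#' starts.  On a circular genome the number of domains equals the number of
#' boundaries.
#'
#' @slot binning a [GenomeBinning].
#' @slot boundaries strictly increasing integer bin indices.
#' @slot conditionLabel free-text label.
#' @seealso [callCidBoundaries()], [compareBoundaries()]
#' @export
setClass("BoundarySet",
    representation(binning = "GenomeBinning", boundaries = "integer",
                   conditionLabel = "character"),
    validity = function(object) {
        b <- object@boundaries
        n <- object@binning@nBins
        msg <- character()
        if (length(b) && (any(b < 1L) || any(b > n)))
            msg <- c(msg, "boundaries out of [1, nBins]")
        if (is.unsorted(b, strictly = TRUE))
            msg <- c(msg, "boundaries must be strictly increasing")
        if (length(msg)) msg else TRUE
    })

#' @param boundaries integer bin indices (1-based).
#' @param binning a [GenomeBinning].
#' @param conditionLabel free-text label.
#' @rdname BoundarySet-class
#' @export
BoundarySet <- function(boundaries, binning, conditionLabel = "") {
    new("BoundarySet", binning = binning,
        boundaries = sort(unique(as.integer(boundaries))),
        conditionLabel = as.character(conditionLabel))
}

#' @rdname BoundarySet-class
#' @param x a `BoundarySet`.
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))
#' @rdname BoundarySet-class
#' @export
setGeneric("nCids", function(x) standardGeneric("nCids"))
setMethod("boundaries", "BoundarySet", function(x) x@boundaries)
setMethod("nCids", "BoundarySet", function(x) length(x@boundaries))
setMethod("binning", "BoundarySet", function(x) x@binning)

setMethod("show", "BoundarySet", function(object) {
    cat("BoundarySet", if (nzchar(object@conditionLabel))
        paste0(" [", object@conditionLabel, "]"), ": ",
        length(object@boundaries), " boundaries / CIDs\n", sep = "")
    if (length(object@boundaries))
        cat("  bins: ", paste(head(object@boundaries, 12), collapse = ", "),
            if (length(object@boundaries) > 12) ", ...", "\n", sep = "")
})

## ---- CompactnessProfile --------------------------------------------------

#' Global and multiscale local compactness of a 3D model
#'
#' Holds the scalar global compactness (GC) of a model together with
#' per-bin local compactness (LC) values computed at one or more genomic
#' scales.  Both metrics are dimensionless log2 ratios; larger values mean
#' a more compact fold.
#'
#' @slot binning a [GenomeBinning].
#' @slot gc scalar global compactness.
#' @slot lc numeric `n x length(scales)` matrix of LC values (NA for bins
#'   missing from the model).
#' @slot scales genomic scales (thresholds) in base pairs, ascending.
#' @seealso [globalCompactness()], [localCompactness()], [lcMultiscale()]
#' @export
setClass("CompactnessProfile",
    representation(binning = "GenomeBinning", gc = "numeric", lc = "matrix",
                   scales = "numeric"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@lc) != object@binning@nBins)
            msg <- c(msg, "lc must have one row per bin")
        if (ncol(object@lc) != length(object@scales))
            msg <- c(msg, "lc must have one column per scale")
        if (is.unsorted(object@scales, strictly = TRUE))
            msg <- c(msg, "scales must be strictly increasing")
        if (length(msg)) msg else TRUE
    })

#' @rdname CompactnessProfile-class
#' @param x a `CompactnessProfile`.
#' @export
setGeneric("lcValues", function(x) standardGeneric("lcValues"))
#' @rdname CompactnessProfile-class
#' @export
setGeneric("lcScales", function(x) standardGeneric("lcScales"))
#' @rdname CompactnessProfile-class
#' @export
setGeneric("gcValue", function(x) standardGeneric("gcValue"))
setMethod("lcValues", "CompactnessProfile", function(x) x@lc)
setMethod("lcScales", "CompactnessProfile", function(x) x@scales)
setMethod("gcValue", "CompactnessProfile", function(x) x@gc)
setMethod("binning", "CompactnessProfile", function(x) x@binning)

setMethod("show", "CompactnessProfile", function(object) {
    cat("CompactnessProfile: GC = ",
        if (length(object@gc) && is.finite(object@gc))
            format(object@gc, digits = 4) else "NA",
        "; LC at ", length(object@scales), " scale(s) [",
        paste(format(range(object@scales)), collapse = " - "), " bp]\n",
        sep = "")
})

## ---- TranscriptionTrack --------------------------------------------------

#' Per-bin transcription levels
#'
#' Gene expression (e.g. FPKM) allocated to genome bins, log2-transformed,
#' with the corresponding Z-scores over non-missing bins.
#'
#' @slot binning a [GenomeBinning].
#' @slot level per-bin log2(1 + allocated expression).
#' @slot zscore per-bin Z-score of `level` (sample SD).
#' @slot source free-text provenance label.
#' @seealso [binTranscription()], [correlateTracks()]
#' @export
setClass("TranscriptionTrack",
    representation(binning = "GenomeBinning", level = "numeric",
                   zscore = "numeric", source = "character"),
    validity = function(object) {
        n <- object@binning@nBins
        msg <- character()
        if (length(object@level) != n || length(object@zscore) != n)
            msg <- c(msg, "level and zscore must have one value per bin")
        z <- object@zscore[!is.na(object@zscore)]
        if (length(z) >= 2) {
            if (abs(mean(z)) > 1e-9) msg <- c(msg, "zscore mean must be ~0")
            if (abs(sd(z) - 1) > 1e-9) msg <- c(msg, "zscore SD must be ~1")
        }
        if (length(msg)) msg else TRUE
    })

#' @rdname TranscriptionTrack-class
#' @param x a `TranscriptionTrack`.
#' @export
setGeneric("trackLevel", function(x) standardGeneric("trackLevel"))
#' @rdname TranscriptionTrack-class
#' @export
setGeneric("trackZscore", function(x) standardGeneric("trackZscore"))
setMethod("trackLevel", "TranscriptionTrack", function(x) x@level)
setMethod("trackZscore", "TranscriptionTrack", function(x) x@zscore)
setMethod("binning", "TranscriptionTrack", function(x) x@binning)

setMethod("show", "TranscriptionTrack", function(object) {
    cat("TranscriptionTrack", if (nzchar(object@source))
        paste0(" [", object@source, "]"), ": ", object@binning@nBins,
        " bins, mean level ", format(mean(object@level, na.rm = TRUE),
        digits = 4), "\n", sep = "")
})
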