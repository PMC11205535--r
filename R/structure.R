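## 3D chromosome models: I/O, distance summaries, fallback embedding.

#' Read a 3D chromosome model
#'
#' Accepts either an XYZ-style table (`index x y z` or `x y z` per line,
#' ordered by bin) or a PDB-like CA trace (parsed with `bio3d`); one point
#' per bin.
#'
#' @param path file path.
#' @param binning a [GenomeBinning]; the file must contain `nBins` points.
#' @param label condition label stored on the result.
#' @return a [Structure3D].
#' @export
readStructure <- function(path, binning, label = "") {
    head <- readLines(path, n = 50L)
    if (any(grepl("^(ATOM|HETATM)", head))) {
        pdb <- bio3d::read.pdb(path)
        xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
    } else {
        tab <- tryCatch(read.table(path, header = FALSE),
                        error = function(e)
                            stop("cannot parse structure file: ",
                                 conditionMessage(e), call. = FALSE))
        m <- as.matrix(tab)
        if (!is.numeric(m)) stop("non-numeric structure file", call. = FALSE)
        xyz <- switch(as.character(ncol(m)),
            "3" = m,
            "4" = m[order(m[, 1]), 2:4, drop = FALSE],
            stop("structure file must have 3 (x y z) or 4 (index x y z) columns",
                 call. = FALSE))
    }
    if (nrow(xyz) != binning@nBins)
        stop(sprintf("structure has %d points but binning expects %d bins",
                     nrow(xyz), binning@nBins), call. = FALSE)
    dimnames(xyz) <- NULL
    Structure3D(xyz, binning, label)
}

#' Write a 3D model as an XYZ table
#'
#' @param s a [Structure3D].
#' @param path output path; lines are `index x y z` (1-based index).
#' @return the path, invisibly.
#' @export
writeStructureXyz <- function(s, path) {
    xyz <- coords(s)
    write.table(data.frame(seq_len(nrow(xyz)), xyz), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# rows of coords with complete (non-NA) coordinates
.presentBins <- function(s) which(stats::complete.cases(coords(s)))

#' Histogram of all pairwise distances in a model
#'
#' Distribution of the Euclidean distance between every unordered pair of
#' model points, the standard genome-wide condensation readout of a 3D
#' model.
#'
#' @param s a [Structure3D] with at least 2 points.
#' @param nHistBins number of histogram bins (default 50).
#' @return a list with `breaks`, `counts`, `mids` and the raw `distances`
#'   vector; counts sum to `n*(n-1)/2` over present bins.
#' @export
pairwiseDistanceDistribution <- function(s, nHistBins = 50) {
    pres <- .presentBins(s)
    if (length(pres) < 2) stop("need at least 2 points", call. = FALSE)
    d <- as.vector(dist(coords(s)[pres, , drop = FALSE]))
    h <- graphics::hist(d, breaks = seq(0, max(d) * (1 + 1e-12),
                                        length.out = nHistBins + 1),
                        plot = FALSE)
    list(breaks = h$breaks, counts = h$counts, mids = h$mids, distances = d)
}

#' Read a macrodomain map from BED
#'
#' BED intervals (0-based half-open on disk, converted to 1-based by
#' rtracklayer) naming the chromosome macrodomains (Ori, Ter, Left, Right)
#' and non-structured regions.
#'
#' @param path BED file path; the 4th (name) column labels each domain.
#' @return a named `GRanges`.
#' @export
readMacrodomains <- function(path) {
    g <- rtracklayer::import(path, format = "bed")
    if (is.null(g$name)) stop("macrodomain BED needs a name column",
                              call. = FALSE)
    names(g) <- g$name
    g
}

# bins (1-based) whose span overlaps a 1-based closed interval
.binsInInterval <- function(binning, start, end) {
    bs <- binning@binSize
    lo <- max(1L, as.integer(floor((start - 1) / bs) + 1))
    hi <- min(binning@nBins, as.integer(ceiling(end / bs)))
    if (hi < lo) return(integer(0))
    seq.int(lo, hi)
}

#' Mean spatial distances between and within macrodomains
#'
#' For every unordered pair of macrodomains the mean Euclidean distance
#' between their member bins in the model (e.g. "OT" = Ori vs Ter), and for
#' each single domain the mean over unordered pairs within it.  A domain
#' with fewer than 2 present bins yields `NA` for its intra-domain class.
#'
#' @param s a [Structure3D].
#' @param domains a named `GRanges` (see [readMacrodomains()]) or a
#'   `data.frame` with columns `name`, `start`, `end` (1-based closed).
#' @return a `data.frame` with columns `domainA`, `domainB`, `nPairs`,
#'   `meanDistance`.
#' @export
macrodomainDistances <- function(s, domains) {
    bn <- binning(s)
    if (is(domains, "GRanges")) {
        dnames <- if (!is.null(names(domains))) names(domains)
                  else domains$name
        starts <- GenomicRanges::start(domains)
        ends <- GenomicRanges::end(domains)
    } else {
        dnames <- as.character(domains$name)
        starts <- domains$start
        ends <- domains$end
    }
    pres <- .presentBins(s)
    members <- lapply(seq_along(dnames), function(k)
        intersect(.binsInInterval(bn, starts[k], ends[k]), pres))
    if (any(lengths(members) == 0))
        stop("macrodomain with no bins: ",
             paste(dnames[lengths(members) == 0], collapse = ", "),
             call. = FALSE)
    xyz <- coords(s)
    classes <- expand.grid(a = seq_along(dnames), b = seq_along(dnames))
    classes <- classes[classes$a <= classes$b, ]
    res <- lapply(seq_len(nrow(classes)), function(r) {
        ia <- members[[classes$a[r]]]; ib <- members[[classes$b[r]]]
        if (classes$a[r] == classes$b[r]) {
            if (length(ia) < 2)
                return(data.frame(domainA = dnames[classes$a[r]],
                                  domainB = dnames[classes$b[r]],
                                  nPairs = 0L, meanDistance = NA_real_))
            d <- dist(xyz[ia, , drop = FALSE])
            np <- length(d)
        } else {
            d <- sqrt(pmax(0, outer(rowSums(xyz[ia, , drop = FALSE]^2),
                                    rowSums(xyz[ib, , drop = FALSE]^2), "+") -
                              2 * xyz[ia, , drop = FALSE] %*%
                                  t(xyz[ib, , drop = FALSE])))
            np <- length(d)
        }
        data.frame(domainA = dnames[classes$a[r]],
                   domainB = dnames[classes$b[r]],
                   nPairs = np, meanDistance = mean(d))
    })
    do.call(rbind, res)
}

#' Classical-scaling embedding of a contact matrix into 3D
#'
#' A simple contacts-to-coordinates converter for testing and exploration:
#' target distances `D_ij proportional to (1/M_ij)^alpha` are embedded by
#' classical metric multidimensional scaling (`cmdscale`) into 3
#' dimensions.  This is deliberately plain plumbing — a deterministic
#' embedding so the downstream metrics can be exercised on desk-scale data
#' — and is not an inference method for real chromosome architecture.
#'
#' @param M a normalised [ContactMatrix]; zero entries receive the smallest
#'   positive entry as pseudocount.
#' @param alpha contact-to-distance exponent (default 1).
#' @param seed integer seed (kept for interface stability; the embedding
#'   itself is deterministic).
#' @param label condition label for the result.
#' @return a [Structure3D].
#' @export
fallbackEmbedding <- function(M, alpha = 1, seed = 1L, label = "embedding") {
    v <- contactValues(M)
    n <- nrow(v)
    if (n < 4) stop("need at least 4 bins to embed", call. = FALSE)
    pos <- v[v > 0]
    if (!length(pos)) stop("empty matrix cannot be embedded", call. = FALSE)
    w <- v
    w[w <= 0] <- min(pos)
    D <- (1 / w)^alpha
    diag(D) <- 0
    D <- (D + t(D)) / 2
    off <- D[upper.tri(D)]
    if (sd(off) / mean(off) < 1e-10)
        stop("degenerate contact matrix: all pairwise distances equal",
             call. = FALSE)
    set.seed(as.integer(seed))
    fit <- cmdscale(D, k = 3, eig = TRUE)
    xyz <- fit$points
    if (ncol(xyz) < 3)           # rank-deficient (e.g. planar) configurations
        xyz <- cbind(xyz, matrix(0, n, 3 - ncol(xyz)))
    if (sum(fit$eig > max(fit$eig) * 1e-12) < 2)
        stop("degenerate embedding: configuration has rank < 2", call. = FALSE)
    Structure3D(xyz, binning(M), label)
}
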