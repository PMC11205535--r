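# Independent brute-force oracles: deliberately naive double-loop
# re-derivations of every summary statistic, kept free of any code path
# from the package itself.

randSymMatrix <- function(n, seed, lo = 0.5, hi = 2) {
    set.seed(seed)
    m <- matrix(runif(n * n, lo, hi), n, n)
    (m + t(m)) / 2
}

circd <- function(i, j, n) { d <- abs(i - j); min(d, n - d) }

# step-by-step SCN reference: L2 row pass, L2 column pass, entrywise
# relative-change stopping rule, final symmetrization
scnOracle <- function(m, tol = 1e-6, maxIter = 200) {
    n <- nrow(m)
    for (it in seq_len(maxIter)) {
        prev <- m
        for (i in seq_len(n)) {
            nrm <- sqrt(sum(m[i, ]^2))
            if (nrm > 0) m[i, ] <- m[i, ] / nrm
        }
        for (j in seq_len(n)) {
            nrm <- sqrt(sum(m[, j]^2))
            if (nrm > 0) m[, j] <- m[, j] / nrm
        }
        delta <- 0
        for (i in seq_len(n)) for (j in seq_len(n))
            if (prev[i, j] > 0)
                delta <- max(delta, abs(m[i, j] - prev[i, j]) / prev[i, j])
        if (delta < tol) break
    }
    (m + t(m)) / 2
}

diOracle <- function(m, w) {
    n <- nrow(m)
    di <- numeric(n)
    for (i in seq_len(n)) {
        A <- 0; B <- 0
        for (d in seq_len(w)) {
            A <- A + m[i, ((i - 1 - d) %% n) + 1]
            B <- B + m[i, ((i - 1 + d) %% n) + 1]
        }
        E <- (A + B) / 2
        if (E > 0 && A != B)
            di[i] <- sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    }
    di
}

decayOracle <- function(m) {
    n <- nrow(m)
    smax <- floor(n / 2)
    sapply(0:smax, function(s) {
        acc <- 0
        for (i in seq_len(n)) acc <- acc + m[i, ((i - 1 + s) %% n) + 1]
        acc / n
    })
}

shortFreqOracle <- function(m, maxd) {
    n <- nrow(m)
    f <- matrix(0, n, maxd + 1)
    for (i in seq_len(n)) for (d in 0:maxd) {
        up <- m[i, ((i - 1 + d) %% n) + 1]
        dn <- m[i, ((i - 1 - d) %% n) + 1]
        f[i, d + 1] <- (up + dn) / 2
    }
    f
}

proportionOracle <- function(m, w) {
    n <- nrow(m)
    sapply(seq_len(n), function(i) {
        num <- 0; den <- 0
        for (j in seq_len(n)) {
            if (j == i) next
            den <- den + m[i, j]
            if (circd(i, j, n) <= w) num <- num + m[i, j]
        }
        if (den > 0) num / den else NA_real_
    })
}

# GC oracle: same definitional reference (inscribed polygon with chords
# equal to backbone segment lengths) rebuilt with bisection and explicit
# double loops
gcOracle <- function(xyz) {
    n <- nrow(xyz)
    seg <- sapply(seq_len(n), function(k) {
        nk <- if (k == n) 1 else k + 1
        sqrt(sum((xyz[nk, ] - xyz[k, ])^2))
    })
    L <- sum(seg)
    f <- function(R) sum(2 * asin(pmin(1, seg / (2 * R)))) - 2 * pi
    lo <- max(seg) / 2 * (1 + 1e-12); hi <- L
    for (it in 1:200) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) lo <- mid else hi <- mid
    }
    R <- (lo + hi) / 2
    theta <- cumsum(c(0, 2 * asin(pmin(1, seg[-n] / (2 * R)))))
    sumD <- 0; sumd <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        sumD <- sumD + sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        sumd <- sumd + 2 * R * sin(abs(theta[i] - theta[j]) / 2)
    }
    -log2(sumD / sumd)
}

lcOracle <- function(xyz, t, circular = TRUE) {
    n <- nrow(xyz)
    sapply(seq_len(n), function(i) {
        win <- if (circular) (((i - t):(i + t) - 1) %% n) + 1
               else max(1, i - t):min(n, i + t)
        pts <- xyz[win, , drop = FALSE]
        m <- nrow(pts)
        pos <- numeric(m)
        for (k in 2:m)
            pos[k] <- pos[k - 1] + sqrt(sum((pts[k, ] - pts[k - 1, ])^2))
        self <- which(win == i)
        sumD <- 0; sumd <- 0
        for (k in seq_len(m)) {
            if (k == self) next
            sumD <- sumD + sqrt(sum((pts[k, ] - pts[self, ])^2))
            sumd <- sumd + abs(pos[k] - pos[self])
        }
        -log2(sumD / sumd)
    })
}

randStructure <- function(n, seed) {
    set.seed(seed)
    matrix(rnorm(n * 3), n, 3)
}

# random rigid motion (+ optional reflection) and uniform scale
rigidTransform <- function(xyz, seed, scale = 1) {
    set.seed(seed)
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    shift <- rnorm(3, sd = 10)
    sweep(xyz %*% Q * scale, 2, shift, "+")
}

makeBinning <- function(n, binSize = 5000, circular = TRUE)
    GenomeBinning(n * binSize, binSize, circular)

makeCM <- function(m, binSize = 5000, normalized = FALSE, circular = TRUE)
    ContactMatrix(m, makeBinning(nrow(m), binSize, circular),
                  normalized = normalized)

# DIProfile with prescribed DI values (upstream/downstream chosen
# consistently for the validity check)
makeDI <- function(di, binning, window = 1e5) {
    new("DIProfile", binning = binning, di = as.numeric(di),
        upstream = numeric(length(di)), downstream = as.numeric(di),
        window = window)
}
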