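## Independent oracles, deliberately naive: direct summation over the
## defining formulas, no shared code with the package internals.

naiveMI <- function(x, y, base = "nats") {
    n <- length(x)
    s <- 0
    for (a in unique(x)) for (b in unique(y)) {
        pxy <- sum(x == a & y == b) / n
        if (pxy > 0) {
            px <- sum(x == a) / n
            py <- sum(y == b) / n
            s <- s + pxy * log(pxy / (px * py))
        }
    }
    if (base == "bits") s / log(2) else s
}

## triple loop over p(x,y,z) log[ p(z) p(x,y,z) / (p(x,z) p(y,z)) ]
naiveCMI <- function(x, y, z, base = "nats") {
    n <- length(x)
    s <- 0
    for (a in unique(x)) for (b in unique(y)) for (cc in unique(z)) {
        pxyz <- sum(x == a & y == b & z == cc) / n
        if (pxyz > 0) {
            pz  <- sum(z == cc) / n
            pxz <- sum(x == a & z == cc) / n
            pyz <- sum(y == b & z == cc) / n
            s <- s + pxyz * log(pz * pxyz / (pxz * pyz))
        }
    }
    if (base == "bits") s / log(2) else s
}

## sup of |ECDF difference| evaluated by brute force at every pooled point
bruteKS <- function(a, b) {
    pts <- c(a, b)
    max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

## random discretized triple with bin counts <= maxBins
randomTriple <- function(n, maxBins = 4L) {
    bx <- sample(2:maxBins, 1)
    by <- sample(2:maxBins, 1)
    bz <- sample(2:maxBins, 1)
    list(x = sample(0:(bx - 1), n, replace = TRUE),
         y = sample(0:(by - 1), n, replace = TRUE),
         z = sample(0:(bz - 1), n, replace = TRUE))
}
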