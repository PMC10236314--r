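## Plug-in (empirical-frequency) mutual information and conditional mutual
## information over discretized vectors. Everything here is deterministic:
## equal-frequency ties are broken by original sample index and all
## estimates are exact functionals of the empirical contingency table.

.labels <- function(v, arg = "x") {
    if (!is.numeric(v) || anyNA(v))
        stop(sprintf("%s must be a numeric label vector without NA", arg),
             call. = FALSE)
    l <- as.integer(v)
    if (any(l != v) || any(l < 0L))
        stop(sprintf("%s must contain non-negative integer bin labels", arg),
             call. = FALSE)
    nb <- attr(v, "nBins")
    nb <- if (is.null(nb)) max(l) + 1L else as.integer(nb)
    if (any(l >= nb))
        stop(sprintf("%s has labels outside 0..nBins-1", arg), call. = FALSE)
    structure(l, nBins = nb)
}

#' Discretize a continuous vector into bins
#'
#' Equal-frequency binning assigns labels by rank: the sorted values are
#' cut into `nBins` consecutive groups whose sizes differ by at most one
#' (earlier bins take the remainder), with ties broken by original sample
#' index so the mapping is deterministic. Equal-width binning splits
#' `[min, max]` into `nBins` half-open intervals, the last one closed; a
#' constant vector collapses into bin 0 (allowed, with a message).
#'
#' @param values numeric vector, length >= `nBins`.
#' @param nBins number of bins, >= 2. The pipeline default elsewhere is
#'   `ceiling(N^(1/3))` for N samples.
#' @param strategy `"equal_frequency"` (default) or `"equal_width"`.
#' @return integer vector of 0-based bin labels with attribute `nBins`.
#' @examples
#' discretize(c(5, 1, 3, 2, 4, 6), 2)              # 1 0 0 0 1 1
#' discretize(c(0, 1, 2, 3), 2, "equal_width")      # 0 0 1 1
#' @export
discretize <- function(values, nBins,
                       strategy = c("equal_frequency", "equal_width")) {
    strategy <- match.arg(strategy)
    stopifnot(is.numeric(values), all(is.finite(values)))
    nBins <- as.integer(nBins)
    if (nBins < 2L)
        stop("nBins must be >= 2", call. = FALSE)
    n <- length(values)
    if (nBins > n)
        stop("nBins must not exceed the number of values", call. = FALSE)
    if (strategy == "equal_frequency") {
        ord <- order(values, method = "radix")   # stable: ties by index
        sizes <- rep(n %/% nBins, nBins)
        extra <- n %% nBins
        if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
        lab <- integer(n)
        lab[ord] <- rep.int(seq_len(nBins) - 1L, sizes)
    } else {
        rng <- range(values)
        if (rng[1L] == rng[2L]) {
            message("discretize: constant vector, all samples in bin 0")
            lab <- integer(n)
        } else {
            width <- (rng[2L] - rng[1L]) / nBins
            lab <- pmin(as.integer(floor((values - rng[1L]) / width)),
                        nBins - 1L)
        }
    }
    structure(lab, nBins = nBins)
}

#' Bin copy-number values into conditioning states
#'
#' Copy-number estimates are rounded to the nearest integer state; states
#' observed in fewer than `max(5, N/50)` samples are merged into the
#' nearest populated state (by state value; ties resolve to the lower
#' state), repeating until every remaining state is adequately populated.
#' This keeps the conditional distributions `p(.|z)` estimable. Set
#' `method = "equal_frequency"` to instead use the same rank-based binning
#' as expression, with `nBins` bins.
#'
#' @param values numeric vector of copy-number values for one conditioning
#'   gene across samples.
#' @param method `"integer_states"` (default) or `"equal_frequency"`.
#' @param nBins bins for `method = "equal_frequency"` (default 3).
#' @param minCount occupancy floor; default `max(5, length(values)/50)`.
#' @return integer 0-based state labels with attribute `nBins`, plus
#'   attribute `states` (the surviving integer copy states, in label
#'   order) when `method = "integer_states"`.
#' @export
binCNVStates <- function(values,
                         method = c("integer_states", "equal_frequency"),
                         nBins = 3L, minCount = NULL) {
    method <- match.arg(method)
    stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
    if (method == "equal_frequency")
        return(discretize(values, nBins, "equal_frequency"))
    n <- length(values)
    if (is.null(minCount)) minCount <- max(5, n / 50)
    st <- as.integer(round(values))
    repeat {
        tab <- table(st)
        states <- as.integer(names(tab))
        if (length(states) <= 1L || min(tab) >= minCount) break
        small <- states[which.min(tab)]          # ties: lowest state value
        others <- setdiff(states, small)
        gap <- abs(others - small)
        target <- min(others[gap == min(gap)])   # ties: lower state
        st[st == small] <- target
    }
    states <- sort(unique(st))
    structure(match(st, states) - 1L,
              nBins = length(states), states = states)
}

## flat contingency counts over (x, y, z) with x fastest
.jointCounts <- function(x, y, z) {
    bx <- attr(x, "nBins"); by <- attr(y, "nBins"); bz <- attr(z, "nBins")
    code <- 1L + unclass(x) + bx * (unclass(y) + by * unclass(z))
    tabulate(code, nbins = bx * by * bz)
}

#' Empirical joint distribution of three discretized vectors
#'
#' @param x,y,z integer label vectors (as from [discretize()] or
#'   [binCNVStates()]), equal lengths.
#' @return 3-d array of empirical probabilities `p(x, y, z)`,
#'   `dim = c(Bx, By, Bz)`; sums to 1.
#' @export
jointDistribution <- function(x, y, z) {
    x <- .labels(x, "x"); y <- .labels(y, "y"); z <- .labels(z, "z")
    if (length(x) != length(y) || length(x) != length(z))
        stop("x, y and z must have equal lengths", call. = FALSE)
    if (length(x) == 0L)
        stop("empty vectors", call. = FALSE)
    cnt <- .jointCounts(x, y, z)
    array(cnt / length(x),
          dim = c(attr(x, "nBins"), attr(y, "nBins"), attr(z, "nBins")))
}

.logbase <- function(base) {
    switch(match.arg(base, c("nats", "bits")), nats = 1, bits = log(2))
}

#' Plug-in mutual information
#'
#' \eqn{I(X;Y) = \sum_{x,y} p(x,y) \log\frac{p(x,y)}{p(x)p(y)}} with
#' empirical probabilities; cells with `p(x,y) = 0` contribute 0. The
#' estimate is clamped to 0 when within `1e-12` of zero (floating-point
#' guard; the population quantity is non-negative).
#'
#' @param x,y integer label vectors of equal length.
#' @param base `"nats"` (default) or `"bits"`.
#' @return non-negative scalar.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1), base = "bits")  # 1
#' mutualInformation(c(0, 0, 1, 1), c(0, 1, 0, 1), base = "bits")  # 0
#' @export
mutualInformation <- function(x, y, base = c("nats", "bits")) {
    x <- .labels(x, "x"); y <- .labels(y, "y")
    if (length(x) != length(y))
        stop("x and y must have equal lengths", call. = FALSE)
    n <- length(x)
    bx <- attr(x, "nBins"); by <- attr(y, "nBins")
    nxy <- tabulate(1L + unclass(x) + bx * unclass(y), nbins = bx * by)
    nx <- tabulate(unclass(x) + 1L, nbins = bx)
    ny <- tabulate(unclass(y) + 1L, nbins = by)
    ix <- rep.int(seq_len(bx), by)
    iy <- rep(seq_len(by), each = bx)
    pos <- nxy > 0L
    v <- sum(nxy[pos] * log(n * nxy[pos] / (nx[ix[pos]] * ny[iy[pos]]))) / n
    .clamp0(v) / .logbase(base)
}

#' Plug-in conditional mutual information
#'
#' \eqn{I(X;Y|Z) = \sum_{x,y,z} p(x,y,z)\log\frac{p(z)\,p(x,y,z)}
#' {p(x,z)\,p(y,z)}} with empirical probabilities. Zero-probability cells
#' contribute 0 and the result is clamped at 0 when within `1e-12` of zero.
#' For a constant `z` this reduces exactly to [mutualInformation()].
#'
#' @param x,y,z integer label vectors of equal length (`z` is the
#'   conditioning variable, e.g. binned copy-number states).
#' @param base `"nats"` (default) or `"bits"`.
#' @return non-negative scalar.
#' @examples
#' x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)
#' z <- bitwXor(x, y)
#' mutualInformation(x, y, base = "bits")                  # 0
#' conditionalMutualInformation(x, y, z, base = "bits")    # 1
#' @export
conditionalMutualInformation <- function(x, y, z,
                                         base = c("nats", "bits")) {
    x <- .labels(x, "x"); y <- .labels(y, "y"); z <- .labels(z, "z")
    if (length(x) != length(y) || length(x) != length(z))
        stop("x, y and z must have equal lengths", call. = FALSE)
    n <- length(x)
    bx <- attr(x, "nBins"); by <- attr(y, "nBins"); bz <- attr(z, "nBins")
    nxyz <- .jointCounts(x, y, z)
    nxz <- tabulate(1L + unclass(x) + bx * unclass(z), nbins = bx * bz)
    nyz <- tabulate(1L + unclass(y) + by * unclass(z), nbins = by * bz)
    nz <- tabulate(unclass(z) + 1L, nbins = bz)
    cells <- seq_len(bx * by * bz) - 1L
    ix <- cells %% bx
    iy <- (cells %/% bx) %% by
    iz <- cells %/% (bx * by)
    pos <- nxyz > 0L
    fx <- 1L + ix[pos] + bx * iz[pos]
    fy <- 1L + iy[pos] + by * iz[pos]
    v <- sum(nxyz[pos] *
             log(nz[iz[pos] + 1L] * nxyz[pos] / (nxz[fx] * nyz[fy]))) / n
    .clamp0(v) / .logbase(base)
}

.clamp0 <- function(v) if (v < 0 && v > -1e-12) 0 else v

#' All-pairs conditional mutual information for one conditioning gene
#'
#' Discretizes every gene's expression vector ([discretize()]) and the
#' conditioning gene's copy-number profile ([binCNVStates()]), then
#' computes the plug-in CMI of every unordered gene pair given the
#' conditioning states — the weighted edge list of one co-expression
#' layer. Pairs are stored once with `gene_i < gene_j` and the list is
#' sorted by decreasing weight, ties broken by pair name.
#'
#' @param expr numeric matrix, genes x samples (aligned with `cnvK`).
#' @param cnvK numeric vector of the conditioning gene's copy-number values
#'   per sample, in the same sample order as `expr` columns.
#' @param nBins expression bins; default `ceiling(N^(1/3))` for N samples.
#' @param strategy expression binning strategy, see [discretize()].
#' @param base logarithm base, see [mutualInformation()].
#' @param zMethod conditioning-state binning, see [binCNVStates()].
#' @param zBins bins when `zMethod = "equal_frequency"`.
#' @return data.frame with columns `gene_i`, `gene_j`, `cmi`; exactly
#'   `G(G-1)/2` rows.
#' @export
pairwiseCMI <- function(expr, cnvK, nBins = NULL,
                        strategy = c("equal_frequency", "equal_width"),
                        base = c("nats", "bits"),
                        zMethod = c("integer_states", "equal_frequency"),
                        zBins = 3L) {
    strategy <- match.arg(strategy)
    base <- match.arg(base)
    zMethod <- match.arg(zMethod)
    stopifnot(is.matrix(expr), nrow(expr) >= 2L)
    n <- ncol(expr)
    if (length(cnvK) != n)
        stop("cnvK must have one value per expression sample", call. = FALSE)
    if (is.null(nBins)) nBins <- ceiling(n^(1 / 3))
    b <- as.integer(nBins)
    genes <- rownames(expr)
    if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(expr)))

    lab <- matrix(0L, nrow(expr), n)
    for (g in seq_len(nrow(expr)))
        lab[g, ] <- discretize(expr[g, ], b, strategy)
    z <- binCNVStates(cnvK, method = zMethod, nBins = zBins)
    bz <- attr(z, "nBins")
    nz <- tabulate(unclass(z) + 1L, nbins = bz)

    ## per-gene (x, z) marginal counts, one row per gene
    mxz <- matrix(0L, nrow(expr), b * bz)
    zb <- b * unclass(z)
    for (g in seq_len(nrow(expr)))
        mxz[g, ] <- tabulate(1L + lab[g, ] + zb, nbins = b * bz)

    nbins <- b * b * bz
    cells <- seq_len(nbins) - 1L
    ix <- cells %% b
    iy <- (cells %/% b) %% b
    iz <- cells %/% (b * b)
    fx <- 1L + ix + b * iz
    fy <- 1L + iy + b * iz
    lnz <- log(nz)[iz + 1L]
    zoff <- b * b * unclass(z)
    lgb <- .logbase(base)

    G <- nrow(expr)
    npair <- G * (G - 1L) / 2L
    wi <- integer(npair); wj <- integer(npair); w <- numeric(npair)
    p <- 0L
    for (i in seq_len(G - 1L)) {
        ci <- 1L + lab[i, ] + zoff
        mi <- mxz[i, ]
        for (j in (i + 1L):G) {
            cnt <- tabulate(ci + b * lab[j, ], nbins = nbins)
            pos <- which(cnt > 0L)
            cp <- cnt[pos]
            v <- sum(cp * (lnz[pos] + log(cp) -
                           log(mi[fx[pos]] * mxz[j, fy[pos]]))) / n
            p <- p + 1L
            wi[p] <- i; wj[p] <- j
            w[p] <- .clamp0(v) / lgb
        }
    }
    gi <- genes[wi]; gj <- genes[wj]
    swap <- gi > gj
    if (any(swap)) {
        tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
    }
    out <- data.frame(gene_i = gi, gene_j = gj, cmi = w)
    out <- out[order(out$cmi, out$gene_i, out$gene_j,
                     decreasing = c(TRUE, FALSE, FALSE), method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
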