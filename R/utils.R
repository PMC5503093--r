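# Internal numerics shared across modules.

# Unit bridge: positions are Angstrom, times ps; diffusion is reported
# in nm^2/ns.  1 A^2/ps = 0.01 nm^2 / 0.001 ns = 10 nm^2/ns.
.A2_PER_PS_TO_NM2_PER_NS <- 10

# Water masses (g/mol) for the center-of-mass option.
.MASS_O <- 15.999
.MASS_H <- 1.008
.MASS_WATER_G <- (.MASS_O + 2 * .MASS_H) / 6.02214076e23  # grams/molecule

# Minimum-image displacement for an orthorhombic box; works on vectors,
# matrices and arrays (box recycled along the first dimension(s)).
.minImage <- function(dx, L) dx - L * round(dx / L)

# Wrap coordinates into [0, L).
.wrapInto <- function(x, L) x - L * floor(x / L)

# Linear autocorrelation sums S2(tau) = sum_k x_k x_{k+tau} for
# tau = 0..N-1, via zero-padded FFT.  x may be a matrix: column-wise.
.acfSums <- function(x) {
    x <- as.matrix(x)
    n <- nrow(x)
    m <- 2L * .nextPow2(n)
    pad <- rbind(x, matrix(0, m - n, ncol(x)))
    F <- stats::mvfft(pad)
    s <- Re(stats::mvfft(Conj(F) * F, inverse = TRUE)) / m
    s[seq_len(n), , drop = FALSE]
}

.nextPow2 <- function(n) 2L^ceiling(log2(max(n, 1L)))

# Trapezoidal integral on an arbitrary grid.
.trapz <- function(x, y) {
    n <- length(x)
    if (n < 2L) return(0)
    sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Tiny polynomial rolling hash of a character scalar (hex string);
# used to stamp run outputs with a configuration fingerprint.
.configHash <- function(s) {
    bytes <- utf8ToInt(s)
    h1 <- 17; h2 <- 5381
    for (b in bytes) {
        h1 <- (h1 * 31 + b) %% 2147483647
        h2 <- (h2 * 33 + b) %% 1000000007
    }
    sprintf("%08x%08x", h1, h2)
}

# Internal constructor with rounding guard on lag grid.
.correlationSeries <- function(lags, values, nPairs, kind) {
    new("CorrelationSeries", lags = as.numeric(lags),
        values = as.numeric(values), nPairs = as.numeric(nPairs),
        kind = kind)
}

# Split n indices into nb contiguous blocks of near-equal size.
.blockSplit <- function(idx, nb) {
    nb <- max(1L, min(nb, length(idx)))
    split(idx, cut(seq_along(idx), nb, labels = FALSE))
}

# Centered running mean with window k (edges use shorter windows).
.runMean <- function(x, k) {
    n <- length(x)
    if (n < 3L || k < 2L) return(x)
    half <- k %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
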