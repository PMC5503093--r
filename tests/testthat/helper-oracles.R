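# Independent brute-force oracles and small fixture builders.
# These deliberately use plain nested loops and explicit periodic
# images so they share no code with the package's optimized paths.

# All-origin MSD of one coordinate matrix [molecules, frames].
bruteMSD1D <- function(x, tau) {
    acc <- 0; n <- 0L
    for (m in seq_len(nrow(x))) {
        for (t0 in seq_len(ncol(x) - tau)) {
            acc <- acc + (x[m, t0 + tau] - x[m, t0])^2
            n <- n + 1L
        }
    }
    acc / n
}

# All-origin dipole autocorrelation of [molecules, 3, frames].
bruteACF <- function(mu, tau) {
    acc <- 0; n <- 0L
    nf <- dim(mu)[3]
    for (m in seq_len(dim(mu)[1])) {
        for (t0 in seq_len(nf - tau)) {
            acc <- acc + sum(mu[m, , t0] * mu[m, , t0 + tau])
            n <- n + 1L
        }
    }
    acc / n
}

# Pooled intermittent bond correlator of an indicator matrix.
bruteHBCorr <- function(ind, tau) {
    num <- 0; den <- 0
    for (p in seq_len(nrow(ind))) {
        for (t0 in seq_len(ncol(ind) - tau)) {
            num <- num + ind[p, t0] * ind[p, t0 + tau]
            den <- den + ind[p, t0]
        }
    }
    num / den
}

# Minimum-image difference (scalar helper for the oracles).
mic <- function(d, L) d - L * round(d / L)

# O(N^2) hydrogen-bond detection: explicit loops over donors,
# hydrogens and acceptors.  Returns a sorted key set "donor/h/acceptor".
bruteHBondKeys <- function(traj, frame, dOOmax = 3.5, angleMax = 30) {
    topo <- topology(traj)
    m <- coords(traj, frame)
    L <- boxDims(traj, frame)
    accIdx <- c(topo@waterO, topo@lipidAcceptors)
    accWat <- c(seq_len(nWaters(topo)),
                rep(NA, length(topo@lipidAcceptors)))
    keys <- character()
    for (d in seq_len(nWaters(topo))) {
        rO <- m[topo@waterO[d], ]
        for (a in seq_along(accIdx)) {
            if (!is.na(accWat[a]) && accWat[a] == d) next
            dOO_vec <- mic(m[accIdx[a], ] - rO, L)
            dOO <- sqrt(sum(dOO_vec^2))
            if (dOO >= dOOmax) next
            for (h in 1:2) {
                iH <- if (h == 1) topo@waterH1[d] else topo@waterH2[d]
                vOH <- mic(m[iH, ] - rO, L)
                ca <- sum(vOH * dOO_vec) /
                    (sqrt(sum(vOH^2)) * dOO)
                ang <- acos(max(-1, min(1, ca))) * 180 / pi
                if (ang < angleMax)
                    keys <- c(keys, paste(d, h, accIdx[a], sep = "/"))
            }
        }
    }
    sort(keys)
}

# 2-D periodic nearest generator by explicit 9-image search.
bruteNearest2D <- function(wat, gen, Lxy) {
    out <- integer(nrow(wat))
    for (i in seq_len(nrow(wat))) {
        best <- Inf; bi <- NA_integer_
        for (g in seq_len(nrow(gen))) {
            for (sx in -1:1) for (sy in -1:1) {
                d2 <- (wat[i, 1] - gen[g, 1] - sx * Lxy[1])^2 +
                      (wat[i, 2] - gen[g, 2] - sy * Lxy[2])^2
                if (d2 < best - 1e-12) { best <- d2; bi <- g }
            }
        }
        out[i] <- bi
    }
    out
}

# A trajectory holding two waters at a prescribed O-O distance, with
# the donor O-H bond at a prescribed angle from the O->O axis.
makeWaterPairTraj <- function(dOO, angleDeg, box = c(20, 20, 20)) {
    ang <- angleDeg * pi / 180
    co <- array(0, c(6, 3, 1))
    co[1, , 1] <- c(5, 5, 5)                             # donor O
    co[2, , 1] <- c(5, 5, 5) + 0.96 * c(cos(ang), sin(ang), 0)
    co[3, , 1] <- c(5 - 0.24, 5 - 0.93, 5)               # other H
    co[4, , 1] <- c(5 + dOO, 5, 5)                       # acceptor O
    co[5, , 1] <- c(5 + dOO + 0.96, 0.3 + 5, 5)          # pointing away
    co[6, , 1] <- c(5 + dOO + 0.96, 5 - 0.3, 5)
    topo <- waterTopology(c(1L, 4L), rbind(c(2L, 3L), c(5L, 6L)))
    mdTrajectory(co, box = box, topology = topo, dt = 1)
}

# Random periodic box of waters (plus optional lipid acceptors) for
# detection property tests.
randomWaterBox <- function(nWaters, box, seed, nLipidO = 0L) {
    set.seed(seed)
    natm <- 3L * nWaters + nLipidO
    co <- array(0, c(natm, 3L, 1L))
    for (w in seq_len(nWaters)) {
        rO <- runif(3) * box
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        vref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        p <- vref - sum(vref * u) * u; p <- p / sqrt(sum(p^2))
        bH <- 0.9572 * cos(52.26 * pi / 180)
        aH <- 0.9572 * sin(52.26 * pi / 180)
        co[w, , 1] <- rO
        co[nWaters + w, , 1] <- rO + bH * u + aH * p
        co[2 * nWaters + w, , 1] <- rO + bH * u - aH * p
    }
    if (nLipidO > 0)
        for (k in seq_len(nLipidO))
            co[3 * nWaters + k, , 1] <- runif(3) * box
    topo <- waterTopology(
        seq_len(nWaters),
        cbind(nWaters + seq_len(nWaters),
              2L * nWaters + seq_len(nWaters)),
        lipidAcceptors = if (nLipidO > 0)
            3L * nWaters + seq_len(nLipidO) else integer())
    mdTrajectory(co, box = box, topology = topo, dt = 1)
}

# CorrelationSeries from explicit values (test fixture convenience).
corrSeries <- function(lags, values, kind = "acf") {
    new("CorrelationSeries", lags = lags, values = values,
        nPairs = rev(seq_along(lags)), kind = kind)
}

expect_rel_equal <- function(object, expected, tol) {
    expect_lt(abs(object - expected) / abs(expected), tol)
}
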