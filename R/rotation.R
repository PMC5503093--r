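#' Dipolar rotational correlation function
#'
#' Rank-1 orientational autocorrelation C(tau) = <mu(t0 + tau) .
#' mu(t0)> of the water dipole direction, averaged over molecules and
#' all time origins (exact all-origin average via FFT, identical to
#' the brute-force double loop).
#'
#' @param dipoles array \code{[nMolecules, 3, frames]} of unit vectors
#'   (as from \code{\link{waterDipoles}} or
#'   \code{\link{generateRotationalDiffusion}}).
#' @param dt frame spacing, ps; defaults to the array's \code{dt}
#'   attribute.
#' @param maxLag largest lag, ps (default full range).
#' @param tol unit-norm tolerance.
#' @return a \linkS4class{CorrelationSeries} of kind \code{"acf"} with
#'   C(0) = 1.
#' @export
dipoleACF <- function(dipoles, dt = attr(dipoles, "dt"), maxLag = NULL,
                      tol = 1e-6) {
    if (is.null(dt)) .stopf("sampling error: dt not given")
    d <- dim(dipoles)
    stopifnot(length(d) == 3L, d[2] == 3L)
    nrm <- sqrt(apply(dipoles^2, c(1, 3), sum))
    if (any(abs(nrm - 1) > tol))
        .stopf("normalization error: dipole vectors must be unit length (max |norm - 1| = %.2g)",
               max(abs(nrm - 1)))
    n <- d[3]
    nLag <- if (is.null(maxLag)) n - 1L else min(n - 1L, floor(maxLag / dt))
    num <- numeric(nLag + 1L)
    for (ax in 1:3) {
        x <- dipoles[, ax, , drop = FALSE]
        dim(x) <- c(d[1], n)
        S2 <- .acfSums(t(x))                 # [lag+1, mol]
        num <- num + rowMeans(S2[seq_len(nLag + 1L), , drop = FALSE])
    }
    vals <- num / (n - (0:nLag))
    vals[1] <- 1                             # exact by construction
    .correlationSeries((0:nLag) * dt, vals, d[1] * (n - (0:nLag)),
                       kind = "acf")
}

#' Model-free relaxation time
#'
#' The time integral of a normalized correlation function, evaluated
#' by trapezoidal quadrature over the observed lags.  With the
#' \code{"exp-tail"} policy (default) a single exponential is fitted
#' to the final decade of the observed decay and the integral is
#' extended analytically to infinity; with \code{"truncate"} the
#' correlator must have decayed below \code{decayThreshold} at the
#' last lag, otherwise the integral is unreliable and an error is
#' raised.  A known stationary plateau (e.g. of a two-state bond
#' process) can be subtracted before integration.
#'
#' @param corr a \linkS4class{CorrelationSeries} (kind \code{"acf"} or
#'   \code{"hb"}).
#' @param tailPolicy \code{"exp-tail"} or \code{"truncate"}.
#' @param plateau long-time limit subtracted before integration
#'   (default 0); the integrand is renormalized to start at 1.
#' @param decayThreshold decay level required at the last lag under
#'   \code{"truncate"}.
#' @return a \linkS4class{RotRelaxation}; \code{tauRot} in ps.
#' @export
relaxationTime <- function(corr, tailPolicy = c("exp-tail", "truncate"),
                           plateau = 0, decayThreshold = 0.05) {
    tailPolicy <- match.arg(tailPolicy)
    stopifnot(is(corr, "CorrelationSeries"))
    t <- lagTimes(corr)
    w <- (corValues(corr) - plateau) / (corValues(corr)[1] - plateau)
    if (tailPolicy == "truncate") {
        tail_lvl <- mean(w[t >= max(t) * 0.9])
        if (tail_lvl > decayThreshold)
            .stopf("unreliable-integral error: correlation has only decayed to %.3f at the last lag; use the exp-tail policy or a longer window",
                   tail_lvl)
        return(new("RotRelaxation", tauRot = .trapz(t, w),
                   tailFraction = 0, method = "truncate"))
    }
    # Quadrature is cut where the (smoothed) correlator first falls
    # below a 1% floor: beyond that point the true signal is
    # negligible while accumulated noise is not.  The analytic
    # exponential tail, fitted to the final observed decade of the
    # decay, is added from the cut point (or from the last lag when
    # the correlator never reaches the floor).
    floor_lvl <- 0.01
    ws <- .runMean(w, 5L)
    cross <- which(ws < floor_lvl)[1]
    cut <- if (is.na(cross)) length(t) else max(cross, 2L)
    base <- .trapz(t[seq_len(cut)], w[seq_len(cut)])
    hiBand <- if (is.na(cross)) {
        wEnd <- max(mean(w[t >= max(t) * 0.95]), floor_lvl)
        min(10 * wEnd, 0.95)
    } else min(10 * floor_lvl, 0.95)
    loBand <- if (is.na(cross)) max(mean(w[t >= max(t) * 0.95]),
                                    floor_lvl) else floor_lvl
    sel <- seq_len(cut)[w[seq_len(cut)] > 0 &
                        w[seq_len(cut)] >= loBand &
                        w[seq_len(cut)] <= hiBand & t[seq_len(cut)] > 0]
    if (length(sel) < 5L)
        sel <- which(t >= t[cut] / 2 & t <= t[cut] & w > 0)
    if (length(sel) < 3L)
        .stopf("unreliable-integral error: too few positive points for the exponential tail fit")
    fit <- stats::lm(lw ~ t, data = data.frame(t = t[sel],
                                               lw = log(w[sel])))
    slope <- stats::coef(fit)[["t"]]
    if (is.na(cross) && slope >= 0)
        .stopf("unreliable-integral error: correlation is not decaying over the fitted tail; use a longer window")
    tail <- 0
    if (slope < 0) {
        tauTail <- -1 / slope
        a <- exp(stats::coef(fit)[["(Intercept)"]])
        tail <- a * tauTail * exp(-t[cut] / tauTail)
    }
    total <- base + tail
    new("RotRelaxation", tauRot = total,
        tailFraction = tail / total, method = "exp-tail")
}

#' Three-exponential model curve
#'
#' C(t) = sum_i f_i exp(-t / tau_i): the three-population (fast,
#' bulk-like, irrotational) decomposition of the rotational
#' correlator.  Used to build fixtures and report fitted curves.
#'
#' @param lags lag times, ps.
#' @param taus numeric length-3 time constants, ps.
#' @param fractions numeric length-3 fractions summing to 1.
#' @return numeric vector of correlation values.
#' @export
triexpCurve <- function(lags, taus, fractions) {
    stopifnot(length(taus) == 3L, length(fractions) == 3L)
    drop(exp(-outer(lags, 1 / taus)) %*% fractions)
}

#' Constrained three-exponential fit
#'
#' Nonlinear least squares of the rotational correlator against
#' \code{\link{triexpCurve}} with the simplex constraint enforced by
#' construction (fractions parameterized by a softmax, so they are
#' non-negative and sum to one exactly) and time constants kept
#' strictly ordered (log-increment parameterization).  Because the
#' five-parameter fit has a rugged objective, a deterministic list of
#' log-spaced multi-starts is tried and the best-residual solution is
#' returned.
#'
#' @param corr a \linkS4class{CorrelationSeries} (kind \code{"acf"}),
#'   with at least 20 points spanning at least two decades of lag.
#' @param nStarts number of deterministic starting points.
#' @param weights optional per-point weights (default unweighted).
#' @return a \linkS4class{TriExpFit}.
#' @export
fitTriexponential <- function(corr, nStarts = 10L, weights = NULL) {
    stopifnot(is(corr, "CorrelationSeries"))
    t <- lagTimes(corr)
    y <- corValues(corr)
    pos <- t[t > 0]
    if (length(t) < 20L || max(pos) / min(pos) < 100)
        .stopf("fit error: need >= 20 points spanning >= 2 decades of lag")
    if (is.null(weights)) weights <- rep(1, length(t))
    sw <- sqrt(weights)
    resid_fun <- function(p) {
        taus <- .thetaToTaus(p)
        fr <- .thetaToFractions(p)
        sw * (triexpCurve(t, taus, fr) - y)
    }
    starts <- .triexpStarts(t, nStarts)
    best <- NULL
    for (s in starts) {
        fit <- tryCatch(
            minpack.lm::nls.lm(par = s, fn = resid_fun,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 400, ptol = 1e-12,
                                   ftol = 1e-12)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rn <- sqrt(sum(fit$fvec^2))
        if (is.null(best) || rn < best$rn)
            best <- list(par = fit$par, rn = rn)
    }
    if (is.null(best))
        .stopf("fit-failure error: no multi-start converged (tried %d starts over lags [%.3g, %.3g] ps)",
               length(starts), min(pos), max(t))
    taus <- .thetaToTaus(best$par)
    fr <- .thetaToFractions(best$par)
    fr <- fr / sum(fr)                # guard against rounding drift
    new("TriExpFit", tauFast = taus[1], tauBulk = taus[2],
        tauIrr = taus[3], fFast = fr[1], fBulk = fr[2], fIrr = fr[3],
        residualNorm = best$rn)
}

# theta = (log tau1, log dtau2, log dtau3, g1, g2):
# tau1 = e^t1, tau2 = tau1 + e^t2, tau3 = tau2 + e^t3 (strict order);
# fractions = softmax(g1, g2, 0).
.thetaToTaus <- function(p) {
    t1 <- exp(p[1])
    t2 <- t1 + exp(p[2])
    t3 <- t2 + exp(p[3])
    c(t1, t2, t3)
}

.thetaToFractions <- function(p) {
    z <- exp(c(p[4], p[5], 0) - max(p[4], p[5], 0))
    z / sum(z)
}

.triexpStarts <- function(t, nStarts) {
    pos <- t[t > 0]
    lo <- log10(min(pos)); hi <- log10(max(pos))
    anchors <- seq(lo, hi - 1, length.out = max(2L, nStarts))
    lapply(anchors, function(a) {
        taus <- 10^c(a, a + (hi - a) / 2, hi)
        c(log(taus[1]), log(taus[2] - taus[1]), log(taus[3] - taus[2]),
          0, 0)
    })
}
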