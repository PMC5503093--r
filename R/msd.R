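#' In-plane mean-square displacement
#'
#' MSD(tau) = <|r_par(t0 + tau) - r_par(t0)|^2> of the water
#' center-of-mass projection on the membrane (xy) plane, averaged over
#' the selected molecules and all admissible time origins.  The
#' all-origin average is computed exactly with the FFT decomposition of
#' the displacement sum, which is algebraically identical to the
#' brute-force double loop over origins.
#'
#' @param traj an unwrapped \linkS4class{MDTrajectory} (see
#'   \code{\link{unwrapCoordinates}}); a consecutive-frame jump larger
#'   than half a box edge raises a must-unwrap error.
#' @param selection integer vector of water molecule indices (default
#'   all).
#' @param maxLag largest lag in ps (default: the full frame range).
#' @param com \code{"mass"} for the mass-weighted O + 2H center of
#'   mass, \code{"oxygen"} to use the oxygen position as proxy.
#' @param dims \code{c(1, 2)} for in-plane MSD (default); \code{1:3}
#'   gives the 3-D MSD used for the bulk reference.
#' @return a \linkS4class{CorrelationSeries} of kind \code{"msd"}
#'   (values in Angstrom^2, \code{nPairs} = origins x molecules per
#'   lag).
#' @export
msdParallel <- function(traj, selection = seq_len(nWaters(traj)),
                        maxLag = NULL, com = c("mass", "oxygen"),
                        dims = c(1L, 2L)) {
    com <- match.arg(com)
    if (!length(selection)) .stopf("parameter error: empty selection")
    nf <- nFrames(traj)
    if (nf < 2L) .stopf("sampling error: need at least two frames")
    X <- .comSeries(traj, selection, com)     # list of [mol, frames]
    dt <- timestep(traj)
    for (ax in dims) {
        jump <- max(abs(X[[ax]][, -1L, drop = FALSE] -
                        X[[ax]][, -nf, drop = FALSE]))
        if (jump > min(traj@box[, ax]) / 2)
            .stopf("must-unwrap error: consecutive-frame jump of %.2f Angstrom exceeds half the box; call unwrapCoordinates() first",
                   jump)
    }
    nLag <- if (is.null(maxLag)) nf - 1L
            else min(nf - 1L, floor(maxLag / dt))
    msd <- numeric(nLag + 1L)
    for (ax in dims)
        msd <- msd + .msdFFT(X[[ax]], nLag)
    nOrig <- (nf - (0:nLag)) * length(selection)
    .correlationSeries((0:nLag) * dt, msd, nOrig, kind = "msd")
}

# Per-axis MSD averaged over molecules (rows of x), exact all-origin
# average via the standard S1 - 2*S2 FFT decomposition.
.msdFFT <- function(x, nLag) {
    n <- ncol(x)
    S2 <- .acfSums(t(x))                        # [lag+1, mol]
    D <- x^2                                    # [mol, frames]
    total <- 2 * rowSums(D)
    out <- numeric(nLag + 1L)
    acc <- total
    for (tau in 0:nLag) {
        if (tau > 0L) {
            acc <- acc - D[, tau] - D[, n - tau + 1L]
        }
        out[tau + 1L] <- mean(acc / (n - tau) -
                              2 * S2[tau + 1L, ] / (n - tau))
    }
    out
}

#' Fit the lateral diffusion coefficient
#'
#' Ordinary least-squares line through the MSD in the diffusive
#' regime; the diffusion coefficient is slope/4 for in-plane MSD
#' (slope/6 in the 3-D bulk mode), converted to nm^2/ns.  The first
#' \code{discard} picoseconds are excluded (ballistic/cage transient);
#' the default fit window runs from there to a quarter of the largest
#' available lag, where the origin average is still well sampled.
#'
#' @param msd a \linkS4class{CorrelationSeries} of kind \code{"msd"}.
#' @param discard initial transient to discard, ps.
#' @param window length-2 fit window (t_min, t_max) in ps; the start
#'   must be at or beyond \code{discard}.
#' @param dim 2 for in-plane (default), 3 for the bulk reference.
#' @return a \linkS4class{DiffusionEstimate} with the OLS standard
#'   error.
#' @export
fitDiffusion <- function(msd, discard = 2, window = NULL, dim = 2L) {
    stopifnot(is(msd, "CorrelationSeries"), msd@kind == "msd")
    lags <- lagTimes(msd)
    if (is.null(window))
        window <- c(discard, max(lags) * 0.25)
    if (window[1] < discard)
        .stopf("fit error: window start %.3g ps precedes the discard threshold %.3g ps",
               window[1], discard)
    sel <- lags >= window[1] & lags <= window[2]
    if (sum(sel) < 5L)
        .stopf("fit error: fewer than 5 MSD points in the fit window [%.3g, %.3g] ps",
               window[1], window[2])
    fit <- stats::lm(y ~ t, data = data.frame(t = lags[sel],
                                              y = corValues(msd)[sel]))
    # noiseless fixtures fit exactly; the perfect-fit note is expected
    sm <- withCallingHandlers(summary(fit), warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
            invokeRestart("muffleWarning")
    })
    slope <- stats::coef(fit)[["t"]]                    # A^2/ps
    se <- sm$coefficients["t", "Std. Error"]
    conv <- .A2_PER_PS_TO_NM2_PER_NS / (2 * dim)
    r2 <- if (is.null(sm$r.squared) || is.nan(sm$r.squared)) NA_real_
          else sm$r.squared
    new("DiffusionEstimate", D = slope * conv, stderr = se * conv,
        window = as.numeric(window), rSquared = r2,
        dim = as.integer(dim), method = "ols")
}

#' Diffusion estimate with molecule-block errors
#'
#' Convenience wrapper: computes the in-plane MSD, fits the diffusive
#' regime, and replaces the OLS standard error (which ignores the
#' strong correlation between MSD lag points) with the standard error
#' across disjoint molecule blocks.
#'
#' @inheritParams msdParallel
#' @inheritParams fitDiffusion
#' @param nBlocks number of molecule blocks for the error estimate.
#' @return a \linkS4class{DiffusionEstimate} (method \code{"blocks"}).
#' @export
estimateDiffusion <- function(traj, selection = seq_len(nWaters(traj)),
                              discard = 2, window = NULL, maxLag = NULL,
                              com = "mass", dims = c(1L, 2L),
                              nBlocks = 5L) {
    full <- fitDiffusion(msdParallel(traj, selection, maxLag = maxLag,
                                     com = com, dims = dims),
                         discard = discard, window = window,
                         dim = length(dims))
    blocks <- .blockSplit(selection, nBlocks)
    if (length(blocks) >= 2L) {
        Db <- vapply(blocks, function(b)
            fitDiffusion(msdParallel(traj, b, maxLag = maxLag,
                                     com = com, dims = dims),
                         discard = discard, window = window,
                         dim = length(dims))@D, numeric(1))
        full@stderr <- stats::sd(Db) / sqrt(length(Db))
        full@method <- "blocks"
    }
    full
}

# Center-of-mass (or oxygen) coordinate series per axis:
# list of three [molecules, frames] matrices.
.comSeries <- function(traj, selection, com) {
    topo <- topology(traj)
    iO <- topo@waterO[selection]
    out <- vector("list", 3L)
    for (ax in 1:3) {
        xO <- traj@coords[iO, ax, , drop = FALSE]
        dim(xO) <- c(length(iO), nFrames(traj))
        if (com == "oxygen") {
            out[[ax]] <- xO
        } else {
            iH1 <- topo@waterH1[selection]
            iH2 <- topo@waterH2[selection]
            x1 <- traj@coords[iH1, ax, , drop = FALSE]
            x2 <- traj@coords[iH2, ax, , drop = FALSE]
            dim(x1) <- dim(x2) <- dim(xO)
            mtot <- .MASS_O + 2 * .MASS_H
            out[[ax]] <- (xO * .MASS_O + (x1 + x2) * .MASS_H) / mtot
        }
    }
    out
}
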