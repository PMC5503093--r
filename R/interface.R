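#' Voronoi assignment of waters to head-group generators
#'
#' Two-dimensional Voronoi tessellation of the membrane plane, built
#' per leaflet from the head-group (P, N) generator atoms with
#' periodic images in xy.  Cell membership by xy-projection is
#' equivalent to the nearest generator in 2-D periodic distance, which
#' is how it is computed; ties go to the lowest generator atom id.
#' The leaflet is then the one whose assigned generator is nearest in
#' |dz| (minimum image).
#'
#' @param traj an \linkS4class{MDTrajectory} with non-empty
#'   \code{lipidHeads}.
#' @param frame frame index.
#' @return data.frame with one row per water: \code{water},
#'   \code{generator} (atom index), \code{leaflet} (\code{"lower"} /
#'   \code{"upper"}).
#' @export
voronoiAssign <- function(traj, frame = 1L) {
    topo <- topology(traj)
    if (!length(topo@lipidHeads))
        .stopf("topology error: no head-group generators for the Voronoi tessellation")
    m <- coords(traj, frame)
    L <- boxDims(traj, frame)
    gen <- m[topo@lipidHeads, , drop = FALSE]
    wat <- m[topo@waterO, , drop = FALSE]
    zg <- .minImage(gen[, 3], L[3])       # center leaflet z for split
    leafOf <- ifelse(zg > mean(range(zg)), "upper", "lower")
    best <- vector("list", 2L)
    for (li in 1:2) {
        leaf <- c("lower", "upper")[li]
        gi <- which(leafOf == leaf)
        if (!length(gi)) next
        nn <- .nearestGenerator2D(wat, gen[gi, , drop = FALSE], L[1:2])
        gAtom <- topo@lipidHeads[gi[nn]]
        dz <- abs(.minImage(wat[, 3] - gen[gi[nn], 3], L[3]))
        best[[li]] <- list(gen = gAtom, dz = dz)
    }
    if (is.null(best[[1L]]) || is.null(best[[2L]])) {
        li <- which(!vapply(best, is.null, logical(1)))
        pick <- rep(li, nrow(wat))
    } else {
        pick <- ifelse(best[[2L]]$dz < best[[1L]]$dz, 2L, 1L)
    }
    data.frame(
        water = seq_len(nrow(wat)),
        generator = vapply(seq_len(nrow(wat)), function(i)
            best[[pick[i]]]$gen[i], numeric(1)),
        leaflet = c("lower", "upper")[pick])
}

# Nearest generator index under 2-D periodic (xy) distance; ties to
# the lowest generator index (which.min convention).
.nearestGenerator2D <- function(wat, gen, Lxy) {
    dx <- .minImage(outer(wat[, 1], gen[, 1], "-"), Lxy[1])
    dy <- .minImage(outer(wat[, 2], gen[, 2], "-"), Lxy[2])
    d2 <- dx^2 + dy^2
    max.col(-d2, ties.method = "first")
}

#' Signed membrane distance
#'
#' xi = z_water - z_generator for waters assigned to the upper
#' leaflet and z_generator - z_water for the lower leaflet (minimum
#' image in z), so positive xi always points from the membrane toward
#' the water slab and negative xi is the membrane interior.
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @param frame frame index.
#' @param assignment data.frame from \code{\link{voronoiAssign}}
#'   (computed if missing).
#' @return numeric vector of xi, Angstrom, one per water.
#' @export
membraneDistance <- function(traj, frame = 1L,
                             assignment = voronoiAssign(traj, frame)) {
    m <- coords(traj, frame)
    L <- boxDims(traj, frame)
    zw <- m[topology(traj)@waterO, 3]
    zg <- m[assignment$generator, 3]
    dz <- .minImage(zw - zg, L[3])
    ifelse(assignment$leaflet == "upper", dz, -dz)
}

#' Classify membrane regions
#'
#' Region thresholds on the membrane distance: interior (xi < 0),
#' first hydration layer (0 <= xi < 5 Angstrom), exterior
#' (xi >= 5 Angstrom); each boundary belongs to the upper region.
#'
#' @param xi numeric membrane distances, Angstrom.
#' @param firstLayerMax upper edge of the first hydration layer.
#' @return character vector: \code{"interior"}, \code{"first_layer"}
#'   or \code{"exterior"}.
#' @export
classifyRegion <- function(xi, firstLayerMax = 5) {
    stopifnot(all(is.finite(xi)))
    ifelse(xi < 0, "interior",
           ifelse(xi < firstLayerMax, "first_layer", "exterior"))
}

#' Water density profile over the membrane distance
#'
#' Histogram of xi over waters and analyzed frames, weighted to
#' g/cm^3 with the slab volume A_xy x binWidth, plus the mean
#' interfacial density rho_bar = N_w m_w / (A_xy x d).  When the
#' interface width \code{d} is not given it defaults to the total
#' width of the bins whose density exceeds 1 percent of the profile
#' maximum.
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @param binWidth xi bin width, Angstrom.
#' @param every frame stride.
#' @param d interface width, Angstrom (optional).
#' @return list of class \code{DensityProfile}: \code{profile}
#'   (data.frame xiMin, xiMax, xiMid, rho), \code{rhoBar},
#'   \code{Axy}, \code{d}, \code{Nw}, \code{nFramesAnalyzed}.
#' @export
densityProfile <- function(traj, binWidth = 0.5, every = 1L, d = NULL) {
    frames <- seq(1L, nFrames(traj), by = every)
    if (any(traj@box[, 1] * traj@box[, 2] <= 0))
        .stopf("geometry error: zero membrane area")
    xi <- unlist(lapply(frames, function(f)
        membraneDistance(traj, f)))
    Axy <- mean(traj@box[frames, 1] * traj@box[frames, 2])
    nW <- nWaters(traj)
    if (nW == 0L || !length(xi)) {
        prof <- data.frame(xiMin = numeric(), xiMax = numeric(),
                           xiMid = numeric(), rho = numeric())
        out <- list(profile = prof, rhoBar = 0, Axy = Axy,
                    d = if (is.null(d)) 0 else d, Nw = 0L,
                    nFramesAnalyzed = length(frames))
        class(out) <- "DensityProfile"
        return(out)
    }
    lo <- floor(min(xi) / binWidth) * binWidth
    hi <- ceiling(max(xi) / binWidth) * binWidth
    if (hi <= lo) hi <- lo + binWidth
    breaks <- seq(lo, hi, by = binWidth)
    counts <- table(cut(xi, breaks, include.lowest = TRUE,
                        right = FALSE))
    meanCounts <- as.numeric(counts) / length(frames)
    vol_cm3 <- Axy * binWidth * 1e-24
    rho <- meanCounts * .MASS_WATER_G / vol_cm3
    if (is.null(d)) {
        keep <- rho > 0.01 * max(rho)
        d <- sum(keep) * binWidth
    }
    rhoBar <- nW * .MASS_WATER_G / (Axy * d * 1e-24)
    prof <- data.frame(xiMin = breaks[-length(breaks)],
                       xiMax = breaks[-1],
                       xiMid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                       rho = rho)
    out <- list(profile = prof, rhoBar = rhoBar, Axy = Axy, d = d,
                Nw = nW, nFramesAnalyzed = length(frames))
    class(out) <- "DensityProfile"
    out
}

#' @export
print.DensityProfile <- function(x, ...) {
    cat(sprintf(
        "DensityProfile: %d waters, A_xy = %.1f A^2, d = %.1f A, rho_bar = %.3f g/cm^3\n",
        x$Nw, x$Axy, x$d, x$rhoBar))
    invisible(x)
}

#' Region-resolved translational and rotational dynamics
#'
#' Each (molecule, time origin) pair contributes to the region the
#' molecule occupies at the origin; per-region in-plane MSD and dipole
#' correlators are then processed by the standard estimators
#' (diffusive-regime line fit; exponential-tail relaxation integral).
#' Standard errors come from disjoint molecule blocks.  Regions
#' contributing fewer than \code{minOrigins} origins are skipped with
#' a warning.
#'
#' @param traj an unwrapped \linkS4class{MDTrajectory}.
#' @param regionEvery stride (frames) at which the Voronoi region
#'   field is re-evaluated; origins in between use the most recent
#'   evaluation.
#' @param discard MSD transient discarded before the fit, ps.
#' @param msdMaxLag largest MSD lag, ps (default quarter trajectory).
#' @param acfMaxLag largest dipole-correlation lag, ps (default full).
#' @param nLagPoints number of lag points per estimator.
#' @param nBlocks molecule blocks for standard errors.
#' @param minOrigins minimum origins for a region to be reported.
#' @param tailPolicy passed to \code{\link{relaxationTime}}.
#' @return data.frame with one row per region: \code{region},
#'   \code{nOrigins}, \code{occupancy} (mean molecules per frame),
#'   \code{D}, \code{Dse} (nm^2/ns), \code{tauRot}, \code{tauRotSe}
#'   (ps).
#' @export
regionResolvedDynamics <- function(traj, regionEvery = 10L,
                                   discard = 2,
                                   msdMaxLag = NULL, acfMaxLag = NULL,
                                   nLagPoints = 150L, nBlocks = 5L,
                                   minOrigins = 10L,
                                   tailPolicy = "exp-tail") {
    nf <- nFrames(traj)
    dt <- timestep(traj)
    nW <- nWaters(traj)
    evalFrames <- seq(1L, nf, by = regionEvery)
    R <- matrix(NA_character_, nW, length(evalFrames))
    for (j in seq_along(evalFrames)) {
        f <- evalFrames[j]
        R[, j] <- classifyRegion(membraneDistance(traj, f))
    }
    originCol <- findInterval(seq_len(nf), evalFrames)
    Rfull <- R[, originCol, drop = FALSE]      # region at each origin
    X <- .comSeries(traj, seq_len(nW), "mass")
    mu <- waterDipoles(traj)
    if (is.null(msdMaxLag)) msdMaxLag <- (nf - 1L) * dt * 0.25
    if (is.null(acfMaxLag)) acfMaxLag <- (nf - 1L) * dt
    msdLagIdx <- .lagGrid(floor(msdMaxLag / dt), nLagPoints)
    acfLagIdx <- .lagGridLog(floor(acfMaxLag / dt), nLagPoints)
    res <- list()
    for (reg in c("interior", "first_layer", "exterior")) {
        mask <- Rfull == reg
        nOrig <- sum(mask)
        if (nOrig < minOrigins) {
            warning(sprintf(
                "region '%s' skipped: only %d contributing origins",
                reg, nOrig), call. = FALSE)
            next
        }
        mols <- which(rowSums(mask) > 0)
        est <- .maskedEstimates(X, mu, mask, mols, msdLagIdx,
                                acfLagIdx, dt, discard, tailPolicy)
        blocks <- .blockSplit(mols, nBlocks)
        Db <- taub <- rep(NA_real_, length(blocks))
        if (length(blocks) >= 2L) {
            for (b in seq_along(blocks)) {
                eb <- tryCatch(
                    .maskedEstimates(X, mu, mask, blocks[[b]],
                                     msdLagIdx, acfLagIdx, dt,
                                     discard, tailPolicy),
                    error = function(e) NULL)
                if (!is.null(eb)) {
                    Db[b] <- eb$D; taub[b] <- eb$tau
                }
            }
        }
        se <- function(v) {
            v <- v[is.finite(v)]
            if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
            else NA_real_
        }
        res[[reg]] <- data.frame(
            region = reg, nOrigins = nOrig,
            occupancy = nOrig / nf, D = est$D, Dse = se(Db),
            tauRot = est$tau, tauRotSe = se(taub))
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

# lag grid in frames: 0 plus ~n evenly spaced positive lags
.lagGrid <- function(maxLagFrames, nPoints) {
    maxLagFrames <- max(1L, maxLagFrames)
    stride <- max(1L, floor(maxLagFrames / nPoints))
    unique(c(0L, seq(stride, maxLagFrames, by = stride)))
}

# log-spaced lag grid (dense short lags) for correlators that span
# orders of magnitude in decay time
.lagGridLog <- function(maxLagFrames, nPoints) {
    maxLagFrames <- max(1L, maxLagFrames)
    pos <- unique(round(10^seq(0, log10(maxLagFrames),
                               length.out = nPoints)))
    c(0L, as.integer(pos))
}

# Masked (origin-region) MSD + dipole ACF and their estimators for a
# molecule subset.
.maskedEstimates <- function(X, mu, mask, mols, msdLagIdx, acfLagIdx,
                             dt, discard, tailPolicy) {
    msd <- .maskedMSD(X, mask, mols, msdLagIdx)
    msdSeries <- .correlationSeries(msdLagIdx * dt, msd$value, msd$n,
                                    kind = "msd")
    # the lag grid is already truncated to the requested maximum
    D <- fitDiffusion(msdSeries, discard = discard,
                      window = c(discard, max(msdLagIdx) * dt))@D
    acf <- .maskedACF(mu, mask, mols, acfLagIdx)
    v <- acf$value
    v[1] <- 1
    acfSeries <- .correlationSeries(acfLagIdx * dt, v, acf$n,
                                    kind = "acf")
    tau <- relaxationTime(acfSeries, tailPolicy = tailPolicy)@tauRot
    list(D = D, tau = tau)
}

.maskedMSD <- function(X, mask, mols, lagIdx) {
    nf <- ncol(mask)
    value <- n <- numeric(length(lagIdx))
    x <- X[[1L]][mols, , drop = FALSE]
    y <- X[[2L]][mols, , drop = FALSE]
    mk <- mask[mols, , drop = FALSE]
    for (k in seq_along(lagIdx)) {
        tau <- lagIdx[k]
        o <- seq_len(nf - tau)
        dx <- x[, o + tau, drop = FALSE] - x[, o, drop = FALSE]
        dy <- y[, o + tau, drop = FALSE] - y[, o, drop = FALSE]
        m <- mk[, o, drop = FALSE]
        n[k] <- sum(m)
        value[k] <- if (n[k] > 0)
            sum((dx^2 + dy^2) * m) / n[k] else NA_real_
    }
    list(value = value, n = n)
}

.maskedACF <- function(mu, mask, mols, lagIdx) {
    nf <- dim(mu)[3]
    value <- n <- numeric(length(lagIdx))
    mk <- mask[mols, , drop = FALSE]
    v1 <- mu[mols, 1, , drop = FALSE]; dim(v1) <- c(length(mols), nf)
    v2 <- mu[mols, 2, , drop = FALSE]; dim(v2) <- c(length(mols), nf)
    v3 <- mu[mols, 3, , drop = FALSE]; dim(v3) <- c(length(mols), nf)
    for (k in seq_along(lagIdx)) {
        tau <- lagIdx[k]
        o <- seq_len(nf - tau)
        dotp <- v1[, o + tau, drop = FALSE] * v1[, o, drop = FALSE] +
            v2[, o + tau, drop = FALSE] * v2[, o, drop = FALSE] +
            v3[, o + tau, drop = FALSE] * v3[, o, drop = FALSE]
        m <- mk[, o, drop = FALSE]
        n[k] <- sum(m)
        value[k] <- if (n[k] > 0) sum(dotp * m) / n[k] else NA_real_
    }
    list(value = value, n = n)
}
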