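#' In-plane Brownian water trajectories
#'
#' Generates waters performing independent 2-D Brownian motion in the
#' membrane (xy) plane with a prescribed lateral diffusion coefficient:
#' per-axis Gaussian steps with variance 2 D dt.  Each molecule carries
#' two rigid hydrogens at a fixed offset so the result is a complete,
#' valid water topology; z is constant.  Coordinates are wrapped into
#' the box, so run \code{\link{unwrapCoordinates}} before MSD analysis.
#'
#' @param D lateral diffusion coefficient, nm^2/ns.
#' @param nMolecules number of waters.
#' @param nSteps number of frames (>= 2).
#' @param dt frame spacing, ps.
#' @param box length-3 box edges, Angstrom.
#' @param seed RNG seed (mandatory: generators are deterministic).
#' @return an \linkS4class{MDTrajectory}; the ground truth is stored in
#'   \code{trajMetadata(x)$groundTruth$D}.
#' @export
generateBrownian2D <- function(D, nMolecules, nSteps, dt, box, seed) {
    if (D < 0 || dt <= 0)
        .stopf("parameter error: D must be >= 0 and dt > 0")
    if (nSteps < 2L) .stopf("parameter error: need nSteps >= 2")
    set.seed(seed)
    n <- as.integer(nMolecules)
    sigma <- sqrt(2 * (D / .A2_PER_PS_TO_NM2_PER_NS) * dt)  # Angstrom
    xy <- array(NA_real_, c(n, 2L, nSteps))
    xy[, 1L, 1L] <- stats::runif(n, 0, box[1])
    xy[, 2L, 1L] <- stats::runif(n, 0, box[2])
    for (ax in 1:2) {
        steps <- matrix(stats::rnorm(n * (nSteps - 1L), sd = sigma),
                        nrow = n)
        for (j in 2:nSteps)
            xy[, ax, j] <- xy[, ax, j - 1L] + steps[, j - 1L]
    }
    coords <- array(0, c(3L * n, 3L, nSteps))
    coords[seq_len(n), 1:2, ] <- xy
    coords[seq_len(n), 3L, ] <- box[3] / 2
    # rigid hydrogens translated with the oxygen (fixed orientation)
    h1 <- c(0.7572, 0.5860, 0); h2 <- c(-0.7572, 0.5860, 0)
    for (ax in 1:3) {
        coords[n + seq_len(n), ax, ] <- coords[seq_len(n), ax, ] + h1[ax]
        coords[2L * n + seq_len(n), ax, ] <-
            coords[seq_len(n), ax, ] + h2[ax]
    }
    topo <- waterTopology(seq_len(n),
                          cbind(n + seq_len(n), 2L * n + seq_len(n)))
    traj <- mdTrajectory(coords, box = box, topology = topo, dt = dt,
                         metadata = list(generator = "brownian2d",
                                         seed = seed,
                                         groundTruth = list(D = D)))
    wrapCoordinates(traj)
}

#' Rotational-diffusion dipole series
#'
#' Unit vectors evolving by small random rotations (isotropic
#' rotational diffusion): per step the orientation is rotated by a
#' random rotation vector with independent components of variance
#' dt/tau, which makes the rank-1 orientational correlator decay as
#' exp(-t/tau).
#'
#' @param tau target rank-1 relaxation time, ps; \code{Inf} freezes the
#'   vectors.
#' @param nMolecules number of rotors.
#' @param nSteps number of frames.
#' @param dt frame spacing, ps; must satisfy dt < tau/2.
#' @param seed RNG seed.
#' @return array \code{[nMolecules, 3, nSteps]} of unit vectors with
#'   attributes \code{tau} and \code{dt}.
#' @export
generateRotationalDiffusion <- function(tau, nMolecules, nSteps, dt,
                                        seed) {
    if (tau <= 0) .stopf("parameter error: tau must be positive")
    if (is.finite(tau) && dt >= tau / 2)
        .stopf("discretization error: dt = %g ps is too coarse for tau = %g ps (need dt < tau/2)",
               dt, tau)
    set.seed(seed)
    n <- as.integer(nMolecules)
    v <- .randomUnitVectors(n)
    out <- array(NA_real_, c(n, 3L, nSteps))
    out[, , 1L] <- v
    sd <- if (is.finite(tau)) sqrt(dt / tau) else 0
    for (f in seq_len(nSteps - 1L)) {
        if (sd > 0) {
            w <- matrix(stats::rnorm(3L * n, sd = sd), ncol = 3L)
            v <- .rotateByVectors(v, w)
        }
        out[, , f + 1L] <- v
    }
    attr(out, "tau") <- tau
    attr(out, "dt") <- dt
    out
}

#' Mixture of rotational populations
#'
#' Concatenates independent rotational-diffusion populations with
#' prescribed relaxation times and fractions; the resulting ensemble
#' dipole correlator is the corresponding sum of exponentials (the
#' three-population model when three components are given).
#'
#' @param taus numeric vector of relaxation times, ps.
#' @param fractions matching population fractions (summing to 1).
#' @inheritParams generateRotationalDiffusion
#' @return array \code{[nMolecules, 3, nSteps]} with attributes
#'   \code{taus}, \code{fractions} (realized, after rounding to whole
#'   molecules) and \code{dt}.
#' @export
generateRotationalMixture <- function(taus, fractions, nMolecules,
                                      nSteps, dt, seed) {
    if (length(taus) != length(fractions))
        .stopf("parameter error: taus and fractions must match")
    if (abs(sum(fractions) - 1) > 1e-8)
        .stopf("parameter error: fractions must sum to 1")
    counts <- .apportion(nMolecules, fractions)
    parts <- vector("list", length(taus))
    for (i in seq_along(taus)) {
        if (counts[i] == 0L) next
        parts[[i]] <- generateRotationalDiffusion(
            taus[i], counts[i], nSteps, dt, seed = seed + i)
    }
    keep <- !vapply(parts, is.null, logical(1))
    out <- array(NA_real_, c(nMolecules, 3L, nSteps))
    at <- 0L
    for (p in parts[keep]) {
        out[at + seq_len(dim(p)[1]), , ] <- p
        at <- at + dim(p)[1]
    }
    attr(out, "taus") <- taus
    attr(out, "fractions") <- counts / sum(counts)
    attr(out, "dt") <- dt
    out
}

# Largest-remainder apportionment of n among fractions.
.apportion <- function(n, fractions) {
    raw <- n * fractions
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
        take <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
        counts[take] <- counts[take] + 1
    }
    as.integer(counts)
}

.randomUnitVectors <- function(n) {
    v <- matrix(stats::rnorm(3L * n), ncol = 3L)
    v / sqrt(rowSums(v^2))
}

# Rodrigues rotation of row vectors v by rotation vectors w.
.rotateByVectors <- function(v, w) {
    th <- sqrt(rowSums(w^2))
    th[th == 0] <- .Machine$double.eps
    k <- w / th
    ct <- cos(th); st <- sin(th)
    kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
                 k[, 3] * v[, 1] - k[, 1] * v[, 3],
                 k[, 1] * v[, 2] - k[, 2] * v[, 1])
    kdv <- rowSums(k * v)
    out <- v * ct + kxv * st + k * (kdv * (1 - ct))
    out / sqrt(rowSums(out^2))
}

#' Two-state hydrogen-bond telegraph process
#'
#' Stationary bonded/unbonded Markov chains with exponential dwell
#' times, observed on a regular grid: the exact discrete skeleton of
#' the continuous-time telegraph process is simulated, so the
#' ground-truth intermittent correlator is
#' C(t) = pi + (1 - pi) exp(-t (1/meanOn + 1/meanOff)) with stationary
#' occupancy pi = meanOn / (meanOn + meanOff).
#'
#' @param meanOn,meanOff mean bonded / unbonded dwell times, ps
#'   (\code{meanOff = Inf} gives pure decay from a bonded start).
#' @param nPairs number of independent chains.
#' @param nSteps number of frames.
#' @param dt frame spacing, ps; a spacing coarser than
#'   \code{min(meanOn, meanOff)/5} triggers a discretization warning.
#' @param seed RNG seed.
#' @param start \code{"stationary"} (default) or \code{"bonded"}.
#' @return integer matrix \code{[nPairs, nSteps]} of bond indicators
#'   with attributes \code{meanOn}, \code{meanOff}, \code{dt},
#'   \code{tauC} (the closed-form correlation time) and \code{pi}.
#' @export
generateHBTelegraph <- function(meanOn, meanOff, nPairs, nSteps, dt,
                                seed, start = c("stationary", "bonded")) {
    start <- match.arg(start)
    if (meanOn <= 0 || meanOff <= 0)
        .stopf("parameter error: dwell times must be positive")
    if (dt > min(meanOn, meanOff) / 5)
        warning(sprintf(
            "discretization warning: dt = %g ps is coarse for dwell times (%g, %g) ps",
            dt, meanOn, meanOff), call. = FALSE)
    set.seed(seed)
    kOn <- 1 / meanOn
    kOff <- if (is.finite(meanOff)) 1 / meanOff else 0
    piOn <- kOff / (kOn + kOff)        # = meanOn/(meanOn+meanOff)
    tauC <- 1 / (kOn + kOff)
    decay <- exp(-dt / tauC)
    p11 <- piOn + (1 - piOn) * decay   # P(on -> on) over dt
    p01 <- piOn * (1 - decay)          # P(off -> on) over dt
    state <- if (start == "bonded") rep(1L, nPairs)
             else stats::rbinom(nPairs, 1L, piOn)
    out <- matrix(0L, nPairs, nSteps)
    out[, 1L] <- state
    for (j in seq_len(nSteps - 1L)) {
        u <- stats::runif(nPairs)
        state <- ifelse(state == 1L, as.integer(u < p11),
                        as.integer(u < p01))
        out[, j + 1L] <- state
    }
    structure(out, meanOn = meanOn, meanOff = meanOff, dt = dt,
              tauC = tauC, pi = piOn)
}

#' Specification of a synthetic layered membrane system
#'
#' Bundles the parameters of \code{\link{generateMembraneSystem}}: a
#' jittered-lattice membrane scaffold, a layered water density profile
#' over the membrane distance xi, and region-dependent translational /
#' rotational dynamics.  Defaults emulate a fully hydrated stacked
#' DMPC system at desk scale: head groups on an 8 Angstrom lattice,
#' leaflets at z = +/-15 Angstrom in a 60 Angstrom box, and the
#' region-resolved dynamics of the membrane interior (slowest), first
#' hydration layer, and exterior (near-bulk) regions; the trajectory
#' length (600 ps) is at least twice the slowest relaxation time.
#'
#' @param nLipidsPerLeaflet head-group lattice sites per leaflet.
#' @param latticeSpacing Angstrom between head groups.
#' @param headJitter Gaussian jitter (sd, Angstrom) of head positions.
#' @param leafletZ length-2, z of the lower and upper leaflet planes.
#' @param nWaters total water count.
#' @param regionD named (interior, first_layer, exterior) lateral
#'   diffusion coefficients, nm^2/ns.
#' @param regionTauRot named rank-1 rotational relaxation times, ps.
#' @param densityProfile data.frame with columns \code{xiMin},
#'   \code{xiMax}, \code{weight} (relative number density per band) or
#'   \code{count} (absolute waters per band, must sum to nWaters).
#' @param hbLifetimes named (ww, wl) mean HB lifetimes, ps (metadata
#'   for companion telegraph fixtures).
#' @param nSteps,dt frames and frame spacing (ps).
#' @param boxZ box height, Angstrom.
#' @param seed RNG seed (mandatory).
#' @param regionMargin Angstrom by which density bands are pulled back
#'   from the region boundaries (xi = 0 and 5) when waters are placed,
#'   so head-group jitter cannot flip a water across its region
#'   boundary; default three times the head jitter.
#' @return a list of class \code{LayeredSystemSpec}.
#' @export
layeredSystemSpec <- function(nLipidsPerLeaflet = 16,
                              latticeSpacing = 8,
                              headJitter = 0.5,
                              leafletZ = c(-15, 15),
                              nWaters = 240,
                              regionD = c(interior = 0.19,
                                          first_layer = 0.81,
                                          exterior = 4.10),
                              regionTauRot = c(interior = 270,
                                               first_layer = 37,
                                               exterior = 3.3),
                              densityProfile = data.frame(
                                  xiMin = c(-4, 0, 5),
                                  xiMax = c(0, 5, 14),
                                  weight = c(0.30, 1.00, 0.95)),
                              hbLifetimes = c(ww = 4.0, wl = 38),
                              nSteps = 6000, dt = 0.1,
                              boxZ = 60, seed = 1,
                              regionMargin = 3 * headJitter) {
    spec <- list(nLipidsPerLeaflet = as.integer(nLipidsPerLeaflet),
                 latticeSpacing = latticeSpacing,
                 headJitter = headJitter, leafletZ = sort(leafletZ),
                 nWaters = as.integer(nWaters), regionD = regionD,
                 regionTauRot = regionTauRot,
                 densityProfile = densityProfile,
                 hbLifetimes = hbLifetimes,
                 nSteps = as.integer(nSteps), dt = dt, boxZ = boxZ,
                 seed = as.integer(seed), regionMargin = regionMargin)
    class(spec) <- "LayeredSystemSpec"
    .validateLayeredSpec(spec)
    spec
}

.validateLayeredSpec <- function(spec) {
    if (any(spec$regionD < 0) || any(spec$regionTauRot <= 0) ||
        any(spec$hbLifetimes <= 0))
        .stopf("spec error: rates and lifetimes must be positive")
    if (diff(spec$leafletZ) <= 0)
        .stopf("spec error: leaflet separation must be positive")
    dp <- spec$densityProfile
    if (!is.null(dp$weight) && any(dp$weight < 0))
        .stopf("spec error: densities must be non-negative")
    if (any(dp$xiMax <= dp$xiMin))
        .stopf("spec error: density bands must have positive width")
    if (!is.null(dp$count) && sum(dp$count) != spec$nWaters)
        .stopf("spec error: density profile integrates to %d waters but nWaters = %d",
               sum(dp$count), spec$nWaters)
    invisible(TRUE)
}

#' Synthetic layered membrane trajectory
#'
#' Builds an end-to-end test system with known ground truth: two
#' leaflets of head-group (P, N) generators on a jittered lattice, two
#' lipid acceptor oxygens per head, and waters placed by a layered
#' density profile over the membrane distance xi.  Waters keep their
#' initial z (no cross-region exchange), diffuse in-plane with the
#' diffusion coefficient of their region and reorient by rotational
#' diffusion with the relaxation time of their region; hydrogen
#' positions follow the dipole orientation rigidly.
#'
#' @param spec a \code{\link{layeredSystemSpec}}.
#' @return an \linkS4class{MDTrajectory} whose
#'   \code{trajMetadata(x)$groundTruth} records the per-water region,
#'   xi offset, and the region-level D and tau_rot truths.
#' @export
generateMembraneSystem <- function(spec) {
    stopifnot(inherits(spec, "LayeredSystemSpec"))
    .validateLayeredSpec(spec)
    set.seed(spec$seed)
    nl <- spec$nLipidsPerLeaflet
    nx <- ceiling(sqrt(nl))
    Lxy <- nx * spec$latticeSpacing
    box <- c(Lxy, Lxy, spec$boxZ)
    grid <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(nx) - 1L)
    grid <- grid[seq_len(nl), ]
    # Head-group scaffold (static): P and N per lipid, 2 acceptor O.
    headP <- headN <- accO <- NULL
    for (leaf in 1:2) {
        z0 <- spec$leafletZ[leaf]
        px <- (grid$ix + 0.5) * spec$latticeSpacing +
            stats::rnorm(nl, sd = spec$headJitter)
        py <- (grid$iy + 0.5) * spec$latticeSpacing +
            stats::rnorm(nl, sd = spec$headJitter)
        pz <- z0 + stats::rnorm(nl, sd = spec$headJitter)
        nxo <- px + 2.2 + stats::rnorm(nl, sd = spec$headJitter / 2)
        nyo <- py + stats::rnorm(nl, sd = spec$headJitter / 2)
        # acceptors sit slightly toward the membrane interior
        inward <- if (leaf == 1L) 1 else -1
        a1 <- cbind(px + 1.2, py, pz + inward * 1.0)
        a2 <- cbind(px - 1.2, py, pz + inward * 1.0)
        headP <- rbind(headP, cbind(px, py, pz))
        headN <- rbind(headN, cbind(nxo, nyo, pz))
        accO <- rbind(accO, a1, a2)
    }
    # Water placement from the layered density profile.
    dp <- spec$densityProfile
    widths <- dp$xiMax - dp$xiMin
    counts <- if (!is.null(dp$count)) as.integer(dp$count)
              else .apportion(spec$nWaters, dp$weight * widths /
                                  sum(dp$weight * widths))
    nW <- sum(counts)
    # Density bands whose edges sit on a region boundary (xi = 0 or
    # 5 Angstrom) are shrunk by regionMargin, so that the membrane
    # distance measured against a jittered head group still classifies
    # every water into its generated region (the fixture keeps waters
    # in their region by construction, for clean parameter recovery).
    marg <- spec$regionMargin
    bounds <- c(0, 5)
    lo <- dp$xiMin + ifelse(dp$xiMin %in% bounds, marg, 0)
    hi <- dp$xiMax - ifelse(dp$xiMax %in% bounds, marg, 0)
    if (any(hi <= lo))
        .stopf("spec error: regionMargin %.2f leaves an empty density band", marg)
    xi <- unlist(lapply(seq_len(nrow(dp)), function(b)
        stats::runif(counts[b], lo[b], hi[b])))
    leaflet <- sample(c(1L, 2L), nW, replace = TRUE)
    zW <- ifelse(leaflet == 2L, spec$leafletZ[2] + xi,
                 spec$leafletZ[1] - xi)
    region <- classifyRegion(xi)
    # Region-dependent in-plane Brownian motion.
    nf <- spec$nSteps
    xyO <- array(NA_real_, c(nW, 2L, nf))
    xyO[, 1L, 1L] <- stats::runif(nW, 0, Lxy)
    xyO[, 2L, 1L] <- stats::runif(nW, 0, Lxy)
    sig <- sqrt(2 * (spec$regionD[region] / .A2_PER_PS_TO_NM2_PER_NS) *
                spec$dt)
    for (ax in 1:2) {
        steps <- matrix(stats::rnorm(nW * (nf - 1L)), nrow = nW) * sig
        for (j in 2:nf)
            xyO[, ax, j] <- xyO[, ax, j - 1L] + steps[, j - 1L]
    }
    # Region-dependent rotational diffusion of the dipole axis.
    mu <- array(NA_real_, c(nW, 3L, nf))
    v <- .randomUnitVectors(nW)
    mu[, , 1L] <- v
    sdRot <- sqrt(spec$dt / spec$regionTauRot[region])
    for (f in seq_len(nf - 1L)) {
        w <- matrix(stats::rnorm(3L * nW), ncol = 3L) * sdRot
        v <- .rotateByVectors(v, w)
        mu[, , f + 1L] <- v
    }
    # Assemble atoms: waters (O, H1, H2 blocks), then P, N, acceptors.
    nHead <- nrow(headP)
    natm <- 3L * nW + 2L * nHead + nrow(accO)
    coords <- array(0, c(natm, 3L, nf))
    coords[seq_len(nW), 1:2, ] <- xyO
    coords[seq_len(nW), 3L, ] <- zW
    bH <- 0.9572 * cos(52.26 * pi / 180)
    aH <- 0.9572 * sin(52.26 * pi / 180)
    for (f in seq_len(nf)) {
        p <- .perpUnit(mu[, , f])
        coords[nW + seq_len(nW), , f] <-
            coords[seq_len(nW), , f] + bH * mu[, , f] + aH * p
        coords[2L * nW + seq_len(nW), , f] <-
            coords[seq_len(nW), , f] + bH * mu[, , f] - aH * p
    }
    headIdx <- 3L * nW + seq_len(2L * nHead)
    accIdx <- 3L * nW + 2L * nHead + seq_len(nrow(accO))
    scaffold <- rbind(headP, headN, accO)
    for (f in seq_len(nf))
        coords[c(headIdx, accIdx), , f] <- scaffold
    topo <- waterTopology(
        seq_len(nW), cbind(nW + seq_len(nW), 2L * nW + seq_len(nW)),
        lipidHeads = headIdx, lipidAcceptors = accIdx,
        hydrationLevel = nW / (2L * nl))
    traj <- mdTrajectory(coords, box = box, topology = topo,
                         dt = spec$dt,
                         metadata = list(
                             generator = "membrane_system",
                             seed = spec$seed, spec = spec,
                             groundTruth = list(
                                 region = region, xi = xi,
                                 leaflet = leaflet,
                                 regionD = spec$regionD,
                                 regionTauRot = spec$regionTauRot)))
    wrapCoordinates(traj)
}

# A unit vector perpendicular to each row of v, chosen from the
# coordinate axis least aligned with v (deterministic).
.perpUnit <- function(v) {
    ref <- matrix(0, nrow(v), 3L)
    ax <- max.col(-abs(v))            # least-aligned axis
    ref[cbind(seq_len(nrow(v)), ax)] <- 1
    p <- ref - v * rowSums(ref * v)
    p / sqrt(rowSums(p^2))
}
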