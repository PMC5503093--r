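#' Bond indicator series
#'
#' Runs hydrogen-bond detection on a stride of frames and builds the
#' intermittent bond-indicator matrix: the pair universe is every
#' (water, partner) pair bonded in at least one analyzed frame, and an
#' entry is 1 when that pair is bonded in that frame, with no
#' continuity requirement (a bond may break and reform).  Pair
#' identity is the unordered water pair for water-water bonds and the
#' (water, lipid acceptor atom) pair for water-lipid bonds.
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @param partnerClass \code{"water"} or \code{"lipid"}.
#' @param records optional precomputed list of per-frame record
#'   data.frames (as from \code{\link{detectHBonds}}), to avoid
#'   re-detection when both partner classes are analyzed.
#' @param every frame stride.
#' @param dOOmax,angleMax criterion cutoffs.
#' @return integer matrix \code{[pairs, frames]} with attributes
#'   \code{dt} (ps between analyzed frames) and \code{pairs} (pair
#'   labels); a zero-row matrix when no bond is ever observed.
#' @export
bondIndicatorSeries <- function(traj, partnerClass = c("water", "lipid"),
                                records = NULL, every = 1L,
                                dOOmax = 3.5, angleMax = 30) {
    partnerClass <- match.arg(partnerClass)
    frames <- seq(1L, nFrames(traj), by = every)
    if (is.null(records))
        records <- lapply(frames, function(f)
            detectHBonds(traj, f, dOOmax = dOOmax, angleMax = angleMax))
    keys <- lapply(records, function(rec) {
        rec <- rec[rec$acceptorClass == partnerClass, , drop = FALSE]
        if (!nrow(rec)) return(character())
        if (partnerClass == "water")
            unique(paste(pmin(rec$donor, rec$acceptorWater),
                         pmax(rec$donor, rec$acceptorWater), sep = "-"))
        else unique(paste(rec$donor, rec$acceptor, sep = "-"))
    })
    universe <- unique(unlist(keys))
    if (!length(universe)) {
        out <- matrix(0L, 0L, length(frames))
        attr(out, "dt") <- timestep(traj) * every
        attr(out, "pairs") <- character()
        return(out)
    }
    out <- matrix(0L, length(universe), length(frames))
    rownames(out) <- universe
    for (j in seq_along(frames))
        out[keys[[j]], j] <- 1L
    attr(out, "dt") <- timestep(traj) * every
    attr(out, "pairs") <- universe
    out
}

#' Intermittent hydrogen-bond correlation function
#'
#' C(tau) = sum over pairs and origins of n(t0) n(t0 + tau), divided
#' by the matching sum of n(t0) (pooled normalization, single ratio of
#' sums), so C(0) = 1 by construction.  Computed exactly for all lags
#' with FFT autocorrelation sums.
#'
#' @param indicators matrix \code{[pairs, frames]} of 0/1 bond
#'   indicators (from \code{\link{bondIndicatorSeries}} or
#'   \code{\link{generateHBTelegraph}}).
#' @param dt frame spacing, ps; defaults to the matrix's \code{dt}
#'   attribute.
#' @param maxLag largest lag, ps.
#' @param perPair if \code{TRUE}, average per-pair normalized
#'   correlators instead of pooling (alternative normalization).
#' @return a \linkS4class{CorrelationSeries} of kind \code{"hb"}.
#' @export
hbCorrelation <- function(indicators, dt = attr(indicators, "dt"),
                          maxLag = NULL, perPair = FALSE) {
    if (is.null(dt)) .stopf("sampling error: dt not given")
    x <- as.matrix(indicators)
    if (nrow(x) == 0L || sum(x) == 0)
        .stopf("undefined-correlator error: no bonded pair in the indicator matrix")
    n <- ncol(x)
    nLag <- if (is.null(maxLag)) n - 1L else min(n - 1L, floor(maxLag / dt))
    S2 <- .acfSums(t(x))[seq_len(nLag + 1L), , drop = FALSE]
    # denominator: sum over origins 1..(n - tau) of n(t0), per pair
    cums <- apply(x, 1L, cumsum)               # [frames, pairs]
    den <- cums[n - (0:nLag), , drop = FALSE]
    if (perPair) {
        ok <- den > 0
        ratio <- matrix(0, nLag + 1L, ncol(S2))
        ratio[ok] <- S2[ok] / den[ok]
        vals <- rowSums(ratio) / rowSums(ok)
    } else {
        vals <- rowSums(S2) / rowSums(den)
    }
    vals[1] <- 1
    .correlationSeries((0:nLag) * dt, vals,
                       nrow(x) * (n - (0:nLag)), kind = "hb")
}

#' Hydrogen-bond relaxation time
#'
#' The time integral of the intermittent bond correlator.  This is the
#' same quadrature/extrapolation code as the rotational
#' \code{\link{relaxationTime}} (shared implementation), so identical
#' input series give bit-identical integrals.
#'
#' @inheritParams relaxationTime
#' @return a \linkS4class{RotRelaxation}; \code{tauRot} is the HB
#'   relaxation time in ps.
#' @export
hbRelaxationTime <- function(corr, tailPolicy = c("exp-tail", "truncate"),
                             plateau = 0, decayThreshold = 0.05) {
    relaxationTime(corr, tailPolicy = tailPolicy, plateau = plateau,
                   decayThreshold = decayThreshold)
}

#' Water-lipid slowdown factor
#'
#' kappa = tau_HB(water-lipid) / tau_HB(water-water): how much longer
#' water-lipid hydrogen bonds persist than water-water bonds.
#'
#' @param tauWL water-lipid HB relaxation time, ps.
#' @param tauWW water-water HB relaxation time, ps.
#' @return list with \code{kappa} (rounded to 2 significant figures,
#'   the reporting convention) and \code{raw}.
#' @examples
#' slowdownFactor(38, 4.0)$kappa   # 9.5
#' @export
slowdownFactor <- function(tauWL, tauWW) {
    if (tauWW <= 0 || tauWL <= 0)
        .stopf("parameter error: relaxation times must be positive")
    raw <- tauWL / tauWW
    list(kappa = signif(raw, 2), raw = raw)
}

#' Full hydrogen-bond kinetics analysis
#'
#' Detects bonds on a stride of frames, builds both indicator
#' matrices, computes both intermittent correlators and their
#' relaxation times, and the slowdown factor.
#'
#' @inheritParams bondIndicatorSeries
#' @param maxLag largest lag, ps.
#' @param tailPolicy passed to \code{\link{hbRelaxationTime}}.
#' @return list with \code{corrWW}, \code{corrWL}
#'   (\linkS4class{CorrelationSeries}), \code{tauWW}, \code{tauWL}
#'   (ps), \code{kappa} (2 significant figures) and \code{kappaRaw}.
#'   Correlator entries are \code{NULL}/\code{NA} for a partner class
#'   never observed.
#' @export
hbKinetics <- function(traj, every = 1L, maxLag = NULL,
                       tailPolicy = "exp-tail", dOOmax = 3.5,
                       angleMax = 30) {
    frames <- seq(1L, nFrames(traj), by = every)
    records <- lapply(frames, function(f)
        detectHBonds(traj, f, dOOmax = dOOmax, angleMax = angleMax))
    out <- list(corrWW = NULL, corrWL = NULL, tauWW = NA_real_,
                tauWL = NA_real_, kappa = NA_real_, kappaRaw = NA_real_)
    for (cls in c("water", "lipid")) {
        ind <- bondIndicatorSeries(traj, cls, records = records,
                                   every = every)
        if (nrow(ind) == 0L) next
        corr <- hbCorrelation(ind, maxLag = maxLag)
        tau <- hbRelaxationTime(corr, tailPolicy = tailPolicy)@tauRot
        if (cls == "water") {
            out$corrWW <- corr; out$tauWW <- tau
        } else {
            out$corrWL <- corr; out$tauWL <- tau
        }
    }
    if (is.finite(out$tauWW) && is.finite(out$tauWL)) {
        k <- slowdownFactor(out$tauWL, out$tauWW)
        out$kappa <- k$kappa; out$kappaRaw <- k$raw
    }
    out
}
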