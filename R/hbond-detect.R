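#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: a water donor hydrogen is bonded to an
#' acceptor oxygen (water oxygen or lipid phosphate/ester oxygen) when
#' the donor-acceptor oxygen distance satisfies dOO < 3.5 Angstrom and
#' the angle between the donor O-H bond and the O->O direction is
#' < 30 degrees (both inequalities strict, minimum-image convention).
#' Water is always the donor for water-lipid bonds.  One record is
#' emitted per (hydrogen, acceptor) pair that satisfies the criterion.
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @param frame frame index.
#' @param dOOmax,angleMax criterion cutoffs (Angstrom, degrees).
#' @param method \code{"grid"} (cell-list neighbor search, default) or
#'   \code{"brute"} (all-pairs reference path); results are identical.
#' @return data.frame with one row per bond: \code{frame},
#'   \code{donor} (water molecule index), \code{hydrogen} (1 or 2),
#'   \code{acceptor} (atom index), \code{acceptorClass}
#'   (\code{"water"}/\code{"lipid"}), \code{acceptorWater} (molecule
#'   index, \code{NA} for lipids), \code{dOO}, \code{angleHOO}.
#' @export
detectHBonds <- function(traj, frame = 1L, dOOmax = 3.5, angleMax = 30,
                         method = c("grid", "brute")) {
    method <- match.arg(method)
    topo <- topology(traj)
    m <- coords(traj, frame)
    L <- boxDims(traj, frame)
    nW <- nWaters(topo)
    don <- m[topo@waterO, , drop = FALSE]
    accIdx <- c(topo@waterO, topo@lipidAcceptors)
    accClass <- rep(c("water", "lipid"),
                    c(nW, length(topo@lipidAcceptors)))
    accWater <- c(seq_len(nW), rep(NA_integer_,
                                   length(topo@lipidAcceptors)))
    acc <- m[accIdx, , drop = FALSE]
    cand <- if (method == "brute") .pairsBrute(don, acc, L, dOOmax)
            else .pairsGrid(don, acc, L, dOOmax)
    if (nrow(cand)) {            # drop self (water donating to itself)
        self <- accClass[cand$acceptor] == "water" &
            accWater[cand$acceptor] == cand$donor
        cand <- cand[!self, , drop = FALSE]
    }
    if (!nrow(cand))
        return(.emptyHBRecords())
    # angle test at the donor oxygen, for each of the two hydrogens
    recs <- vector("list", 2L)
    for (h in 1:2) {
        iH <- if (h == 1L) topo@waterH1 else topo@waterH2
        rOH <- .minImage(m[iH[cand$donor], , drop = FALSE] -
                         don[cand$donor, , drop = FALSE],
                         rep(L, each = nrow(cand)))
        dOH <- sqrt(rowSums(rOH^2))
        cosang <- rowSums(rOH * as.matrix(cand[, c("dx", "dy", "dz")])) /
            (dOH * cand$dOO)
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        keep <- ang < angleMax
        if (any(keep))
            recs[[h]] <- data.frame(
                frame = frame, donor = cand$donor[keep], hydrogen = h,
                acceptor = accIdx[cand$acceptor[keep]],
                acceptorClass = accClass[cand$acceptor[keep]],
                acceptorWater = accWater[cand$acceptor[keep]],
                dOO = cand$dOO[keep], angleHOO = ang[keep])
    }
    out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(out)) return(.emptyHBRecords())
    out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
}

.emptyHBRecords <- function() {
    data.frame(frame = integer(), donor = integer(),
               hydrogen = integer(), acceptor = integer(),
               acceptorClass = character(), acceptorWater = integer(),
               dOO = numeric(), angleHOO = numeric())
}

# All-pairs candidate search (strict cutoff), minimum image.
.pairsBrute <- function(don, acc, L, cutoff) {
    nd <- nrow(don); na <- nrow(acc)
    di <- rep(seq_len(nd), times = na)
    ai <- rep(seq_len(na), each = nd)
    d <- .minImage(acc[ai, , drop = FALSE] - don[di, , drop = FALSE],
                   rep(L, each = nd * na))
    dOO <- sqrt(rowSums(d^2))
    keep <- dOO < cutoff
    data.frame(donor = di[keep], acceptor = ai[keep],
               dx = d[keep, 1], dy = d[keep, 2], dz = d[keep, 3],
               dOO = dOO[keep])
}

# Cell-list candidate search; falls back to all-pairs when the box is
# too small to hold 3 cells per axis.
.pairsGrid <- function(don, acc, L, cutoff) {
    nc <- pmax(1L, floor(L / cutoff))
    if (any(nc < 3L)) return(.pairsBrute(don, acc, L, cutoff))
    wAcc <- sweep(.wrapInto(acc, rep(L, each = nrow(acc))), 2, L / nc, "/")
    cellA <- pmin(floor(wAcc), matrix(nc - 1L, nrow(acc), 3,
                                      byrow = TRUE))
    idA <- cellA[, 1] + nc[1] * (cellA[, 2] + nc[2] * cellA[, 3])
    accByCell <- split(seq_len(nrow(acc)), idA)
    wDon <- sweep(.wrapInto(don, rep(L, each = nrow(don))), 2, L / nc, "/")
    cellD <- pmin(floor(wDon), matrix(nc - 1L, nrow(don), 3,
                                      byrow = TRUE))
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    out <- vector("list", nrow(don))
    for (i in seq_len(nrow(don))) {
        nb <- sweep(off, 2, cellD[i, ], "+")
        nb <- sweep(nb, 2, nc, function(a, b) a %% b)
        ids <- unique(nb[, 1] + nc[1] * (nb[, 2] + nc[2] * nb[, 3]))
        cIdx <- unlist(accByCell[as.character(ids)], use.names = FALSE)
        if (!length(cIdx)) next
        d <- .minImage(acc[cIdx, , drop = FALSE] -
                       matrix(don[i, ], length(cIdx), 3, byrow = TRUE),
                       rep(L, each = length(cIdx)))
        dOO <- sqrt(rowSums(d^2))
        keep <- dOO < cutoff
        if (any(keep))
            out[[i]] <- data.frame(donor = i, acceptor = cIdx[keep],
                                   dx = d[keep, 1], dy = d[keep, 2],
                                   dz = d[keep, 3], dOO = dOO[keep])
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out))
        return(data.frame(donor = integer(), acceptor = integer(),
                          dx = numeric(), dy = numeric(),
                          dz = numeric(), dOO = numeric()))
    do.call(rbind, out)
}

#' Per-water hydrogen-bond counts
#'
#' From one frame's bond records, counts for every water molecule the
#' number of water-water bonds it participates in (donated or
#' accepted; pairwise multiplicity capped at one, so a pair linked by
#' both donor hydrogens still counts once) and the number of bonds it
#' donates to lipid acceptors.
#'
#' @param records data.frame from \code{\link{detectHBonds}} (one
#'   frame).
#' @param nWaters total number of water molecules.
#' @return data.frame with columns \code{water}, \code{nWat},
#'   \code{nLip}.
#' @export
hbCountsPerWater <- function(records, nWaters) {
    if (nrow(records)) {
        aw <- records$acceptorWater
        known <- is.na(aw) | (aw >= 1L & aw <= nWaters)
        if (any(records$donor > nWaters) || !all(known))
            .stopf("index error: record references an unknown water id")
    }
    nWat <- integer(nWaters); nLip <- integer(nWaters)
    ww <- records[records$acceptorClass == "water", , drop = FALSE]
    if (nrow(ww)) {
        pair <- cbind(pmin(ww$donor, ww$acceptorWater),
                      pmax(ww$donor, ww$acceptorWater))
        pair <- unique(pair)
        tab <- table(factor(c(pair[, 1], pair[, 2]),
                            levels = seq_len(nWaters)))
        nWat <- as.integer(tab)
    }
    wl <- records[records$acceptorClass == "lipid", , drop = FALSE]
    if (nrow(wl)) {
        tab <- table(factor(wl$donor, levels = seq_len(nWaters)))
        nLip <- as.integer(tab)
    }
    data.frame(water = seq_len(nWaters), nWat = nWat, nLip = nLip)
}

#' Hydrogen-bond structure summary
#'
#' Detects bonds on a stride of frames and aggregates the structural
#' statistics: the mean number of bonds per water, the share of
#' water-lipid bonds, normalized histograms of the per-water bond
#' counts (water-water, water-lipid, total; counts above \code{nMax}
#' are pooled into the top bin with a warning), and the joint
#' (nWat, nLip) distribution.
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @param every frame stride (1 = every frame).
#' @param nMax largest histogram bin.
#' @param dOOmax,angleMax criterion cutoffs.
#' @return a list of class \code{HBStructureSummary}: \code{meanNHB},
#'   \code{lipidFraction}, \code{distWW}, \code{distWL},
#'   \code{distTotal} (named numeric over 0..nMax), \code{joint}
#'   (matrix nWat x nLip), \code{nFramesAnalyzed}.
#' @export
hbStructureSummary <- function(traj, every = 1L, nMax = 5L,
                               dOOmax = 3.5, angleMax = 30) {
    frames <- seq(1L, nFrames(traj), by = every)
    nW <- nWaters(traj)
    hWW <- hWL <- hTot <- numeric(nMax + 1L)
    joint <- matrix(0, nMax + 1L, nMax + 1L,
                    dimnames = list(nWat = 0:nMax, nLip = 0:nMax))
    nWW <- 0; nWL <- 0; sumNHB <- 0
    overflow <- FALSE
    for (f in frames) {
        rec <- detectHBonds(traj, f, dOOmax = dOOmax,
                            angleMax = angleMax)
        cnt <- hbCountsPerWater(rec, nW)
        nWWf <- nrow(unique(cbind(
            pmin(rec$donor, rec$acceptorWater),
            pmax(rec$donor, rec$acceptorWater))[
                rec$acceptorClass == "water", , drop = FALSE]))
        nWW <- nWW + nWWf
        nWL <- nWL + sum(rec$acceptorClass == "lipid")
        tot <- cnt$nWat + cnt$nLip
        sumNHB <- sumNHB + sum(tot)
        if (any(c(cnt$nWat, cnt$nLip, tot) > nMax)) overflow <- TRUE
        hWW <- hWW + tabulate(pmin(cnt$nWat, nMax) + 1L, nMax + 1L)
        hWL <- hWL + tabulate(pmin(cnt$nLip, nMax) + 1L, nMax + 1L)
        hTot <- hTot + tabulate(pmin(tot, nMax) + 1L, nMax + 1L)
        iw <- pmin(cnt$nWat, nMax) + 1L
        il <- pmin(cnt$nLip, nMax) + 1L
        for (k in seq_len(nW))
            joint[iw[k], il[k]] <- joint[iw[k], il[k]] + 1
    }
    if (overflow)
        warning(sprintf(
            "bond counts above %d pooled into the top histogram bin",
            nMax), call. = FALSE)
    nObs <- length(frames) * nW
    totalBonds <- nWW + nWL
    out <- list(
        meanNHB = sumNHB / nObs,
        lipidFraction = if (totalBonds > 0) nWL / totalBonds else 0,
        distWW = stats::setNames(hWW / nObs, 0:nMax),
        distWL = stats::setNames(hWL / nObs, 0:nMax),
        distTotal = stats::setNames(hTot / nObs, 0:nMax),
        joint = joint / nObs,
        nFramesAnalyzed = length(frames))
    class(out) <- "HBStructureSummary"
    out
}

#' @export
print.HBStructureSummary <- function(x, ...) {
    cat(sprintf(
        "HBStructureSummary: <nHB> = %.3f per water, %.1f%% of bonds are water-lipid (%d frames)\n",
        x$meanNHB, 100 * x$lipidFraction, x$nFramesAnalyzed))
    invisible(x)
}
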