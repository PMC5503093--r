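#' Water dipole directions
#'
#' Unit vector along the HOH bisector of each water molecule,
#' mu = normalize((rH1 - rO) + (rH2 - rO)), with hydrogen positions
#' taken relative to the oxygen under the minimum-image convention so
#' molecules split across the periodic boundary are handled correctly.
#' For a rigid three-site water model this direction coincides with the
#' molecular dipole.
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @param frame single frame index; omit for all frames.
#' @param tol hydrogens farther than this from their oxygen (after
#'   minimum image) indicate a broken molecule, Angstrom.
#' @return for a single frame an \code{[nWaters, 3]} matrix of unit
#'   vectors; otherwise an \code{[nWaters, 3, frames]} array.
#' @examples
#' topo <- waterTopology(1L, c(2L, 3L))
#' co <- array(0, c(3, 3, 1))
#' co[2, , 1] <- c(0.76, 0.59, 0); co[3, , 1] <- c(-0.76, 0.59, 0)
#' traj <- mdTrajectory(co, box = c(20, 20, 20), topology = topo, dt = 1)
#' waterDipoles(traj, frame = 1)   # (0, 1, 0)
#' @export
waterDipoles <- function(traj, frame = NULL, tol = 1.5) {
    if (!is.null(frame))
        return(.dipoleFrame(traj, frame, tol))
    nf <- nFrames(traj)
    out <- array(NA_real_, c(nWaters(traj), 3L, nf))
    for (f in seq_len(nf)) out[, , f] <- .dipoleFrame(traj, f, tol)
    out
}

.dipoleFrame <- function(traj, frame, tol) {
    topo <- topology(traj)
    m <- coords(traj, frame)
    L <- boxDims(traj, frame)
    rO <- m[topo@waterO, , drop = FALSE]
    d1 <- .minImage(m[topo@waterH1, , drop = FALSE] - rO,
                    rep(L, each = nrow(rO)))
    d2 <- .minImage(m[topo@waterH2, , drop = FALSE] - rO,
                    rep(L, each = nrow(rO)))
    if (any(sqrt(rowSums(d1^2)) > tol) || any(sqrt(rowSums(d2^2)) > tol))
        .stopf("degenerate-dipole error: OH distance exceeds %.2f Angstrom (broken water geometry)", tol)
    bis <- d1 + d2
    nrm <- sqrt(rowSums(bis^2))
    if (any(nrm < 1e-8))
        .stopf("degenerate-dipole error: opposing OH vectors give a null bisector")
    bis / nrm
}
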