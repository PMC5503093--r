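#' Unwrap periodic coordinates
#'
#' Makes atomic trajectories continuous across the periodic boundaries
#' by accumulating minimum-image steps: each consecutive-frame
#' displacement is mapped into \code{(-L/2, L/2]} per axis and summed.
#' This is exact provided no atom truly moves half a box edge or more
#' between saved frames (the unwrap precondition; a violation is
#' indistinguishable from a legitimate wrap after the fact).
#' Required before any mean-square-displacement analysis.
#'
#' @param traj an \linkS4class{MDTrajectory} with wrapped coordinates.
#' @return an \linkS4class{MDTrajectory} with continuous coordinates;
#'   positions are congruent to the input modulo the box, and
#'   \code{trajMetadata(x)$unwrapped} is set.  Idempotent on already
#'   continuous trajectories.
#' @examples
#' traj <- generateBrownian2D(D = 1, nMolecules = 3, nSteps = 50,
#'                            dt = 0.1, box = c(10, 10, 10), seed = 1)
#' u <- unwrapCoordinates(traj)
#' max(abs(u@coords[, 1, ] - traj@coords[, 1, ]) %% 10)  # congruent
#' @export
unwrapCoordinates <- function(traj) {
    nf <- nFrames(traj)
    if (nf < 2L) return(traj)
    out <- traj@coords
    natm <- nAtoms(traj)
    for (ax in 1:3) {
        x <- traj@coords[, ax, , drop = FALSE]
        dim(x) <- c(natm, nf)                 # atoms x frames
        L <- traj@box[, ax]
        dx <- x[, -1L, drop = FALSE] - x[, -nf, drop = FALSE]
        Lm <- rep(L[-1L], each = natm)
        dx <- dx - Lm * round(dx / Lm)
        if (ncol(dx) > 1L)
            for (j in 2:ncol(dx)) dx[, j] <- dx[, j - 1L] + dx[, j]
        out[, ax, ] <- cbind(x[, 1L], x[, 1L] + dx)
    }
    md <- traj@metadata
    md$unwrapped <- TRUE
    initialize(traj, coords = out, metadata = md)
}

#' Wrap coordinates into the primary box
#'
#' Maps all positions into \code{[0, L)} per axis.  Inverse (modulo the
#' lattice) of \code{\link{unwrapCoordinates}}.
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @return an \linkS4class{MDTrajectory} with wrapped coordinates.
#' @export
wrapCoordinates <- function(traj) {
    out <- traj@coords
    for (ax in 1:3) {
        L <- traj@box[, ax]
        out[, ax, ] <- .wrapInto(traj@coords[, ax, ],
                                 rep(L, each = dim(out)[1]))
    }
    md <- traj@metadata
    md$unwrapped <- FALSE
    initialize(traj, coords = out, metadata = md)
}
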