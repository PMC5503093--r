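#' Accessors for the core containers
#'
#' Small accessor functions so user code never touches slots directly.
#'
#' @param x a \linkS4class{MDTrajectory}, \linkS4class{WaterTopology} or
#'   \linkS4class{CorrelationSeries}.
#' @param frame integer frame index (for \code{coords}/\code{boxDims});
#'   omit to get all frames.
#' @return the requested component: counts are integers, \code{coords}
#'   returns an \code{[atoms, 3]} matrix for one frame or the full
#'   \code{[atoms, 3, frames]} array, \code{boxDims} a length-3 vector
#'   or \code{[frames, 3]} matrix.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nWaters", "WaterTopology", function(x) length(x@waterO))

#' @rdname accessors
setMethod("nWaters", "MDTrajectory", function(x) length(x@topology@waterO))

#' @rdname accessors
setMethod("nFrames", "MDTrajectory", function(x) dim(x@coords)[3])

#' @rdname accessors
setMethod("nAtoms", "MDTrajectory", function(x) dim(x@coords)[1])

#' @rdname accessors
setMethod("timestep", "MDTrajectory", function(x) {
    if (nFrames(x) < 2L) return(NA_real_)
    x@times[2] - x@times[1]
})

#' @rdname accessors
setMethod("frameTimes", "MDTrajectory", function(x) x@times)

#' @rdname accessors
setMethod("boxDims", "MDTrajectory", function(x, frame) {
    if (missing(frame)) return(x@box)
    x@box[frame, ]
})

#' @rdname accessors
setMethod("topology", "MDTrajectory", function(x) x@topology)

#' @rdname accessors
setMethod("coords", "MDTrajectory", function(x, frame) {
    if (missing(frame)) return(x@coords)
    x@coords[, , frame, drop = FALSE][, , 1]
})

#' @rdname accessors
setMethod("trajMetadata", "MDTrajectory", function(x) x@metadata)

#' @rdname accessors
setMethod("lagTimes", "CorrelationSeries", function(x) x@lags)

#' @rdname accessors
setMethod("corValues", "CorrelationSeries", function(x) x@values)

#' @rdname accessors
setMethod("nPairs", "CorrelationSeries", function(x) x@nPairs)

setMethod("show", "WaterTopology", function(object) {
    cat("WaterTopology:", nWaters(object), "waters,",
        length(object@lipidHeads), "head-group atoms,",
        length(object@lipidAcceptors), "lipid acceptor oxygens\n")
    if (!is.na(object@hydrationLevel))
        cat("  hydration level (waters per lipid):",
            object@hydrationLevel, "\n")
})

setMethod("show", "MDTrajectory", function(object) {
    cat("MDTrajectory:", nAtoms(object), "atoms,",
        nFrames(object), "frames, dt =", timestep(object), "ps\n")
    b <- object@box[1, ]
    cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f Angstrom\n",
                b[1], b[2], b[3]))
    show(object@topology)
    if (isTRUE(object@metadata$unwrapped))
        cat("  coordinates: unwrapped (continuous across the box)\n")
})

setMethod("show", "CorrelationSeries", function(object) {
    unit <- if (object@kind == "msd") "Angstrom^2" else "dimensionless"
    cat(sprintf("CorrelationSeries (%s, %s): %d lags, 0 .. %.4g ps\n",
                object@kind, unit, length(object@lags),
                max(object@lags)))
})

setMethod("show", "DiffusionEstimate", function(object) {
    cat(sprintf(
        "DiffusionEstimate: D%s = %.4g +/- %.2g nm^2/ns (window %.3g-%.3g ps, R^2 = %.4f, %s errors)\n",
        if (object@dim == 2L) "_par" else "", object@D, object@stderr,
        object@window[1], object@window[2], object@rSquared,
        object@method))
})

setMethod("show", "RotRelaxation", function(object) {
    cat(sprintf(
        "RotRelaxation: tau = %.4g ps (%s; tail fraction %.3f)\n",
        object@tauRot, object@method, object@tailFraction))
})

setMethod("show", "TriExpFit", function(object) {
    cat("TriExpFit (fast / bulk-like / irrotational):\n")
    cat(sprintf("  tau = %.4g / %.4g / %.4g ps\n",
                object@tauFast, object@tauBulk, object@tauIrr))
    cat(sprintf("  f   = %.4f / %.4f / %.4f (sum = 1)\n",
                object@fFast, object@fBulk, object@fIrr))
    cat(sprintf("  residual norm = %.3g\n", object@residualNorm))
})
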