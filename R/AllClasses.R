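#' @import methods
NULL

#' Topology of a hydrated membrane system
#'
#' Maps atom indices of a trajectory onto the roles the analyses need:
#' water oxygens and hydrogens, lipid head-group centers (the phosphorus
#' and nitrogen atoms used as Voronoi generators), and the lipid oxygens
#' that can accept a hydrogen bond from water (phosphate and ester
#' oxygens of a phosphatidylcholine lipid).
#'
#' @slot waterO integer vector, oxygen atom index per water molecule.
#' @slot waterH1,waterH2 integer vectors, the two hydrogen atom indices
#'   per water molecule (parallel to \code{waterO}).
#' @slot lipidHeads integer vector of head-group atom indices (P and N),
#'   may be empty when no membrane analyses are requested.
#' @slot lipidAcceptors integer vector of lipid hydrogen-bond acceptor
#'   oxygen indices, may be empty.
#' @slot hydrationLevel numeric, waters per lipid (omega); \code{NA}
#'   when unknown. Metadata only.
#'
#' @export
setClass("WaterTopology",
    representation(
        waterO = "integer",
        waterH1 = "integer",
        waterH2 = "integer",
        lipidHeads = "integer",
        lipidAcceptors = "integer",
        hydrationLevel = "numeric"
    ),
    prototype(
        waterO = integer(), waterH1 = integer(), waterH2 = integer(),
        lipidHeads = integer(), lipidAcceptors = integer(),
        hydrationLevel = NA_real_
    )
)

setValidity("WaterTopology", function(object) {
    msg <- character()
    nw <- length(object@waterO)
    if (length(object@waterH1) != nw || length(object@waterH2) != nw)
        msg <- c(msg, "every water must have exactly one O and two H indices")
    wat <- c(object@waterO, object@waterH1, object@waterH2)
    if (anyDuplicated(wat))
        msg <- c(msg, "water atom indices must be distinct")
    if (anyDuplicated(object@lipidHeads))
        msg <- c(msg, "lipid head indices must be distinct")
    if (anyDuplicated(object@lipidAcceptors))
        msg <- c(msg, "lipid acceptor indices must be distinct")
    all_idx <- c(wat, object@lipidHeads, object@lipidAcceptors)
    if (length(all_idx) && (any(is.na(all_idx)) || any(all_idx < 1L)))
        msg <- c(msg, "atom indices must be positive and non-missing")
    if (length(msg)) msg else TRUE
})

#' Molecular-dynamics trajectory
#'
#' Ordered frames of atomic positions in an orthorhombic periodic box,
#' sampled at a constant timestep, together with the role topology.
#' Positions are in Angstrom and times in picoseconds throughout.
#'
#' @slot topology a \linkS4class{WaterTopology}.
#' @slot coords numeric array \code{[atoms, 3, frames]}, Angstrom.
#' @slot box numeric matrix \code{[frames, 3]} of box edge lengths
#'   (Lx, Ly, Lz), Angstrom.
#' @slot times numeric vector of frame times, ps, uniformly spaced.
#' @slot metadata list of free-form provenance (generator ground truth,
#'   file of origin, unwrapped flag, ...).
#'
#' @export
setClass("MDTrajectory",
    representation(
        topology = "WaterTopology",
        coords = "array",
        box = "matrix",
        times = "numeric",
        metadata = "list"
    ),
    prototype(metadata = list())
)

setValidity("MDTrajectory", function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
        msg <- c(msg, "coords must be an [atoms, 3, frames] array")
    nf <- if (length(d) == 3L) d[3] else 0L
    if (nf < 1L)
        msg <- c(msg, "trajectory needs at least one frame")
    if (!all(is.finite(object@coords)))
        msg <- c(msg, "positions must be finite")
    if (nrow(object@box) != nf || ncol(object@box) != 3L)
        msg <- c(msg, "box must be a [frames, 3] matrix")
    else if (any(object@box <= 0))
        msg <- c(msg, "box edges must be positive")
    if (length(object@times) != nf)
        msg <- c(msg, "times must have one entry per frame")
    if (nf >= 2L) {
        dts <- diff(object@times)
        if (any(dts <= 0))
            msg <- c(msg, "frame times must be strictly increasing")
        else if (max(dts) - min(dts) > 1e-6 * max(dts))
            msg <- c(msg, "frame spacing must be uniform")
    }
    topo <- object@topology
    idx <- c(topo@waterO, topo@waterH1, topo@waterH2,
             topo@lipidHeads, topo@lipidAcceptors)
    if (length(idx) && length(d) == 3L && any(idx > d[1]))
        msg <- c(msg, "topology indices exceed atom count")
    if (length(msg)) msg else TRUE
})

#' Lag-time correlation series
#'
#' A correlation (or mean-square displacement) curve on a grid of lag
#' times, together with the number of (origin, molecule/pair) samples
#' averaged at each lag.  \code{kind} records what the values are:
#' \code{"msd"} (Angstrom^2), \code{"acf"} (dimensionless dipolar
#' correlator), or \code{"hb"} (dimensionless bond correlator).
#'
#' @slot lags numeric, ps, strictly increasing from 0.
#' @slot values numeric, same length as \code{lags}.
#' @slot nPairs numeric, samples averaged per lag (non-increasing).
#' @slot kind character scalar.
#'
#' @export
setClass("CorrelationSeries",
    representation(
        lags = "numeric",
        values = "numeric",
        nPairs = "numeric",
        kind = "character"
    ),
    prototype(kind = "acf")
)

setValidity("CorrelationSeries", function(object) {
    msg <- character()
    n <- length(object@lags)
    if (n < 1L || object@lags[1] != 0)
        msg <- c(msg, "lags must start at 0")
    if (n > 1L && any(diff(object@lags) <= 0))
        msg <- c(msg, "lags must be strictly increasing")
    if (length(object@values) != n)
        msg <- c(msg, "values must match lags in length")
    if (length(object@nPairs) != n)
        msg <- c(msg, "nPairs must match lags in length")
    else if (n > 1L && any(diff(object@nPairs) > 0))
        msg <- c(msg, "nPairs must be non-increasing with lag")
    if (!length(object@kind) == 1L)
        msg <- c(msg, "kind must be a single string")
    else if (object@kind %in% c("acf", "hb") && n >= 1L &&
             abs(object@values[1] - 1) > 1e-9)
        msg <- c(msg, "normalized correlators must have value 1 at lag 0")
    if (length(msg)) msg else TRUE
})

#' Lateral diffusion estimate
#'
#' Result of the linear fit of the in-plane mean-square displacement in
#' the diffusive regime: D_parallel = slope / 4 (or slope / 6 for the
#' 3-D bulk reference), reported in nm^2/ns.
#'
#' @slot D numeric, diffusion coefficient, nm^2/ns.
#' @slot stderr numeric, standard error of D, nm^2/ns.
#' @slot window numeric length-2, fit window (t_min, t_max), ps.
#' @slot rSquared numeric, coefficient of determination of the fit.
#' @slot dim integer, spatial dimensionality of the MSD (2 or 3).
#' @slot method character, how the error bar was obtained
#'   (\code{"ols"} or \code{"blocks"}).
#'
#' @export
setClass("DiffusionEstimate",
    representation(
        D = "numeric", stderr = "numeric", window = "numeric",
        rSquared = "numeric", dim = "integer", method = "character"
    )
)

setValidity("DiffusionEstimate", function(object) {
    msg <- character()
    if (length(object@window) != 2L || diff(object@window) <= 0)
        msg <- c(msg, "window must be an increasing (t_min, t_max) pair")
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (!object@dim %in% c(2L, 3L))
        msg <- c(msg, "dim must be 2 or 3")
    if (length(msg)) msg else TRUE
})

#' Model-free relaxation time
#'
#' The time integral of a normalized correlation function, computed by
#' trapezoidal quadrature over the observed lags, optionally extended
#' to infinity with a single exponential fitted to the final decade of
#' the decay.
#'
#' @slot tauRot numeric, relaxation time, ps.
#' @slot tailFraction numeric in [0, 1), share of the integral
#'   contributed by the extrapolated tail.
#' @slot method character, \code{"truncate"} or \code{"exp-tail"}.
#'
#' @export
setClass("RotRelaxation",
    representation(
        tauRot = "numeric", tailFraction = "numeric", method = "character"
    )
)

setValidity("RotRelaxation", function(object) {
    msg <- character()
    if (object@tauRot <= 0)
        msg <- c(msg, "relaxation time must be positive")
    if (object@tailFraction < 0 || object@tailFraction >= 1)
        msg <- c(msg, "tailFraction must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Three-population exponential decomposition
#'
#' Parameters of the constrained fit of a rotational correlator to a
#' sum of three decaying exponentials: fast, bulk-like and irrotational
#' water populations with fractions on the simplex (summing to one) and
#' strictly ordered time constants.
#'
#' @slot tauFast,tauBulk,tauIrr numeric time constants, ps, ordered
#'   tauFast < tauBulk < tauIrr.
#' @slot fFast,fBulk,fIrr numeric fractions, non-negative, summing to 1.
#' @slot residualNorm numeric, Euclidean norm of the fit residuals.
#'
#' @export
setClass("TriExpFit",
    representation(
        tauFast = "numeric", tauBulk = "numeric", tauIrr = "numeric",
        fFast = "numeric", fBulk = "numeric", fIrr = "numeric",
        residualNorm = "numeric"
    )
)

setValidity("TriExpFit", function(object) {
    msg <- character()
    taus <- c(object@tauFast, object@tauBulk, object@tauIrr)
    if (any(taus <= 0) || is.unsorted(taus, strictly = TRUE))
        msg <- c(msg, "time constants must be positive and strictly ordered")
    fr <- c(object@fFast, object@fBulk, object@fIrr)
    if (any(fr < 0))
        msg <- c(msg, "fractions must be non-negative")
    if (abs(sum(fr) - 1) > 1e-12)
        msg <- c(msg, "fractions must sum to 1")
    if (length(msg)) msg else TRUE
})
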