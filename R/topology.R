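#' Construct a water/membrane topology
#'
#' @param waterO integer vector of water oxygen atom indices.
#' @param waterH integer matrix \code{[nWaters, 2]} (or length-2 vector
#'   for a single water) of the hydrogen atom indices per water.
#' @param lipidHeads integer vector of lipid head-group (P, N) atom
#'   indices used as Voronoi generators.
#' @param lipidAcceptors integer vector of lipid hydrogen-bond acceptor
#'   oxygen indices (phosphate and ester oxygens).
#' @param hydrationLevel numeric, waters per lipid (metadata).
#' @return a validated \linkS4class{WaterTopology}.
#' @examples
#' topo <- waterTopology(waterO = c(1L, 4L),
#'                       waterH = rbind(c(2L, 3L), c(5L, 6L)))
#' nWaters(topo)
#' @export
waterTopology <- function(waterO, waterH, lipidHeads = integer(),
                          lipidAcceptors = integer(),
                          hydrationLevel = NA_real_) {
    waterO <- as.integer(waterO)
    if (is.null(dim(waterH))) waterH <- matrix(waterH, ncol = 2)
    waterH <- matrix(as.integer(waterH), ncol = 2)
    if (nrow(waterH) != length(waterO))
        .stopf("role error: need exactly two hydrogens per water (%d waters, %d hydrogen pairs)",
               length(waterO), nrow(waterH))
    if (anyNA(waterH))
        .stopf("role error: missing hydrogen index in topology")
    new("WaterTopology",
        waterO = waterO,
        waterH1 = waterH[, 1], waterH2 = waterH[, 2],
        lipidHeads = as.integer(lipidHeads),
        lipidAcceptors = as.integer(lipidAcceptors),
        hydrationLevel = as.numeric(hydrationLevel))
}

#' Read / write a topology descriptor
#'
#' The descriptor is a small YAML document mapping roles to 1-based
#' atom index lists (and optionally carrying the frame spacing
#' \code{dt} in ps, the box for XYZ input, and the hydration level):
#' \preformatted{
#' dt: 0.1
#' hydration_level: 34
#' water:
#'   oxygens: [1, 4]
#'   hydrogens: [[2, 3], [5, 6]]
#' lipid_heads: [7, 8]
#' lipid_acceptors: [9]
#' box: [20, 20, 20]      # only needed for XYZ input
#' }
#'
#' @param path file path of the YAML descriptor.
#' @return \code{readTopologyDescriptor}: a list with elements
#'   \code{topology} (a \linkS4class{WaterTopology}), \code{dt}
#'   (ps or \code{NA}) and \code{box} (length-3 numeric or \code{NULL}).
#' @export
readTopologyDescriptor <- function(path) {
    spec <- yaml::read_yaml(path)
    if (is.null(spec$water) || is.null(spec$water$oxygens))
        .stopf("role error: descriptor lacks water oxygen indices")
    hyd <- spec$water$hydrogens
    if (is.null(hyd))
        .stopf("role error: descriptor lacks water hydrogen indices")
    nH <- vapply(hyd, length, integer(1))
    if (any(nH != 2L))
        .stopf("role error: water %d has %d hydrogen indices (need 2)",
               which(nH != 2L)[1], nH[nH != 2L][1])
    topo <- waterTopology(
        waterO = unlist(spec$water$oxygens),
        waterH = do.call(rbind, lapply(hyd, as.integer)),
        lipidHeads = as.integer(unlist(spec$lipid_heads)),
        lipidAcceptors = as.integer(unlist(spec$lipid_acceptors)),
        hydrationLevel = if (is.null(spec$hydration_level)) NA_real_
                         else as.numeric(spec$hydration_level))
    list(topology = topo,
         dt = if (is.null(spec$dt)) NA_real_ else as.numeric(spec$dt),
         box = if (is.null(spec$box)) NULL else as.numeric(spec$box))
}

#' @rdname readTopologyDescriptor
#' @param topo a \linkS4class{WaterTopology}.
#' @param dt frame spacing in ps to record alongside the roles.
#' @param box optional length-3 box to record (needed for XYZ files).
#' @export
writeTopologyDescriptor <- function(topo, path, dt = NA_real_,
                                    box = NULL) {
    spec <- list(
        dt = as.numeric(dt),
        water = list(
            oxygens = as.integer(topo@waterO),
            hydrogens = lapply(seq_len(nWaters(topo)), function(i)
                c(topo@waterH1[i], topo@waterH2[i]))),
        lipid_heads = as.integer(topo@lipidHeads),
        lipid_acceptors = as.integer(topo@lipidAcceptors))
    if (!is.na(topo@hydrationLevel))
        spec$hydration_level <- topo@hydrationLevel
    if (!is.null(box)) spec$box <- as.numeric(box)
    yaml::write_yaml(spec, path)
    invisible(path)
}
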