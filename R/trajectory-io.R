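#' Construct a trajectory from coordinates
#'
#' @param coords numeric array \code{[atoms, 3, frames]}, Angstrom.
#' @param box length-3 numeric (constant box) or \code{[frames, 3]}
#'   matrix of orthorhombic box edges, Angstrom.
#' @param topology a \linkS4class{WaterTopology}.
#' @param dt frame spacing, ps (used when \code{times} is missing).
#' @param times explicit frame times, ps.
#' @param metadata free-form provenance list.
#' @return a validated \linkS4class{MDTrajectory}.
#' @export
mdTrajectory <- function(coords, box, topology, dt = NULL, times = NULL,
                         metadata = list()) {
    coords <- as.array(coords)
    nf <- dim(coords)[3]
    if (is.null(times)) {
        if (is.null(dt)) .stopf("sampling error: supply dt or times")
        times <- (seq_len(nf) - 1) * dt
    }
    if (is.null(dim(box)))
        box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    new("MDTrajectory", topology = topology, coords = coords,
        box = box, times = as.numeric(times), metadata = metadata)
}

#' Load a trajectory from disk
#'
#' Reads a multi-model PDB (MODEL/ENDMDL records, CRYST1 box) or a
#' concatenated-frame XYZ file, resolving atom roles through a YAML
#' topology descriptor (see \code{\link{readTopologyDescriptor}}).
#' For XYZ input the box must be given in the descriptor.
#'
#' @param path trajectory file (\code{.pdb} or \code{.xyz}).
#' @param topologySpec path to the YAML descriptor, or a list as
#'   returned by \code{readTopologyDescriptor}.
#' @param dt frame spacing in ps; overrides the descriptor value.
#' @return a validated \linkS4class{MDTrajectory}.
#' @seealso \code{\link{writeTrajectory}}
#' @export
readTrajectory <- function(path, topologySpec, dt = NULL) {
    spec <- if (is.character(topologySpec))
        readTopologyDescriptor(topologySpec) else topologySpec
    if (is.null(dt)) dt <- spec$dt
    if (is.null(dt) || is.na(dt))
        .stopf("sampling error: frame spacing dt not given in descriptor or argument")
    ext <- tolower(tools::file_ext(path))
    raw <- if (ext == "xyz") .readXYZFrames(path)
           else .readPDBFrames(path)
    box <- raw$box
    if (is.null(box)) box <- spec$box
    if (is.null(box))
        .stopf("format error: no box found (CRYST1 record or descriptor 'box')")
    mdTrajectory(raw$coords, box = box, topology = spec$topology,
                 dt = dt, metadata = list(source = path))
}

# Multi-model PDB via bio3d; CRYST1 parsed from the raw lines because
# bio3d's reader does not expose it for multi-model files.
.readPDBFrames <- function(path) {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e)
                        .stopf("format error: %s", conditionMessage(e)))
    xyz <- pdb$xyz                       # [frames, 3*atoms]
    natm <- ncol(xyz) / 3L
    if (natm != round(natm))
        .stopf("format error: inconsistent atom counts across models")
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(natm, 3L, nf))
    for (f in seq_len(nf))
        coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    cl <- grep("^CRYST1", readLines(path), value = TRUE)
    box <- NULL
    if (length(cl)) {
        box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                            substr(cl[1], 25, 33)))
        if (anyNA(box)) box <- NULL
    }
    list(coords = coords, box = box)
}

# Plain XYZ frame series: "natoms\ncomment\nname x y z ..." repeated.
.readXYZFrames <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    pos <- 1L
    frames <- list()
    while (pos <= length(lines)) {
        n <- suppressWarnings(as.integer(trimws(lines[pos])))
        if (is.na(n) || pos + 1L + n > length(lines))
            .stopf("format error: malformed XYZ frame header at line %d", pos)
        block <- lines[(pos + 2L):(pos + 1L + n)]
        fields <- strsplit(trimws(block), "\\s+")
        xyz <- t(vapply(fields, function(f)
            as.numeric(f[2:4]), numeric(3)))
        if (anyNA(xyz))
            .stopf("format error: non-numeric coordinates in XYZ frame")
        frames[[length(frames) + 1L]] <- xyz
        pos <- pos + 2L + n
    }
    natm <- unique(vapply(frames, nrow, integer(1)))
    if (length(natm) != 1L)
        .stopf("format error: inconsistent atom counts across XYZ frames")
    coords <- array(unlist(frames), c(natm, 3L, length(frames)))
    list(coords = coords, box = NULL)
}

#' Write a trajectory to disk
#'
#' Writes a multi-model PDB (one MODEL per frame plus a CRYST1 record)
#' or an XYZ frame series, together with a YAML topology descriptor so
#' the file can be re-loaded with \code{\link{readTrajectory}}.  PDB
#' output carries a single CRYST1 record, so a constant box is
#' required; coordinates round-trip at PDB precision (1e-3 Angstrom).
#'
#' @param traj an \linkS4class{MDTrajectory}.
#' @param path output trajectory file (\code{.pdb} or \code{.xyz}).
#' @param topologyPath output YAML descriptor; default replaces the
#'   trajectory extension with \code{.yaml}.
#' @return invisibly, \code{path}.
#' @export
writeTrajectory <- function(traj, path,
                            topologyPath = paste0(
                                tools::file_path_sans_ext(path), ".yaml")) {
    box <- traj@box
    if (any(abs(sweep(box, 2, box[1, ])) > 1e-9))
        .stopf("format error: file output requires a constant box")
    ext <- tolower(tools::file_ext(path))
    if (ext == "xyz") {
        .writeXYZFrames(traj, path)
    } else {
        .writePDBFrames(traj, path)
    }
    writeTopologyDescriptor(topology(traj), topologyPath,
                            dt = timestep(traj), box = box[1, ])
    invisible(path)
}

.writePDBFrames <- function(traj, path) {
    topo <- topology(traj)
    natm <- nAtoms(traj)
    elety <- rep("X", natm); resid <- rep("UNK", natm)
    resno <- rep(1L, natm)
    elety[topo@waterO] <- "OH2"; elety[topo@waterH1] <- "H1"
    elety[topo@waterH2] <- "H2"
    wat <- c(topo@waterO, topo@waterH1, topo@waterH2)
    resid[wat] <- "HOH"
    resno[topo@waterO] <- seq_len(nWaters(topo))
    resno[topo@waterH1] <- seq_len(nWaters(topo))
    resno[topo@waterH2] <- seq_len(nWaters(topo))
    lip <- c(topo@lipidHeads, topo@lipidAcceptors)
    elety[topo@lipidHeads] <- "P"
    elety[topo@lipidAcceptors] <- "OP"
    resid[lip] <- "LIP"
    resno[lip] <- nWaters(topo) + 1L
    xyz <- t(apply(traj@coords, 3, function(m) as.numeric(t(m))))
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp, xyz = xyz, elety = elety,
                     resid = resid, resno = resno,
                     eleno = seq_len(natm))
    b <- traj@box[1, ]
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                     b[1], b[2], b[3], 90, 90, 90)
    writeLines(c(cryst, readLines(tmp)), path)
    unlink(tmp)
    invisible(path)
}

.writeXYZFrames <- function(traj, path) {
    natm <- nAtoms(traj)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nFrames(traj))) {
        writeLines(c(as.character(natm),
                     sprintf("frame %d t= %.6f ps", f, traj@times[f])),
                   con)
        m <- traj@coords[, , f]
        writeLines(sprintf("X %.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]),
                   con)
    }
    invisible(path)
}
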