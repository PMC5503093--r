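test_that("toy multi-model PDB loads with box, topology and dt", {
    tr <- generateBrownian2D(D = 0.5, nMolecules = 2, nSteps = 3,
                             dt = 0.5, box = c(20, 20, 20), seed = 4)
    pdb <- withr::local_tempfile(fileext = ".pdb")
    yml <- withr::local_tempfile(fileext = ".yaml")
    writeTrajectory(tr, pdb, topologyPath = yml)
    got <- readTrajectory(pdb, yml)
    expect_s4_class(got, "MDTrajectory")
    expect_equal(nWaters(got), 2L)
    expect_equal(nFrames(got), 3L)
    expect_equal(timestep(got), 0.5)
    expect_equal(boxDims(got, 1), c(20, 20, 20))
})

test_that("missing hydrogen in the descriptor is a role error", {
    yml <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(dt = 0.5,
                          water = list(oxygens = list(1L, 4L),
                                       hydrogens = list(c(2L, 3L),
                                                        list(5L)))),
                     yml)
    expect_error(readTopologyDescriptor(yml), "role error")
    expect_error(waterTopology(c(1L, 4L), rbind(c(2L, 3L))),
                 "role error")
})

test_that("write -> load round-trips positions and topology", {
    tr <- generateBrownian2D(D = 1, nMolecules = 5, nSteps = 10,
                             dt = 0.1, box = c(25, 25, 25), seed = 9)
    for (ext in c(".pdb", ".xyz")) {
        f <- withr::local_tempfile(fileext = ext)
        y <- withr::local_tempfile(fileext = ".yaml")
        writeTrajectory(tr, f, topologyPath = y)
        got <- readTrajectory(f, y)
        expect_lt(max(abs(got@coords - tr@coords)), 1e-3)
        expect_identical(topology(got)@waterO, topology(tr)@waterO)
        expect_identical(topology(got)@waterH1, topology(tr)@waterH1)
    }
})

test_that("unwrap restores a boundary crossing and is idempotent", {
    topo <- waterTopology(1L, c(2L, 3L))
    co <- array(0, c(3, 3, 2))
    co[1, 1, ] <- c(19.9, 0.1)     # O crosses +x boundary
    co[2, , 1] <- co[2, , 2] <- c(0.5, 0.5, 0)
    co[3, , 1] <- co[3, , 2] <- c(-0.5, 0.5, 0)
    tr <- mdTrajectory(co, box = c(20, 20, 20),
                       topology = topo, dt = 1)
    u <- unwrapCoordinates(tr)
    expect_equal(u@coords[1, 1, ], c(19.9, 20.1))
    expect_equal(unwrapCoordinates(u)@coords, u@coords)
})

test_that("wrap-then-unwrap recovers a continuous Brownian path", {
    tr <- generateBrownian2D(D = 2, nMolecules = 8, nSteps = 200,
                             dt = 0.1, box = c(12, 12, 12), seed = 3)
    u <- unwrapCoordinates(tr)
    # congruence modulo the box
    expect_lt(max(abs(membranewater:::.wrapInto(u@coords[, 1, ], 12) -
                      tr@coords[, 1, ])), 1e-9)
    # wrapping the unwrapped path and unwrapping again is stable
    u2 <- unwrapCoordinates(wrapCoordinates(u))
    d <- u2@coords - u@coords
    # paths may differ by a whole-lattice offset fixed at frame 1
    off <- d[, , 1]
    expect_lt(max(abs(sweep(d, 1:2, off))), 1e-9)
})

test_that("stationary molecules unwrap to identical coordinates", {
    tr <- generateBrownian2D(D = 0, nMolecules = 4, nSteps = 6,
                             dt = 0.1, box = c(10, 10, 10), seed = 1)
    u <- unwrapCoordinates(tr)
    expect_equal(u@coords, tr@coords)
})

test_that("dipole is the HOH bisector, rotation-equivariant", {
    topo <- waterTopology(1L, c(2L, 3L))
    co <- array(0, c(3, 3, 1))
    co[2, , 1] <- c(0.76, 0.59, 0)
    co[3, , 1] <- c(-0.76, 0.59, 0)
    tr <- mdTrajectory(co, box = c(20, 20, 20), topology = topo,
                       dt = 1)
    expect_equal(drop(waterDipoles(tr, 1)), c(0, 1, 0))
    # rigid 90-degree rotation about z: (x, y) -> (-y, x)
    co2 <- co
    co2[, 1, 1] <- -co[, 2, 1]
    co2[, 2, 1] <- co[, 1, 1]
    tr2 <- mdTrajectory(co2, box = c(20, 20, 20), topology = topo,
                        dt = 1)
    expect_equal(drop(waterDipoles(tr2, 1)), c(-1, 0, 0))
})

test_that("dipoles match the unshifted bisector and survive lattice translations of whole molecules", {
    tr <- randomWaterBox(20, c(15, 15, 15), seed = 21)
    mu <- waterDipoles(tr, 1)
    m <- coords(tr, 1)
    topo <- topology(tr)
    for (w in seq_len(nWaters(tr))) {
        b <- (m[topo@waterH1[w], ] - m[topo@waterO[w], ]) +
             (m[topo@waterH2[w], ] - m[topo@waterO[w], ])
        expect_equal(mu[w, ], b / sqrt(sum(b^2)), tolerance = 1e-12)
    }
    shifted <- tr
    shifted@coords[, 1, ] <- shifted@coords[, 1, ] + 15  # +Lx for all
    expect_equal(waterDipoles(shifted, 1), mu, tolerance = 1e-9)
})

test_that("degenerate opposed hydrogens raise a dipole error", {
    topo <- waterTopology(1L, c(2L, 3L))
    co <- array(0, c(3, 3, 1))
    co[2, , 1] <- c(0.96, 0, 0)
    co[3, , 1] <- c(-0.96, 0, 0)
    tr <- mdTrajectory(co, box = c(20, 20, 20), topology = topo,
                       dt = 1)
    expect_error(waterDipoles(tr, 1), "degenerate-dipole")
})

test_that("trajectory validity rejects broken containers", {
    topo <- waterTopology(1L, c(2L, 3L))
    co <- array(0, c(3, 3, 2))
    expect_error(mdTrajectory(co, box = c(-1, 10, 10),
                              topology = topo, dt = 1), "box")
    expect_error(mdTrajectory(co, box = c(10, 10, 10),
                              topology = topo,
                              times = c(0, 0)), "increasing")
    expect_error(mdTrajectory(co, box = c(10, 10, 10),
                              topology = waterTopology(9L, c(10L, 11L)),
                              dt = 1), "exceed")
})
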