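# Small membrane scene: explicit generators and waters at known z.
makeInterfaceTraj <- function(watXYZ, genXYZ, box = c(32, 32, 60)) {
    nW <- nrow(watXYZ); nG <- nrow(genXYZ)
    co <- array(0, c(3 * nW + nG, 3, 1))
    for (w in seq_len(nW)) {
        co[w, , 1] <- watXYZ[w, ]
        co[nW + w, , 1] <- watXYZ[w, ] + c(0.76, 0.59, 0)
        co[2 * nW + w, , 1] <- watXYZ[w, ] + c(-0.76, 0.59, 0)
    }
    for (g in seq_len(nG)) co[3 * nW + g, , 1] <- genXYZ[g, ]
    topo <- waterTopology(seq_len(nW),
                          cbind(nW + seq_len(nW), 2 * nW + seq_len(nW)),
                          lipidHeads = 3L * nW + seq_len(nG))
    mdTrajectory(co, box = box, topology = topo, dt = 1)
}

test_that("a single generator per leaflet collects every water; ties break to the lowest id", {
    gen <- rbind(c(16, 16, -15), c(16, 16, 15))
    wat <- rbind(c(3, 4, 20), c(30, 1, 22))
    tr <- makeInterfaceTraj(wat, gen)
    va <- voronoiAssign(tr)
    expect_true(all(va$generator == topology(tr)@lipidHeads[2]))
    # two equidistant generators in one leaflet: lowest atom id wins
    gen2 <- rbind(c(8, 16, 15), c(24, 16, 15), c(16, 16, -15))
    wat2 <- matrix(c(16, 10, 20), 1)      # exactly halfway in x
    tr2 <- makeInterfaceTraj(wat2, gen2)
    va2 <- voronoiAssign(tr2)
    expect_equal(va2$generator, topology(tr2)@lipidHeads[1])
    expect_error(voronoiAssign(makeInterfaceTraj(wat2,
        matrix(numeric(0), 0, 3))), "topology error")
})

test_that("projection membership equals brute-force periodic nearest generator on random instances", {
    set.seed(123)
    for (k in 1:100) {
        nG <- 16
        gx <- (rep(1:4, 4) - 0.5) * 8 + rnorm(nG, sd = 0.6)
        gy <- (rep(1:4, each = 4) - 0.5) * 8 + rnorm(nG, sd = 0.6)
        gen <- cbind(gx, gy, 15)      # one flat leaflet
        wat <- cbind(runif(20, 0, 32), runif(20, 0, 32),
                     runif(20, 16, 28))
        tr <- makeInterfaceTraj(wat, gen)
        va <- voronoiAssign(tr)
        nn <- bruteNearest2D(wat, gen, c(32, 32))
        expect_equal(va$generator,
                     topology(tr)@lipidHeads[nn])
    }
})

test_that("membrane distance has the leaflet-aware sign convention", {
    gen <- rbind(c(16, 16, -15), c(16, 16, 15))
    wat <- rbind(c(16, 16, 18),   # 3 A above upper leaflet
                 c(16, 16, 13),   # 2 A below upper leaflet (interior)
                 c(16, 16, -19))  # 4 A below lower leaflet
    tr <- makeInterfaceTraj(wat, gen)
    va <- voronoiAssign(tr)
    xi <- membraneDistance(tr, 1, va)
    expect_equal(va$leaflet, c("upper", "upper", "lower"))
    expect_equal(xi, c(3, -2, 4))
})

test_that("region thresholds and half-open boundaries", {
    expect_equal(classifyRegion(c(-1, 2.5, 5, 0, 7, -0.001)),
                 c("interior", "first_layer", "exterior",
                   "first_layer", "exterior", "interior"))
})

test_that("membrane fixture offsets are recovered exactly with an unjittered lattice", {
    spec <- layeredSystemSpec(nWaters = 60, nSteps = 3,
                              headJitter = 0, regionMargin = 0.5,
                              seed = 17)
    tr <- generateMembraneSystem(spec)
    gt <- trajMetadata(tr)$groundTruth
    xi <- membraneDistance(tr, 1)
    expect_equal(xi, gt$xi, tolerance = 1e-9)
})

test_that("uniform slab density matches the closed form and integrates to the water mass", {
    spec <- layeredSystemSpec(
        nWaters = 120, nSteps = 4, headJitter = 0,
        densityProfile = data.frame(xiMin = 6, xiMax = 12, weight = 1),
        seed = 23)
    tr <- generateMembraneSystem(spec)
    dp <- densityProfile(tr, binWidth = 1, d = 6)
    mW <- 18.015 / 6.02214076e23
    rhoExp <- 120 * mW / (32 * 32 * 6 * 1e-24)
    expect_equal(dp$rhoBar, rhoExp, tolerance = 1e-3)
    inner <- dp$profile$rho[dp$profile$xiMin >= 6.5 &
                            dp$profile$xiMax <= 11.5]
    expect_true(all(abs(inner - rhoExp) / rhoExp < 0.5))
    # sum(rho * bin volume) returns the total water mass
    mass <- sum(dp$profile$rho * dp$Axy * 1 * 1e-24)
    expect_rel_equal(mass, 120 * mW, 1e-6)
})

test_that("region occupancies sum to the water count in every frame", {
    spec <- layeredSystemSpec(nWaters = 50, nSteps = 5, seed = 31)
    tr <- generateMembraneSystem(spec)
    for (f in 1:5) {
        xi <- membraneDistance(tr, f)
        expect_equal(length(xi), 50)
        expect_equal(sum(table(classifyRegion(xi))), 50)
    }
})

test_that("single-region fixture: region-resolved dynamics equal the whole-system estimators", {
    spec <- layeredSystemSpec(
        nWaters = 80, nSteps = 1500, nLipidsPerLeaflet = 16,
        densityProfile = data.frame(xiMin = 7, xiMax = 13, weight = 1),
        regionD = c(interior = 1, first_layer = 1, exterior = 1.8),
        regionTauRot = c(interior = 10, first_layer = 10,
                         exterior = 4),
        seed = 41)
    tr <- unwrapCoordinates(generateMembraneSystem(spec))
    tab <- NULL
    w <- capture_warnings(tab <- regionResolvedDynamics(tr,
                                                        nBlocks = 4))
    expect_true(any(grepl("skipped", w)))
    expect_equal(tab$region, "exterior")
    whole <- estimateDiffusion(tr, window = c(2, 37.5))
    expect_rel_equal(tab$D, whole@D, 0.05)
    acf <- dipoleACF(waterDipoles(tr), dt = timestep(tr))
    tauWhole <- relaxationTime(acf, tailPolicy = "exp-tail")@tauRot
    expect_rel_equal(tab$tauRot, tauWhole, 0.05)
})
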