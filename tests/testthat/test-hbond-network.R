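test_that("criterion geometry: accepted inside, rejected on distance and angle", {
    expect_equal(nrow(detectHBonds(makeWaterPairTraj(3.0, 0))), 1L)
    expect_equal(nrow(detectHBonds(makeWaterPairTraj(3.6, 0))), 0L)
    expect_equal(nrow(detectHBonds(makeWaterPairTraj(3.0, 45))), 0L)
    rec <- detectHBonds(makeWaterPairTraj(3.0, 12))
    expect_equal(rec$acceptorClass, "water")
    expect_equal(rec$angleHOO, 12, tolerance = 1e-6)
})

test_that("criterion boundaries are strict: exactly 3.5 A and exactly 30 degrees are excluded", {
    expect_equal(nrow(detectHBonds(makeWaterPairTraj(3.5, 0))), 0L)
    expect_equal(nrow(detectHBonds(makeWaterPairTraj(3.5 - 1e-9, 0))),
                 1L)
    # angle strictness probed at the computed angle itself: a cutoff
    # exactly equal to the bond angle excludes the bond
    tr <- makeWaterPairTraj(3.0, 12)
    ang <- detectHBonds(tr)$angleHOO[1]
    expect_equal(nrow(detectHBonds(tr, angleMax = ang)), 0L)
    expect_equal(nrow(detectHBonds(tr, angleMax = ang + 1e-9)), 1L)
    expect_equal(nrow(detectHBonds(makeWaterPairTraj(3.0, 30.001))),
                 0L)
    expect_equal(nrow(detectHBonds(makeWaterPairTraj(3.0, 29.999))),
                 1L)
})

test_that("water donates to a lipid oxygen with the lipid class label", {
    topo <- waterTopology(1L, c(2L, 3L), lipidAcceptors = 4L)
    co <- array(0, c(4, 3, 1))
    ang <- 12 * pi / 180
    co[1, , 1] <- c(5, 5, 5)
    co[2, , 1] <- c(5, 5, 5) + 0.96 * c(cos(ang), sin(ang), 0)
    co[3, , 1] <- c(5 - 0.24, 5 - 0.93, 5)
    co[4, , 1] <- c(5 + 2.8, 5, 5)
    tr <- mdTrajectory(co, box = c(20, 20, 20), topology = topo,
                       dt = 1)
    rec <- detectHBonds(tr)
    expect_equal(nrow(rec), 1L)
    expect_equal(rec$acceptorClass, "lipid")
    expect_true(is.na(rec$acceptorWater))
})

test_that("grid-accelerated detection equals O(N^2) brute force on random periodic boxes", {
    for (k in 1:100) {
        box <- c(runif(1, 8, 22), runif(1, 8, 22), runif(1, 8, 22))
        tr <- randomWaterBox(nWaters = 25, box = box, seed = 1000 + k,
                             nLipidO = 5L)
        grid <- detectHBonds(tr, method = "grid")
        brute <- detectHBonds(tr, method = "brute")
        keyG <- paste(grid$donor, grid$hydrogen, grid$acceptor,
                      sep = "/")
        keyB <- paste(brute$donor, brute$hydrogen, brute$acceptor,
                      sep = "/")
        expect_identical(sort(keyG), sort(keyB))
        expect_identical(sort(keyG), bruteHBondKeys(tr, 1))
    }
})

test_that("per-water counts follow the double-counting rule and conservation", {
    rec <- data.frame(frame = 1, donor = c(1L, 2L, 3L),
                      hydrogen = c(1L, 1L, 2L),
                      acceptor = c(4L, 7L, 100L),
                      acceptorClass = c("water", "water", "lipid"),
                      acceptorWater = c(2L, 3L, NA),
                      dOO = 3, angleHOO = 10)
    cnt <- hbCountsPerWater(rec, 4L)
    expect_equal(cnt$nWat, c(1L, 2L, 1L, 0L))
    expect_equal(cnt$nLip, c(0L, 0L, 1L, 0L))
    expect_equal(sum(cnt$nWat), 2L * 2L)   # two unique w-w pairs
    expect_equal(sum(cnt$nLip), 1L)
    bad <- rec; bad$donor[1] <- 99L
    expect_error(hbCountsPerWater(bad, 4L), "index error")
})

test_that("counting identities hold on random record sets", {
    set.seed(77)
    for (k in 1:50) {
        nW <- 12L
        nRec <- sample(0:20, 1)
        if (nRec == 0) next
        donor <- sample(nW, nRec, replace = TRUE)
        cls <- sample(c("water", "lipid"), nRec, replace = TRUE)
        accW <- ifelse(cls == "water",
                       ((donor + sample(nW - 1, nRec, replace = TRUE) - 1)
                        %% nW) + 1, NA)
        rec <- data.frame(frame = 1, donor = donor, hydrogen = 1L,
                          acceptor = ifelse(is.na(accW), 500 +
                                            seq_len(nRec), accW),
                          acceptorClass = cls, acceptorWater = accW,
                          dOO = 3, angleHOO = 5)
        cnt <- hbCountsPerWater(rec, nW)
        ww <- rec[cls == "water", ]
        nPairs <- nrow(unique(cbind(pmin(ww$donor, ww$acceptorWater),
                                    pmax(ww$donor, ww$acceptorWater))))
        expect_equal(sum(cnt$nWat), 2L * nPairs)
        expect_equal(sum(cnt$nLip), sum(cls == "lipid"))
    }
})

test_that("structure summary: point mass, symmetry, and hand-computed average", {
    # ring of 4 waters, each bonded to 2 neighbours -> point mass at 2
    topo <- waterTopology(c(1L, 4L, 7L, 10L),
                          rbind(c(2L, 3L), c(5L, 6L), c(8L, 9L),
                                c(11L, 12L)))
    co <- array(0, c(12, 3, 1))
    pos <- rbind(c(5, 5, 5), c(7.8, 5, 5), c(7.8, 7.8, 5),
                 c(5, 7.8, 5))
    dir <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
    for (w in 1:4) {
        iO <- (w - 1) * 3 + 1
        co[iO, , 1] <- pos[w, ]
        co[iO + 1, , 1] <- pos[w, ] + 0.96 * dir[w, ]   # to next water
        perp <- c(-dir[w, 2], dir[w, 1], 0)
        co[iO + 2, , 1] <- pos[w, ] +
            0.96 * (cos(104.5 * pi / 180) * dir[w, ] +
                    sin(104.5 * pi / 180) * perp)
    }
    tr <- mdTrajectory(co, box = c(50, 50, 50), topology = topo,
                       dt = 1)
    s <- hbStructureSummary(tr)
    expect_equal(s$meanNHB, 2)
    expect_equal(s$lipidFraction, 0)
    expect_equal(as.numeric(s$distTotal), c(0, 0, 1, 0, 0, 0))
    expect_equal(sum(s$distTotal), 1, tolerance = 1e-9)
    expect_equal(sum(s$distWW), 1, tolerance = 1e-9)
    expect_equal(sum(s$joint), 1, tolerance = 1e-9)
    # joint marginals match the single-variable distributions
    expect_equal(rowSums(s$joint), as.numeric(s$distWW),
                 ignore_attr = TRUE)
    expect_equal(colSums(s$joint), as.numeric(s$distWL),
                 ignore_attr = TRUE)
    # mean of dist_total equals meanNHB
    expect_equal(sum(as.numeric(names(s$distTotal)) * s$distTotal),
                 s$meanNHB)
})

test_that("zero bonds give a degenerate but valid summary", {
    topo <- waterTopology(c(1L, 4L), rbind(c(2L, 3L), c(5L, 6L)))
    co <- array(0, c(6, 3, 1))
    co[1, , 1] <- c(5, 5, 5); co[4, , 1] <- c(25, 25, 25)
    for (w in c(1L, 4L)) {
        co[w + 1L, , 1] <- co[w, , 1] + c(0.96, 0, 0)
        co[w + 2L, , 1] <- co[w, , 1] + c(-0.24, 0.93, 0)
    }
    tr <- mdTrajectory(co, box = c(40, 40, 40), topology = topo,
                       dt = 1)
    s <- hbStructureSummary(tr)
    expect_equal(s$meanNHB, 0)
    expect_equal(s$lipidFraction, 0)
    expect_equal(as.numeric(s$distTotal)[1], 1)
})
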