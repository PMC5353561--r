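test_that("expression gate uses a closed lower bound on the mean", {
    m <- randomMatrix(5, 4, mean = 10)
    m[1, ] <- 4          # exactly at the default threshold
    m[2, ] <- 3.999
    study <- makeStudy(m)
    flags <- flagExpressed(study)
    expect_true(flags[["g001"]])
    expect_false(flags[["g002"]])
    # brute-force recomputation on random data
    m2 <- randomMatrix(50, 6, seed = 9, mean = 4, sd = 2)
    study2 <- makeStudy(m2)
    expect_identical(unname(flagExpressed(study2)),
                     unname(apply(m2, 1, mean) >= 4))
})

test_that("NEA rule: null case, forced direction, degenerate input", {
    m <- randomMatrix(8, 6, mean = 9)
    m[, 4:6] <- m[, 1:3]           # treatment identical to control
    cs <- makeContrastStudy(m, 3, 3)
    deg <- callDegNEA(cs$study, cs$contrast)
    expect_true(all(deg$call == "ns"))
    expect_equal(deg$fc, rep(1, 8))

    m2 <- rbind(gU = c(9, 9, 9, 7, 7, 7), gT = c(5, 5, 5, 5, 5, 5))
    colnames(m2) <- paste0("s", 1:6)
    cs2 <- makeContrastStudy(m2, 3, 3)
    deg2 <- callDegNEA(cs2$study, cs2$contrast)
    expect_equal(deg2$fc[deg2$gene == "gU"], 4)      # 2^(9-7)
    expect_identical(deg2$call[deg2$gene == "gU"], "up")
    # all values tied: p forced to 1, never a call
    expect_equal(deg2$p[deg2$gene == "gT"], 1)
    expect_identical(deg2$call[deg2$gene == "gT"], "ns")
})

test_that("NEA calls require both the fold-change and the p gate", {
    set.seed(4)
    m <- randomMatrix(40, 12, seed = 4, mean = 9, sd = 0.3)
    m[1:10, 1:8] <- m[1:10, 1:8] + 1        # strong planted effect
    cs <- makeContrastStudy(m, 8, 4)
    deg <- callDegNEA(cs$study, cs$contrast)
    up <- deg$call == "up"; down <- deg$call == "down"
    expect_true(all(deg$fc[up] > 1.2) && all(deg$p[up] < 0.05))
    expect_true(all(deg$fc[down] < 1 / 1.2) && all(deg$p[down] < 0.05))
    expect_true(all(up[1:10]))
    # exact-test variant stays well-defined at these group sizes
    degEx <- callDegNEA(cs$study, cs$contrast,
                        pipelineConfig(rankTest = "ranksum_exact"))
    expect_true(all(degEx$p >= 0 & degEx$p <= 1))
    # at 8v4 the exact test can still reject: planted genes with full
    # separation keep their calls
    sep <- vapply(seq_len(nrow(m)), function(i)
        min(m[i, 1:8]) > max(m[i, 9:12]), logical(1))
    expect_true(all(degEx$call[sep & seq_len(nrow(m)) <= 10] == "up"))
})

test_that("NEA direction antisymmetry: swapping groups maps up<->down", {
    for (seed in 1:5) {
        m <- randomMatrix(30, 7, seed = seed, mean = 9, sd = 0.8)
        cs <- makeContrastStudy(m, 3, 4)
        fwd <- callDegNEA(cs$study, cs$contrast)
        swapped <- contrastDesign("c1", controlSamples(cs$contrast),
                                  treatmentSamples(cs$contrast))
        rev <- callDegNEA(cs$study, swapped)
        expect_equal(rev$fc, 1 / fwd$fc, tolerance = 1e-12)
        expect_equal(rev$p, fwd$p, tolerance = 1e-12)
        map <- c(up = "down", down = "up", ns = "ns",
                 not_expressed = "not_expressed")
        expect_identical(rev$call, unname(map[fwd$call]))
    }
})

test_that("adding a constant to all log2 values changes no call", {
    for (seed in 1:3) {
        m <- randomMatrix(25, 6, seed = seed, mean = 9, sd = 0.7)
        cs <- makeContrastStudy(m, 3, 3)
        base <- callDegNEA(cs$study, cs$contrast)
        cs2 <- makeContrastStudy(m + 2.5, 3, 3)
        shifted <- callDegNEA(cs2$study, cs2$contrast)
        expect_identical(shifted$call, base$call)
        expect_equal(shifted$fc, base$fc, tolerance = 1e-9)
        # EA rule: relative differences are also shift-invariant
        study <- makeStudy(m, c("parent", rep("evolved", 5)))
        ea1 <- callDegEA(study, "s01", paste0("s0", 2:6))
        study2 <- makeStudy(m + 2.5, c("parent", rep("evolved", 5)))
        ea2 <- callDegEA(study2, "s01", paste0("s0", 2:6))
        expect_identical(ea2$call, ea1$call)
        expect_equal(ea2$mean_rel_diff, ea1$mean_rel_diff,
                     tolerance = 1e-9)
    }
})

test_that("EA rule: forced cases and unanimity", {
    # parent at linear 100, six evolved at linear 130: +30% unanimous
    m <- rbind(gA = log2(c(100, rep(130, 6))))
    colnames(m) <- c("p0", paste0("e", 1:6))
    study <- makeStudy(m, c("parent", rep("evolved", 6)))
    ea <- callDegEA(study, "p0", paste0("e", 1:6))
    expect_identical(ea$call, "up")
    expect_equal(ea$mean_rel_diff, 0.3, tolerance = 1e-12)
    # one strain below the parent breaks unanimity
    m2 <- rbind(gA = log2(c(100, rep(130, 5), 90)))
    colnames(m2) <- colnames(m)
    study2 <- makeStudy(m2, c("parent", rep("evolved", 6)))
    expect_identical(callDegEA(study2, "p0", paste0("e", 1:6))$call, "ns")
})

test_that("EA rule matches a brute-force oracle on random vectors", {
    oracle <- function(parent, evolved, thr = 0.20) {
        d <- 2^evolved - 2^parent
        if (all(d > 0) && mean(d) / 2^parent > thr) return("up")
        if (all(d < 0) && mean(abs(d)) / 2^parent > thr) return("down")
        "ns"
    }
    set.seed(11)
    for (i in 1:200) {
        parent <- runif(1, 6, 10)
        evolved <- parent + rnorm(6, 0, 0.4)
        m <- rbind(g1 = c(parent, evolved))
        colnames(m) <- c("p0", paste0("e", 1:6))
        study <- makeStudy(m, c("parent", rep("evolved", 6)))
        got <- callDegEA(study, "p0", paste0("e", 1:6))$call
        expect_identical(got, oracle(parent, evolved))
    }
})

test_that("negating one evolved difference abolishes an up call", {
    set.seed(21)
    for (i in 1:30) {
        parent <- runif(1, 6, 10)
        evolved <- parent + runif(6, 0.4, 1)   # unanimous strong up
        for (j in 1:6) {
            pert <- evolved
            pert[j] <- parent - (pert[j] - parent)
            m <- rbind(g1 = c(parent, pert))
            colnames(m) <- c("p0", paste0("e", 1:6))
            study <- makeStudy(m, c("parent", rep("evolved", 6)))
            expect_false(
                callDegEA(study, "p0", paste0("e", 1:6))$call == "up")
        }
    }
})

test_that("group errors and the signed-rank variant are well-defined", {
    m <- randomMatrix(5, 6, mean = 9)
    study <- makeStudy(m)
    expect_error(callDegNEA(study,
        contrastDesign("x", "nosuch", "s04")), "absent")
    expect_error(callDegEA(study, "nosuch", c("s01", "s02")), "parent")
    expect_error(callDegEA(study, "s01", "s02"), "at least 2")
    cs <- makeContrastStudy(m, 4, 2)
    deg <- callDegNEA(cs$study, cs$contrast,
                      pipelineConfig(rankTest = "signedrank"))
    expect_true(all(deg$p >= 0 & deg$p <= 1))
})

test_that("null data yield a DEG rate bounded near alpha", {
    cfg <- synthConfig(nGenes = 1000, neaEthanol = 3, neaTreatReps = 8,
                       neaCtrlReps = 4, degFraction = 0, effectSize = 0,
                       nDoseSets = 0, aberrantFraction = 0,
                       notExpressedFraction = 0, seed = 5L)
    net <- generateNetwork(cfg)
    nea <- generateNEAStudy(cfg, net)
    deg <- callDegNEA(nea$study, nea$contrasts[[1]])
    rate <- mean(deg$call %in% c("up", "down"))
    expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})
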