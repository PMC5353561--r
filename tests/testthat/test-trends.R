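# direct pairwise-comparison oracle for the monotone classifier
monotoneOracle <- function(s, tol = 0) {
    d <- diff(s)
    if (all(d >= -tol) && any(d > tol)) return("monotone_up")
    if (all(d <= tol) && any(d < -tol)) return("monotone_down")
    "non_monotone"
}

test_that("monotone classifier: examples, boundaries, oracle", {
    expect_identical(classifyMonotone(c(0.1, 0.4, 0.5, 0.9, 1.2)),
                     "monotone_up")
    expect_identical(classifyMonotone(rep(0.3, 5)), "non_monotone")
    expect_identical(classifyMonotone(c(1, 1, 2)), "monotone_up")
    expect_identical(classifyMonotone(c(3, 2, 2, 1)), "monotone_down")
    expect_error(classifyMonotone(1), "length")
    expect_error(classifyMonotone(c(1, NA)), "finite")
    expect_error(classifyMonotone(c(1, 2), tieTolerance = -1))
    set.seed(41)
    for (i in 1:200) {
        s <- round(rnorm(5), sample(0:2, 1))   # ties happen often
        tol <- sample(c(0, 0.1), 1)
        expect_identical(classifyMonotone(s, tol), monotoneOracle(s, tol))
    }
})

test_that("classification is invariant under increasing transforms", {
    set.seed(43)
    for (i in 1:50) {
        s <- rnorm(5)
        cls <- classifyMonotone(s)
        for (f in list(exp, atan, function(x) x^3, function(x) 5 * x + 2))
            expect_identical(classifyMonotone(f(s)), cls)
        # reversal swaps directions and fixes non_monotone
        map <- c(monotone_up = "monotone_down",
                 monotone_down = "monotone_up",
                 non_monotone = "non_monotone")
        expect_identical(classifyMonotone(rev(s)), unname(map[cls]))
    }
})

test_that("trend table classifies planted noise-free trajectories", {
    cfg <- smallSynthConfig(seed = 3L, eaNoiseSd = 0,
                            monotoneFraction = 0.3)
    ea <- generateEATimecourse(cfg)
    trends <- trendTable(ea$study)
    truth <- ea$truth$monotone
    got <- trends[trends$gene %in% truth$gene, ]
    merged <- merge(got, truth, by = "gene")
    # region genes aside, every planted trajectory is recovered exactly
    regionRows <- merged$gene %in% ea$truth$region$gene
    expect_identical(merged$class[!regionRows],
                     merged$direction[!regionRows])
    # planted step increments are strictly monotone at every step
    expect_true(all(merged$stepwise[!regionRows]))
    # unplanted expressed genes are non-monotone in the absence of noise?
    # no: flat series are non_monotone by the boundary convention
    flat <- trends[!(trends$gene %in% truth$gene) &
                   trends$class != "not_expressed", ]
    flat <- flat[!(flat$gene %in% ea$truth$region$gene), ]
    expect_true(all(flat$class == "non_monotone"))
})

test_that("step-wise flag demands at most one lax step", {
    # 4 strict steps of 4
    expect_true(regustress:::.stepwiseFlag(c(0, 1, 2, 3, 4)))
    # 3 strict of 4: still step-wise
    expect_true(regustress:::.stepwiseFlag(c(0, 1, 1, 2, 3)))
    # 2 strict of 4: monotone but not step-wise
    expect_false(regustress:::.stepwiseFlag(c(0, 1, 1, 2, 2)))
    expect_false(regustress:::.stepwiseFlag(c(0, 1, 0, 2, 3)))
})

test_that("annotation concordance counts annotated DE series", {
    trends <- data.frame(
        gene = paste0("g", 1:10), strain = "A",
        class = c(rep("monotone_up", 9), "monotone_down"),
        stepwise = TRUE, stringsAsFactors = FALSE)
    sets <- GeneSetCollection(
        list(tol = paste0("g", 1:10)),
        direction = list(tol = setNames(
            rep("overexpression_tolerant", 10), paste0("g", 1:10))))
    res <- concordanceWithAnnotation(trends, sets)
    expect_equal(res$percent, 90)
    expect_equal(res$n, 10)
    # restriction to a DEG list changes the denominator
    res2 <- concordanceWithAnnotation(trends, sets,
                                      degGenes = paste0("g", 1:5))
    expect_equal(res2$percent, 100)
    expect_warning(
        res3 <- concordanceWithAnnotation(trends, sets,
                                          degGenes = "absent"),
        "undefined")
    expect_false(res3$defined)
})

test_that("region shift test: forced shift, null, permutation oracle", {
    nG <- 20
    m <- matrix(8, nG, 2, dimnames = list(paste0("g", 1:nG),
                                          c("a1", "b1")))
    set.seed(47)
    m[, 1] <- rnorm(nG, 8, 0.5)
    m[, 2] <- m[, 1] + 1
    study <- ExpressionStudy(m, data.frame(
        condition = "evolved", strain = "C", time = c(1224, 1824),
        row.names = c("a1", "b1")))
    res <- regionShiftTest(study, paste0("g", 1:nG), 1224, 1824, "C")
    expect_lt(res$p, 0.01)
    expect_equal(res$n, nG)
    # identical values at both time points: p = 1
    m2 <- m; m2[, 2] <- m2[, 1]
    study2 <- ExpressionStudy(m2, sampleData(study))
    expect_equal(regionShiftTest(study2, paste0("g", 1:nG),
                                 1224, 1824, "C")$p, 1)
    expect_error(regionShiftTest(study, paste0("g", 1:2), 1224, 1824,
                                 "C"), "at least 3")

    # sign-flip permutation oracle on a 10-gene fixture
    set.seed(49)
    m3 <- matrix(rnorm(20, 8, 1), 10, 2,
                 dimnames = list(paste0("g", 1:10), c("a1", "b1")))
    m3[, 2] <- m3[, 1] + rnorm(10, 0.4, 0.6)
    study3 <- ExpressionStudy(m3, data.frame(
        condition = "evolved", strain = "C", time = c(1224, 1824),
        row.names = c("a1", "b1")))
    p <- regionShiftTest(study3, paste0("g", 1:10), 1224, 1824, "C")$p
    d <- m3[, 2] - m3[, 1]
    r <- rank(abs(d))
    wObs <- sum(r[d > 0])
    nPerm <- 20000
    wPerm <- replicate(nPerm, {
        flip <- sample(c(TRUE, FALSE), 10, replace = TRUE)
        dd <- ifelse(flip, -d, d)
        sum(rank(abs(dd))[dd > 0])
    })
    pPerm <- mean(wPerm >= wObs)
    expect_lt(abs(p - pPerm), 3 * sqrt(pPerm * (1 - pPerm) / nPerm) +
                              0.01)
})

test_that("pathway profiles average member series linearly", {
    mk <- function(genes, series) {
        do.call(rbind, lapply(genes, function(g) data.frame(
            gene = g, strain = "A", class = "monotone_up",
            stepwise = TRUE, lfc_h384 = series[1], lfc_h744 = series[2],
            lfc_h1224 = series[3], stringsAsFactors = FALSE)))
    }
    shared <- mk(paste0("g", 1:4), c(1, 2, 3))
    prof <- stepwisePathwayProfile(shared, paste0("g", 1:4))
    expect_equal(prof$mean_lfc, c(1, 2, 3))
    expect_equal(prof$time, c(384, 744, 1224))
    # union profile is the size-weighted mean of the part profiles
    a <- mk(paste0("a", 1:3), c(1, 1, 1))
    b <- mk(paste0("b", 1:2), c(4, 4, 4))
    both <- rbind(a, b)
    pa <- stepwisePathwayProfile(both, paste0("a", 1:3))$mean_lfc
    pb <- stepwisePathwayProfile(both, paste0("b", 1:2))$mean_lfc
    pu <- stepwisePathwayProfile(both,
                                 c(paste0("a", 1:3),
                                   paste0("b", 1:2)))$mean_lfc
    expect_equal(pu, (3 * pa + 2 * pb) / 5, tolerance = 1e-12)
    # random fixture against direct averaging
    set.seed(53)
    rnd <- mk(paste0("r", 1:6), c(0, 0, 0))
    for (j in 1:6) rnd[j, 5:7] <- rnorm(3)
    pr <- stepwisePathwayProfile(rnd, paste0("r", 1:6))
    expect_equal(pr$mean_lfc, unname(colMeans(rnd[, 5:7])),
                 tolerance = 1e-12)
    expect_warning(stepwisePathwayProfile(rnd, "zz"), "overlap")
})

test_that("region-test p-values are near-uniform under the null", {
    set.seed(59)
    nSim <- 400; nG <- 12
    ps <- replicate(nSim, {
        m <- matrix(rnorm(nG * 2, 8, 0.5), nG, 2,
                    dimnames = list(paste0("g", 1:nG), c("a1", "b1")))
        study <- ExpressionStudy(m, data.frame(
            condition = "evolved", strain = "C", time = c(1224, 1824),
            row.names = c("a1", "b1")))
        regionShiftTest(study, paste0("g", 1:nG), 1224, 1824, "C")$p
    })
    # discrete exact test: compare against uniform with KS tolerance
    ks <- suppressWarnings(ks.test(ps, "punif")$statistic)
    expect_lt(unname(ks), 0.1)
    expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
})
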