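test_that("display rounding is half away from zero", {
    expect_equal(roundHalfUp(c(76.92, 92.3, 0.5, 1.5, 2.5, -0.5, -2.5)),
                 c(77, 92, 1, 2, 3, -1, -3))
    expect_equal(roundHalfUp(3.14159, 2), 3.14)
})

test_that("set proportions count only expressed members", {
    deg <- makeDegTable(nUp = 20, nDown = 2, nNs = 4)
    sets <- GeneSetCollection(list(all26 = deg$gene))
    prof <- setDegProportions(deg, sets)
    expect_equal(prof$n_expressed, 26)
    expect_equal(prof$pct_up, 77)       # 20/26
    expect_equal(prof$prop_up, 20 / 26, tolerance = 1e-12)
    # not_expressed members never enter the denominator
    deg2 <- makeDegTable(nUp = 20, nDown = 2, nNs = 4, nNotExpr = 10)
    prof2 <- setDegProportions(deg2, GeneSetCollection(
        list(all36 = deg2$gene)))
    expect_equal(prof2$n_expressed, 26)
    expect_equal(prof2$pct_up, 77)
    # disjoint set: undefined row
    prof3 <- setDegProportions(deg, GeneSetCollection(
        list(none = c("zz1", "zz2"))))
    expect_false(prof3$defined)
    expect_true(is.na(prof3$prop_up))
})

test_that("proportions match direct counting and ignore row order", {
    set.seed(3)
    deg <- makeDegTable(nUp = 7, nDown = 5, nNs = 13, nNotExpr = 6)
    members <- sample(deg$gene, 15)
    sets <- GeneSetCollection(list(s = members))
    prof <- setDegProportions(deg, sets)
    d <- deg[deg$gene %in% members & deg$call != "not_expressed", ]
    expect_equal(prof$prop_up, sum(d$call == "up") / nrow(d))
    expect_equal(prof$prop_down, sum(d$call == "down") / nrow(d))
    shuffled <- deg[sample(nrow(deg)), ]
    expect_equal(setDegProportions(shuffled, sets)$prop_up, prof$prop_up)
    # invariant: prop_up + prop_down <= 1
    expect_lte(prof$prop_up + prof$prop_down, 1)
})

test_that("response levels by each method", {
    deg <- makeDegTable(nUp = 4, nDown = 1, nNs = 5)
    deg$fc <- 2                      # log2 FC exactly +1 for everyone
    lv <- setResponseLevel(deg, deg$gene, "mean_lfc")
    expect_equal(unname(lv["c1"]), 1.0, tolerance = 1e-12)
    lv2 <- setResponseLevel(deg, deg$gene, "prop_up_minus_down")
    expect_equal(unname(lv2["c1"]), 0.4 - 0.1, tolerance = 1e-12)
    expect_error(setResponseLevel(deg, deg$gene, "bogus"))

    # percent change: parent linear 100, treatment linear 80 -> -20
    m <- rbind(gA = log2(c(80, 100)))
    colnames(m) <- c("t1", "c1s")
    cs <- list(contrastDesign("c1", "t1", "c1s"))
    study <- makeStudy(m, c("treatment", "control"))
    deg3 <- data.frame(gene = "gA", contrast = "c1", fc = 0.8, p = NA,
                       mean_rel_diff = NA, call = "down")
    pc <- setResponseLevel(deg3, "gA", "percent_change", study, cs)
    expect_equal(unname(pc["c1"]), -20, tolerance = 1e-12)
})

test_that("correlation matches the closed-form estimator", {
    x <- c(2.5, 5, 3, 15, 15, 15, 15)
    y <- 0.3 + 0.02 * x
    expect_equal(correlateWithCovariate(y, x)$r, 1, tolerance = 1e-12)
    expect_equal(correlateWithCovariate(y, -x)$r, -1, tolerance = 1e-12)
    set.seed(8)
    for (i in 1:20) {
        a <- rnorm(7); b <- rnorm(7)
        r <- correlateWithCovariate(a, b)$r
        manual <- sum((a - mean(a)) * (b - mean(b))) /
            sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
        expect_equal(r, manual, tolerance = 1e-12)
        expect_equal(correlateProcesses(a, b)$r, r)
        rs <- correlateWithCovariate(a, b, "spearman")$r
        expect_equal(rs, cor(rank(a), rank(b)), tolerance = 1e-12)
    }
    expect_equal(correlateProcesses(x, x)$r, 1)
    expect_equal(correlateProcesses(x, -x)$r, -1)
})

test_that("correlation flags degenerate inputs instead of returning 0", {
    expect_warning(res <- correlateWithCovariate(rep(1, 5), 1:5),
                   "constant")
    expect_true(is.na(res$r))
    expect_false(res$defined)
    expect_error(correlateWithCovariate(c(1, 2), c(1, 2)), "at least 3")
    expect_error(correlateWithCovariate(c(1, 2, NA), c(1, 2, 3)),
                 "at least 3")
})

test_that("hypergeometric enrichment: closed forms and validation", {
    universe <- paste0("u", 1:20)
    degGenes <- universe[1:5]
    sets <- GeneSetCollection(list(hit = degGenes,
                                   miss = paste0("u", 10:14)))
    res <- enrichGeneSets(degGenes, universe, sets, correction = "none")
    expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5),
                 tolerance = 1e-12)
    disj <- GeneSetCollection(list(d = universe[6:10]))
    expect_equal(enrichGeneSets(degGenes[1:3], universe, disj)$p, 1)
    expect_error(enrichGeneSets(c("u1", "zz"), universe, sets), "zz")
    expect_error(enrichGeneSets("u1", character(), sets), "universe")
})

test_that("enrichment equals exhaustive enumeration on small universes", {
    enumerate <- function(universe, degGenes, set) {
        draws <- combn(length(universe), length(degGenes))
        inSet <- universe %in% set
        k <- length(intersect(degGenes, set))
        mean(apply(draws, 2, function(ix) sum(inSet[ix]) >= k))
    }
    set.seed(13)
    for (i in 1:8) {
        N <- sample(8:14, 1)
        universe <- paste0("u", seq_len(N))
        degGenes <- sample(universe, sample(2:4, 1))
        set0 <- sample(universe, sample(2:5, 1))
        p <- enrichGeneSets(degGenes, universe,
                            GeneSetCollection(list(s = set0)),
                            correction = "none")$p
        expect_equal(p, enumerate(universe, degGenes, set0),
                     tolerance = 1e-12)
    }
})

test_that("hypergeometric p is monotone in overlap and BH is sane", {
    # fixed margins, growing overlap -> non-increasing p
    universe <- paste0("u", 1:18)
    ps <- vapply(1:5, function(k) {
        degGenes <- universe[1:5]
        set0 <- c(universe[seq_len(k)], universe[6:(11 - k)])
        enrichGeneSets(degGenes, universe,
                       GeneSetCollection(list(s = set0)),
                       correction = "none")$p
    }, 0)
    expect_true(all(diff(ps) <= 1e-12))
    set.seed(2)
    sets <- lapply(1:6, function(i) sample(universe, 5))
    names(sets) <- paste0("s", 1:6)
    res <- enrichGeneSets(universe[1:4], universe,
                          GeneSetCollection(sets), correction = "BH")
    expect_true(all(res$p_adj <= 1))
    expect_true(all(res$p_adj >= res$p - 1e-12))
    # adjusted values are monotone with respect to raw p ordering
    for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res)))
        if (res$p[i] <= res$p[j])
            expect_lte(res$p_adj[i], res$p_adj[j] + 1e-12)
})
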