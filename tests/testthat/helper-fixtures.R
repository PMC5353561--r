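# Shared fixture builders; everything generated in code, nothing on disk.

# genes x samples matrix of log2 values well above the detection gate
randomMatrix <- function(nGenes = 10, nSamples = 6, seed = 1,
                         mean = 8, sd = 1) {
    set.seed(seed)
    matrix(rnorm(nGenes * nSamples, mean, sd), nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(nSamples))))
}

makeStudy <- function(values, condition = NULL, ...) {
    if (is.null(condition))
        condition <- rep(c("treatment", "control"),
                         length.out = ncol(values))
    ExpressionStudy(values, data.frame(condition = condition, ...))
}

# two-group study: first nT columns treatment, next nC control
makeContrastStudy <- function(values, nT, nC, id = "c1", ethanol = 5) {
    stopifnot(ncol(values) == nT + nC)
    study <- makeStudy(values, c(rep("treatment", nT), rep("control", nC)))
    list(study = study,
         contrast = contrastDesign(id, colnames(values)[seq_len(nT)],
                                   colnames(values)[nT + seq_len(nC)],
                                   ethanol))
}

# DEG table with prescribed counts of calls for one set of genes
makeDegTable <- function(nUp, nDown, nNs, nNotExpr = 0, contrast = "c1",
                         prefix = "g") {
    n <- nUp + nDown + nNs + nNotExpr
    calls <- c(rep("up", nUp), rep("down", nDown), rep("ns", nNs),
               rep("not_expressed", nNotExpr))
    data.frame(gene = sprintf("%s%04d", prefix, seq_len(n)),
               contrast = contrast,
               fc = ifelse(calls == "up", 2,
                    ifelse(calls == "down", 0.5,
                    ifelse(calls == "ns", 1, NA))),
               p = ifelse(calls == "not_expressed", NA, 0.01),
               mean_rel_diff = NA_real_, call = calls,
               stringsAsFactors = FALSE)
}

# Hand-written verdict table for all 18 (tf, tu, sign) combinations,
# frozen independently of the implementation.
aberrancyTruthTable <- function() {
    tab <- expand.grid(tf = c("up", "down", "ns"),
                       tu = c("up", "down", "ns"),
                       sign = c("activation", "repression"),
                       stringsAsFactors = FALSE)
    expected <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
        tf <- tab$tf[i]; tu <- tab$tu[i]; sgn <- tab$sign[i]
        expected[i] <-
            if (tf == "down") "indeterminate"
            else if (sgn == "activation") {
                if (tf == "ns" && tu == "down") "aberrant"
                else if (tf == "up" && tu != "up") "aberrant"
                else "consistent"
            } else {
                if (tf == "ns" && tu == "up") "aberrant"
                else if (tf == "up" && tu == "up") "aberrant"
                else "consistent"
            }
    }
    tab$expected <- expected
    tab
}

smallSynthConfig <- function(seed = 1L, ...) {
    synthConfig(nGenes = 200, nSets = 4, setSizeRange = c(5, 10),
                nTFs = 3, tusPerTF = 2, genesPerTU = 2,
                nToleranceGenes = 40, nRegionGenes = 10, seed = seed, ...)
}
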