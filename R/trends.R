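#' @include AllClasses.R accessors.R deg.R
NULL

#' Classify a differential-expression time series as monotone
#'
#' A series is \code{monotone_up} when every consecutive difference is at
#' least \code{-tieTolerance} and at least one difference exceeds
#' \code{tieTolerance}; \code{monotone_down} is symmetric; anything else
#' (including a constant series, which has no strict step) is
#' \code{non_monotone}.  The classification is invariant under strictly
#' increasing transforms of the series when \code{tieTolerance = 0}.
#'
#' @param series ordered numeric vector, length >= 2, finite.
#' @param tieTolerance non-negative slack for near-ties.
#' @return one of \code{"monotone_up"}, \code{"monotone_down"},
#'   \code{"non_monotone"}.
#' @export
classifyMonotone <- function(series, tieTolerance = 0) {
    if (length(series) < 2L) stop("series must have length >= 2")
    if (any(!is.finite(series))) stop("series must be finite")
    if (tieTolerance < 0) stop("tieTolerance must be >= 0")
    d <- diff(series)
    if (all(d >= -tieTolerance) && any(d > tieTolerance)) return("monotone_up")
    if (all(d <= tieTolerance) && any(d < -tieTolerance))
        return("monotone_down")
    "non_monotone"
}

.stepwiseFlag <- function(series, tieTolerance = 0) {
    cls <- classifyMonotone(series, tieTolerance)
    if (cls == "non_monotone") return(FALSE)
    d <- diff(series)
    strict <- if (cls == "monotone_up") sum(d > tieTolerance)
              else sum(d < -tieTolerance)
    strict >= length(d) - 1L
}

#' Build the trend table for an adaptive-evolution time course
#'
#' For each gene and evolved strain, computes the log2 fold change versus
#' the parent sample at every post-zero time point and classifies the
#' series as monotone up/down or non-monotone; a stricter step-wise flag
#' marks monotone series with at most one non-strict step.  Genes below
#' the expression gate are \code{not_expressed} and carry no series.
#'
#' The study's evolved samples must carry \code{strain} and \code{time}
#' annotations; the parent is the sample with \code{condition ==
#' "parent"} (or the id given).
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param config a \linkS4class{PipelineConfig}
#'   (\code{tieTolerance}, \code{detectionThreshold}).
#' @param parentSample parent sample id; default: the unique sample with
#'   condition \code{parent}.
#' @return data.frame with one row per (gene, strain): \code{gene},
#'   \code{strain}, \code{class}, \code{stepwise}, and one
#'   \code{lfc_h<time>} column per post-zero time point.
#' @export
trendTable <- function(study, config = pipelineConfig(),
                       parentSample = NULL) {
    md <- sampleData(study)
    if (is.null(parentSample)) {
        parentSample <- rownames(md)[md$condition == "parent"]
        if (length(parentSample) != 1L)
            stop("study must contain exactly one parent sample ",
                 "(or pass parentSample)")
    }
    ev <- md[md$condition == "evolved", , drop = FALSE]
    if (!nrow(ev)) stop("study contains no evolved samples")
    if (!all(c("strain", "time") %in% colnames(ev)))
        stop("evolved samples need strain and time annotations")
    times <- sort(unique(ev$time[ev$time > 0]))
    v <- exprValues(study)
    expressed <- flagExpressed(study, config)
    strains <- sort(unique(ev$strain))
    rows <- list()
    for (st in strains) {
        sampleAt <- vapply(times, function(tp) {
            id <- rownames(ev)[ev$strain == st & ev$time == tp]
            if (length(id) != 1L)
                stop("strain ", st, " needs exactly one sample at h", tp)
            id
        }, "")
        lfc <- v[, sampleAt, drop = FALSE] - v[, parentSample]
        cls <- rep("not_expressed", nrow(v))
        sw <- rep(FALSE, nrow(v))
        idx <- which(expressed)
        cls[idx] <- apply(lfc[idx, , drop = FALSE], 1L, classifyMonotone,
                          tieTolerance = config@tieTolerance)
        sw[idx] <- apply(lfc[idx, , drop = FALSE], 1L, .stepwiseFlag,
                         tieTolerance = config@tieTolerance)
        df <- data.frame(gene = rownames(v), strain = st, class = cls,
                         stepwise = sw, stringsAsFactors = FALSE,
                         row.names = NULL)
        lfcDf <- as.data.frame(lfc, row.names = NULL)
        colnames(lfcDf) <- paste0("lfc_h", times)
        lfcDf[cls == "not_expressed", ] <- NA_real_
        rows[[st]] <- cbind(df, lfcDf)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Tally monotone trends per strain and pooled
#'
#' Percentage of expressed (gene, strain) series classified monotone (up
#' or down), reported per strain and pooled across strains; both tallies
#' are given because either counting unit is defensible for a
#' whole-course monotonicity statistic.
#'
#' @param trends output of \code{\link{trendTable}}.
#' @param genes optional gene subset (e.g. differentially expressed
#'   genes) over which to tally.
#' @return list with \code{perStrain} data.frame (\code{strain},
#'   \code{n}, \code{pct_monotone}) and scalar \code{pooled}.
#' @export
monotoneTally <- function(trends, genes = NULL) {
    t0 <- trends[trends$class != "not_expressed", , drop = FALSE]
    if (!is.null(genes)) t0 <- t0[t0$gene %in% genes, , drop = FALSE]
    mono <- t0$class %in% c("monotone_up", "monotone_down")
    per <- do.call(rbind, lapply(split(mono, t0$strain), function(m)
        data.frame(n = length(m), pct_monotone = 100 * mean(m))))
    per <- data.frame(strain = rownames(per), per, row.names = NULL,
                      stringsAsFactors = FALSE)
    list(perStrain = per,
         pooled = if (nrow(t0)) 100 * mean(mono) else NA_real_)
}

#' Concordance of expression trends with tolerance annotations
#'
#' An ethanol-tolerance gene annotated \code{overexpression_tolerant} is
#' expected to trend \code{monotone_up} during adaptation, a
#' \code{knockout_tolerant} gene \code{monotone_down}.  Reports the
#' percentage of annotated, differentially expressed (gene, strain)
#' series whose trend class matches the expectation.
#'
#' @param trends output of \code{\link{trendTable}}.
#' @param sets a \linkS4class{GeneSetCollection} carrying per-gene
#'   direction annotations.
#' @param degGenes optional character vector restricting to
#'   differentially expressed genes (e.g. from \code{\link{callDegEA}}).
#' @return list: \code{percent} concordant, \code{n} series counted,
#'   \code{defined}.
#' @export
concordanceWithAnnotation <- function(trends, sets, degGenes = NULL) {
    expected <- character()
    for (nm in names(sets)) {
        d <- setDirections(sets, nm)
        d <- d[d %in% c("overexpression_tolerant", "knockout_tolerant")]
        expected[names(d)] <- ifelse(d == "overexpression_tolerant",
                                     "monotone_up", "monotone_down")
    }
    t0 <- trends[trends$gene %in% names(expected) &
                 trends$class != "not_expressed", , drop = FALSE]
    if (!is.null(degGenes)) t0 <- t0[t0$gene %in% degGenes, , drop = FALSE]
    if (!nrow(t0)) {
        warning("no annotated differentially expressed genes; ",
                "concordance undefined")
        return(list(percent = NA_real_, n = 0L, defined = FALSE))
    }
    match0 <- t0$class == expected[t0$gene]
    list(percent = 100 * mean(match0), n = nrow(t0), defined = TRUE)
}

#' One-sided shift test for a genomic region between two time points
#'
#' Tests whether the genes of a region (e.g. a duplicated segment) are
#' up-regulated between two time points of one strain, pairing each
#' expressed region gene's value at the two time points (Wilcoxon
#' signed-rank, alternative: greater at the later point).  All-zero
#' paired differences give p = 1.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param regionGenes gene ids of the region.
#' @param timeA,timeB the two time points (hours); the alternative is
#'   that expression at \code{timeB} exceeds that at \code{timeA}.
#' @param strain strain identifier.
#' @param config a \linkS4class{PipelineConfig}.
#' @return one-row data.frame: \code{strain}, \code{time_a},
#'   \code{time_b}, \code{n} (expressed region genes), \code{p}.
#' @export
regionShiftTest <- function(study, regionGenes, timeA, timeB, strain,
                            config = pipelineConfig()) {
    md <- sampleData(study)
    idA <- rownames(md)[!is.na(md$strain) & md$strain == strain &
                        !is.na(md$time) & md$time == timeA]
    idB <- rownames(md)[!is.na(md$strain) & md$strain == strain &
                        !is.na(md$time) & md$time == timeB]
    if (length(idA) != 1L || length(idB) != 1L)
        stop("strain ", strain, " needs exactly one sample at each of h",
             timeA, " and h", timeB)
    expressed <- flagExpressed(study, config)
    genes <- intersect(regionGenes, rownames(study)[expressed])
    if (length(genes) < 3L)
        stop("need at least 3 expressed region genes, got ", length(genes))
    v <- exprValues(study)
    a <- v[genes, idA]; b <- v[genes, idB]
    if (all(b - a == 0)) {
        p <- 1
    } else {
        p <- suppressWarnings(
            stats::wilcox.test(b, a, paired = TRUE,
                               alternative = "greater")$p.value)
        if (is.na(p)) p <- 1
    }
    data.frame(strain = strain, time_a = timeA, time_b = timeB,
               n = length(genes), p = p, stringsAsFactors = FALSE)
}

#' Mean differential-expression profile of a gene set over time
#'
#' Mean log2 fold change versus parent of the set's expressed members at
#' each time point, per strain — the quantity plotted in step-wise
#' pathway-decline figures.
#'
#' @param trends output of \code{\link{trendTable}}.
#' @param set character vector of gene ids.
#' @return data.frame: \code{strain}, \code{time}, \code{mean_lfc},
#'   \code{n}.  NULL with a warning when the set has no expressed
#'   overlap.
#' @export
stepwisePathwayProfile <- function(trends, set) {
    t0 <- trends[trends$gene %in% set &
                 trends$class != "not_expressed", , drop = FALSE]
    if (!nrow(t0)) {
        warning("set has no expressed overlap with the trend table")
        return(NULL)
    }
    lfcCols <- grep("^lfc_h", colnames(t0), value = TRUE)
    times <- as.numeric(sub("^lfc_h", "", lfcCols))
    rows <- lapply(split(t0, t0$strain), function(d) {
        data.frame(strain = d$strain[1L], time = times,
                   mean_lfc = colMeans(d[, lfcCols, drop = FALSE]),
                   n = nrow(d), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
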