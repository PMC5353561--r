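#' @include AllClasses.R accessors.R
NULL

#' Flag expressed genes
#'
#' A gene counts as expressed when its mean log2 level across all samples
#' of the study is at or above the detection threshold (closed lower
#' bound).  These flags feed every downstream proportion denominator:
#' genes below the gate are carried as \code{not_expressed} and excluded
#' from all rates.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return named logical vector over genes.
#' @export
flagExpressed <- function(study, config = pipelineConfig()) {
    rowMeans(exprValues(study)) >= config@detectionThreshold
}

## Rank-test p-value for one gene under the configured variant.
## Degenerate input (all values tied) yields p = 1.
.rankP <- function(x, y, rankTest) {
    if (all(c(x, y) == c(x, y)[1L])) return(1)
    p <- switch(rankTest,
        ranksum = suppressWarnings(
            stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value),
        ranksum_exact = suppressWarnings(
            stats::wilcox.test(x, y, exact = TRUE)$p.value),
        signedrank = {
            k <- min(length(x), length(y))
            suppressWarnings(
                stats::wilcox.test(x[seq_len(k)], y[seq_len(k)],
                                   paired = TRUE)$p.value)
        },
        stop("unknown rankTest: ", rankTest))
    if (is.na(p)) 1 else p
}

#' Call differentially expressed genes for a treatment-vs-control contrast
#'
#' Implements the acute-stress (NEA) rule: a gene is up-regulated when its
#' linear fold change \eqn{2^{\bar{t} - \bar{c}}} exceeds the threshold
#' (default 1.2) and the Wilcoxon rank test gives p below alpha (default
#' 0.05); down-regulation is symmetric with the reciprocal threshold.
#' All inequalities are strict.  Genes below the expression gate get the
#' call \code{not_expressed} with no fold change or p-value.
#'
#' @param study an \linkS4class{ExpressionStudy} (log2 values).
#' @param contrast a \linkS4class{ContrastDesign}.
#' @param config a \linkS4class{PipelineConfig}; \code{rankTest} selects
#'   the test variant and \code{adjust} an optional BH correction.
#' @return data.frame with columns \code{gene}, \code{contrast},
#'   \code{fc} (linear ratio), \code{p}, \code{mean_rel_diff} (NA for
#'   this rule), \code{call}.
#' @export
callDegNEA <- function(study, contrast, config = pipelineConfig()) {
    v <- exprValues(study)
    tIdx <- match(treatmentSamples(contrast), colnames(v))
    cIdx <- match(controlSamples(contrast), colnames(v))
    if (anyNA(tIdx) || anyNA(cIdx))
        stop("contrast ", contrastId(contrast),
             " names sample(s) absent from the study")
    if (!length(tIdx) || !length(cIdx))
        stop("contrast groups must be non-empty")
    expressed <- flagExpressed(study, config)
    genes <- rownames(v)
    fc <- p <- rep(NA_real_, length(genes))
    call <- rep("not_expressed", length(genes))
    idx <- which(expressed)
    if (length(idx)) {
        tm <- v[idx, tIdx, drop = FALSE]
        cm <- v[idx, cIdx, drop = FALSE]
        fc[idx] <- 2^(rowMeans(tm) - rowMeans(cm))
        p[idx] <- vapply(seq_along(idx), function(i)
            .rankP(tm[i, ], cm[i, ], config@rankTest), 0)
        if (config@adjust == "BH")
            p[idx] <- stats::p.adjust(p[idx], method = "BH")
        call[idx] <- ifelse(
            fc[idx] > config@fcThreshold & p[idx] < config@alpha, "up",
            ifelse(fc[idx] < 1 / config@fcThreshold & p[idx] < config@alpha,
                   "down", "ns"))
    }
    data.frame(gene = genes, contrast = contrastId(contrast), fc = fc,
               p = p, mean_rel_diff = NA_real_, call = call,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes for an evolved-vs-parent design
#'
#' Implements the adaptation (EA) rule: with linear-scale differences
#' \eqn{d_i = 2^{e_i} - 2^{p}} between each evolved sample and the single
#' parent sample, a gene is up-regulated when every \eqn{d_i > 0} and the
#' mean difference exceeds the configured fraction (default 20 percent)
#' of the parent's linear level; down-regulation is symmetric.  The rule
#' is unanimity-based: one discordant strain abolishes the call.  With
#' \code{eaScale = "log2"} the differences are taken on the log2 scale
#' and the relative difference is \eqn{2^{\bar d} - 1}.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param parentSample single parent/control sample id.
#' @param evolvedSamples two or more evolved sample ids.
#' @param config a \linkS4class{PipelineConfig}.
#' @param contrast label stored in the \code{contrast} column.
#' @return data.frame as for \code{\link{callDegNEA}}; \code{fc} is the
#'   ratio of the mean evolved linear level to the parent level, \code{p}
#'   is NA (no test in this rule), and \code{mean_rel_diff} is the signed
#'   mean relative difference.
#' @export
callDegEA <- function(study, parentSample, evolvedSamples,
                      config = pipelineConfig(), contrast = "EA") {
    v <- exprValues(study)
    if (!(parentSample %in% colnames(v)))
        stop("parent sample not in study: ", parentSample)
    missing <- setdiff(evolvedSamples, colnames(v))
    if (length(missing))
        stop("evolved sample(s) not in study: ",
             paste(missing, collapse = ", "))
    if (length(evolvedSamples) < 2L)
        stop("need at least 2 evolved samples")
    expressed <- flagExpressed(study, config)
    genes <- rownames(v)
    fc <- mrd <- rep(NA_real_, length(genes))
    call <- rep("not_expressed", length(genes))
    idx <- which(expressed)
    if (length(idx)) {
        pv <- v[idx, parentSample]
        ev <- v[idx, evolvedSamples, drop = FALSE]
        if (config@eaScale == "linear") {
            d <- 2^ev - 2^pv
            rel <- rowMeans(d) / 2^pv
        } else {
            d <- ev - pv
            rel <- 2^rowMeans(d) - 1
        }
        allUp <- rowSums(d > 0) == ncol(d)
        allDown <- rowSums(d < 0) == ncol(d)
        mrd[idx] <- rel
        fc[idx] <- rel + 1
        call[idx] <- ifelse(allUp & rel > config@eaMinRelDiff, "up",
                     ifelse(allDown & -rel > config@eaMinRelDiff, "down",
                            "ns"))
    }
    data.frame(gene = genes, contrast = contrast, fc = fc, p = NA_real_,
               mean_rel_diff = mrd, call = call,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Call DEGs for a list of contrasts
#'
#' Convenience wrapper applying \code{\link{callDegNEA}} to each contrast
#' and binding the per-contrast tables.
#'
#' @inheritParams callDegNEA
#' @param contrasts list of \linkS4class{ContrastDesign}.
#' @return a combined DEG data.frame.
#' @export
callDegAll <- function(study, contrasts, config = pipelineConfig()) {
    do.call(rbind, lapply(contrasts, callDegNEA, study = study,
                          config = config))
}
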