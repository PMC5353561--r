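#' @include AllClasses.R
NULL

#' Accessors for ExpressionStudy
#'
#' \code{exprValues} returns the log2 expression matrix; \code{sampleData}
#' the per-sample annotations as a data.frame; \code{geneIds} and
#' \code{sampleIds} the identifier vectors.
#'
#' @param x an \linkS4class{ExpressionStudy}.
#' @return matrix, data.frame or character vector as described.
#' @export
exprValues <- function(x) assay(x, "log2expr")

#' @rdname exprValues
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @rdname exprValues
#' @export
geneIds <- function(x) rownames(x)

#' @rdname exprValues
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "ExpressionStudy", function(object) {
    cd <- colData(object)
    cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  conditions:",
        paste(sprintf("%s(%d)", names(table(cd$condition)),
                      as.integer(table(cd$condition))), collapse = " "), "\n")
    if ("ethanol" %in% colnames(cd) && any(!is.na(cd$ethanol)))
        cat("  ethanol % v/v:",
            paste(sort(unique(stats::na.omit(cd$ethanol))), collapse = ", "), "\n")
    if ("time" %in% colnames(cd) && any(!is.na(cd$time)))
        cat("  time points (h):",
            paste(sort(unique(stats::na.omit(cd$time))), collapse = ", "), "\n")
})

#' Accessors for GeneSetCollection
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param name set name.
#' @return \code{geneSets}: the named list of sets; \code{setCategory}:
#'   named character of category tags; \code{setDirections}: per-gene
#'   direction annotations for one set (named character, possibly empty).
#' @export
geneSets <- function(x) x@sets

#' @rdname geneSets
#' @export
setCategory <- function(x) x@category

#' @rdname geneSets
#' @export
setDirections <- function(x, name) {
    d <- x@direction[[name]]
    if (is.null(d)) setNames(character(0), character(0)) else d
}

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "sets\n")
    sz <- lengths(object@sets)
    if (length(sz))
        cat("  set sizes:", min(sz), "-", max(sz), "genes\n")
    tb <- table(object@category, useNA = "no")
    if (length(tb))
        cat("  categories:", paste(sprintf("%s(%d)", names(tb),
                                           as.integer(tb)), collapse = " "), "\n")
})

#' Accessors for RegulatoryNetwork
#'
#' @param x a \linkS4class{RegulatoryNetwork}.
#' @param tu a TU identifier.
#' @param tf optionally restrict to one TF.
#' @return \code{tfEdges}: the signed edge table; \code{tuMembers}: gene
#'   ids of one TU; \code{networkTFs}: TF ids (optionally EBP-only);
#'   \code{soleRegulatorTUs}: TUs whose single incoming edge is from
#'   \code{tf} (or, with \code{tf = NULL}, all TUs with exactly one
#'   regulator).
#' @export
tfEdges <- function(x) x@edges

#' @rdname tfEdges
#' @export
tuMembers <- function(x, tu) x@members$gene[x@members$tu == tu]

#' @rdname tfEdges
#' @param ebpOnly if TRUE, only TFs flagged as ethanol-binding proteins.
#' @export
networkTFs <- function(x, ebpOnly = FALSE) {
    tfs <- unique(x@edges$tf)
    if (ebpOnly) tfs <- tfs[x@isEBP[tfs]]
    tfs
}

#' @rdname tfEdges
#' @export
soleRegulatorTUs <- function(x, tf = NULL) {
    regPerTU <- tapply(x@edges$tf, x@edges$tu,
                       function(v) unique(v), simplify = FALSE)
    sole <- names(regPerTU)[lengths(regPerTU) == 1L]
    if (is.null(tf)) return(sole)
    sole[vapply(regPerTU[sole], function(v) v == tf, logical(1))]
}

setMethod("show", "RegulatoryNetwork", function(object) {
    cat("RegulatoryNetwork:", length(unique(object@edges$tf)), "TFs,",
        length(unique(object@edges$tu)), "TUs,",
        nrow(object@members), "memberships\n")
    cat("  sole-regulator TUs:", length(soleRegulatorTUs(object)), "\n")
    cat("  EBP TFs:", sum(object@isEBP), "\n")
})

setMethod("show", "ContrastDesign", function(object) {
    cat("ContrastDesign", object@id, ": ",
        length(object@treatment), "treatment vs",
        length(object@control), "control samples",
        if (!is.na(object@ethanol))
            sprintf("(%g%% ethanol)", object@ethanol) else "", "\n")
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig: FC >", object@fcThreshold,
        "| alpha", object@alpha,
        "| EA rel diff >", object@eaMinRelDiff,
        "| detection >=", object@detectionThreshold, "\n")
    cat("  rankTest:", object@rankTest, "| eaScale:", object@eaScale,
        "| tuRule:", object@tuRule,
        "| correlation:", object@correlationMethod, "\n")
})

#' Contrast accessors
#'
#' @param x a \linkS4class{ContrastDesign}.
#' @return identifier, sample groups or ethanol concentration.
#' @export
contrastId <- function(x) x@id

#' @rdname contrastId
#' @export
treatmentSamples <- function(x) x@treatment

#' @rdname contrastId
#' @export
controlSamples <- function(x) x@control

#' @rdname contrastId
#' @export
contrastEthanol <- function(x) x@ethanol
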