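#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.CONDITIONS <- c("treatment", "control", "parent", "evolved")
.CALLS <- c("up", "down", "ns", "not_expressed")
.SIGNS <- c("activation", "repression")
.DIRECTIONS <- c("overexpression_tolerant", "knockout_tolerant", "none")

#' ExpressionStudy: a log2 expression matrix with sample annotations
#'
#' An \code{ExpressionStudy} holds a genes-by-samples matrix of normalized
#' log2 expression values together with per-sample annotations, as a thin
#' extension of \linkS4class{SummarizedExperiment}.  Required sample
#' annotation: \code{condition} (one of \code{treatment}, \code{control},
#' \code{parent}, \code{evolved}).  Optional: \code{replicate} (integer
#' >= 1), \code{strain}, \code{time} (hours, >= 0) and \code{ethanol}
#' (percent v/v, >= 0); absent values are \code{NA}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; the single assay is
#'   named \code{"log2expr"}.
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

.validExpressionStudy <- function(object) {
    msg <- character()
    if (!("log2expr" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'log2expr' is required")
    g <- rownames(object); s <- colnames(object)
    if (is.null(g) || anyNA(g) || !all(nzchar(g)))
        msg <- c(msg, "gene identifiers must be non-empty strings")
    if (anyDuplicated(g))
        msg <- c(msg, sprintf("duplicated gene identifier(s): %s",
                              paste(unique(g[duplicated(g)]), collapse = ", ")))
    if (is.null(s) || anyDuplicated(s))
        msg <- c(msg, sprintf("duplicated sample identifier(s): %s",
                              paste(unique(s[duplicated(s)]), collapse = ", ")))
    cd <- colData(object)
    if (!("condition" %in% colnames(cd))) {
        msg <- c(msg, "sample metadata must contain a 'condition' column")
    } else {
        bad <- !(cd$condition %in% .CONDITIONS)
        if (any(bad))
            msg <- c(msg, sprintf("invalid condition label for sample(s): %s",
                                  paste(s[bad], collapse = ", ")))
    }
    if ("replicate" %in% colnames(cd)) {
        r <- cd$replicate
        if (any(!is.na(r) & (r < 1 | r != round(r))))
            msg <- c(msg, "replicate indices must be integers >= 1")
    }
    if ("ethanol" %in% colnames(cd)) {
        e <- cd$ethanol
        if (any(!is.na(e) & e < 0))
            msg <- c(msg, "ethanol concentrations must be >= 0")
    }
    if ("time" %in% colnames(cd)) {
        tm <- cd$time
        if (any(!is.na(tm) & tm < 0))
            msg <- c(msg, "time points must be >= 0 hours")
    }
    if (anyNA(assay(object, "log2expr")))
        msg <- c(msg, "missing values are not permitted in the expression matrix")
    if (length(msg)) msg else TRUE
}
setValidity("ExpressionStudy", .validExpressionStudy)

#' Construct an ExpressionStudy
#'
#' @param values numeric matrix of log2 expression values, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param sampleData data.frame of per-sample annotations, one row per
#'   sample in column order of \code{values} (or with rownames matching
#'   the sample ids).  Must contain \code{condition}.
#' @return a validated \linkS4class{ExpressionStudy}.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' es <- ExpressionStudy(m, data.frame(
#'     condition = c("treatment", "treatment", "control", "control")))
#' @export
ExpressionStudy <- function(values, sampleData) {
    values <- as.matrix(values)
    if (!is.null(rownames(sampleData)) &&
        !all(rownames(sampleData) == as.character(seq_len(nrow(sampleData))))) {
        missing <- setdiff(rownames(sampleData), colnames(values))
        if (length(missing))
            stop("metadata sample(s) missing from matrix: ",
                 paste(missing, collapse = ", "))
        sampleData <- sampleData[colnames(values), , drop = FALSE]
    }
    if (nrow(sampleData) != ncol(values))
        stop("metadata has ", nrow(sampleData), " rows but matrix has ",
             ncol(values), " samples")
    se <- SummarizedExperiment(
        assays = list(log2expr = values),
        colData = DataFrame(sampleData, row.names = colnames(values)))
    new("ExpressionStudy", se)
}

#' ContrastDesign: a treatment-versus-control comparison
#'
#' Identifies the two disjoint sample groups of one contrast, with the
#' ethanol concentration (percent v/v) of the treatment when known.
#'
#' @slot id character contrast identifier.
#' @slot treatment,control character vectors of sample identifiers.
#' @slot ethanol numeric(1), percent v/v or NA.
#' @export
setClass("ContrastDesign",
    representation(id = "character", treatment = "character",
                   control = "character", ethanol = "numeric"))

setValidity("ContrastDesign", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "contrast id must be a single non-empty string")
    if (length(object@treatment) < 1L || length(object@control) < 1L)
        msg <- c(msg, "both sample groups must be non-empty")
    overlap <- intersect(object@treatment, object@control)
    if (length(overlap))
        msg <- c(msg, sprintf("groups are not disjoint (shared: %s)",
                              paste(overlap, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @rdname ContrastDesign-class
#' @param id contrast identifier.
#' @param treatment,control sample identifier vectors.
#' @param ethanol ethanol concentration of the treatment, percent v/v.
#' @export
contrastDesign <- function(id, treatment, control, ethanol = NA_real_) {
    new("ContrastDesign", id = as.character(id),
        treatment = as.character(treatment),
        control = as.character(control),
        ethanol = as.numeric(ethanol))
}

#' GeneSetCollection: named gene sets with category and direction tags
#'
#' Sets may overlap; within a set genes are unique.  Each set can carry a
#' category tag (\code{regulon}, \code{stress_response}, \code{pathway},
#' \code{tolerance}, \code{EBP}) and per-gene direction annotations used
#' for tolerance-concordance analysis (\code{overexpression_tolerant},
#' \code{knockout_tolerant}, \code{none}).
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot category named character vector (one per set, possibly NA).
#' @slot direction named list; per set a named character vector of
#'   per-gene direction annotations.
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", category = "character", direction = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (length(object@sets) && (is.null(nm) || any(!nzchar(nm))))
        msg <- c(msg, "all sets must be named")
    if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicated set name(s): %s",
                              paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    dup <- vapply(object@sets, anyDuplicated, 0L)
    if (any(dup > 0))
        msg <- c(msg, sprintf("duplicated gene(s) within set(s): %s",
                              paste(nm[dup > 0], collapse = ", ")))
    for (s in names(object@direction)) {
        d <- object@direction[[s]]
        if (!all(d %in% .DIRECTIONS))
            msg <- c(msg, sprintf("invalid direction annotation in set %s", s))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors.
#' @param category optional named character vector of category tags.
#' @param direction optional named list of per-gene direction annotations.
#' @export
GeneSetCollection <- function(sets, category = NULL, direction = NULL) {
    if (is.null(category))
        category <- setNames(rep(NA_character_, length(sets)), names(sets))
    category <- category[names(sets)]
    names(category) <- names(sets)
    if (is.null(direction)) direction <- list()
    new("GeneSetCollection", sets = sets, category = category,
        direction = direction)
}

#' RegulatoryNetwork: signed TF-to-TU edges plus TU memberships
#'
#' Encodes the regulatory structure used for aberrancy scoring: which
#' transcription factor regulates which transcription unit and with what
#' sign, which genes each TU contains, and which TFs are annotated as
#' ethanol-binding proteins (EBPs).  TF identifiers are the TF's own gene
#' identifiers, so a TF's differential-expression call can be looked up
#' directly in a DEG table.
#'
#' @slot edges data.frame with columns \code{tf}, \code{tu}, \code{sign}.
#' @slot members data.frame with columns \code{tu}, \code{gene}.
#' @slot isEBP named logical vector over TFs.
#' @export
setClass("RegulatoryNetwork",
    representation(edges = "data.frame", members = "data.frame",
                   isEBP = "logical"))

setValidity("RegulatoryNetwork", function(object) {
    msg <- character()
    e <- object@edges; m <- object@members
    if (!all(c("tf", "tu", "sign") %in% colnames(e)))
        msg <- c(msg, "edges must have columns tf, tu, sign")
    if (!all(c("tu", "gene") %in% colnames(m)))
        msg <- c(msg, "members must have columns tu, gene")
    if (length(msg)) return(msg)
    if (any(!nzchar(e$tf)) || any(!nzchar(e$tu)))
        msg <- c(msg, "edge TF and TU identifiers must be non-empty")
    if (!all(e$sign %in% .SIGNS))
        msg <- c(msg, sprintf("unknown sign token(s): %s",
                 paste(unique(e$sign[!(e$sign %in% .SIGNS)]), collapse = ", ")))
    key <- paste(e$tf, e$tu)
    if (anyDuplicated(key))
        msg <- c(msg, sprintf("duplicate edge(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
    orphan <- setdiff(e$tu, m$tu)
    if (length(orphan))
        msg <- c(msg, sprintf("TU(s) with no member genes: %s",
                              paste(orphan, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @rdname RegulatoryNetwork-class
#' @param edges data.frame (tf, tu, sign).
#' @param members data.frame (tu, gene).
#' @param isEBP named logical over TFs; TFs not named default to FALSE.
#' @export
RegulatoryNetwork <- function(edges, members, isEBP = NULL) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    members <- as.data.frame(members, stringsAsFactors = FALSE)
    tfs <- unique(edges$tf)
    flags <- setNames(rep(FALSE, length(tfs)), tfs)
    if (!is.null(isEBP)) flags[intersect(names(isEBP), tfs)] <-
        as.logical(isEBP[intersect(names(isEBP), tfs)])
    new("RegulatoryNetwork", edges = edges, members = members, isEBP = flags)
}

#' PipelineConfig: thresholds and method switches for the whole pipeline
#'
#' Houses every tunable the analysis rules use.  Defaults reproduce the
#' published procedure: fold-change gate 1.2, alpha 0.05, evolved-strain
#' mean relative difference 20 percent, and strict inequalities at all
#' thresholds.
#'
#' @slot fcThreshold linear fold-change gate (> 1).
#' @slot alpha rank-test significance level, in (0, 1).
#' @slot eaMinRelDiff minimum mean relative difference for the
#'   evolved-versus-parent rule (linear scale fraction, > 0).
#' @slot detectionThreshold log2 expression level at or above which a
#'   gene counts as expressed (mean over all samples; closed lower bound).
#' @slot rankTest one of \code{"ranksum"} (normal approximation, no
#'   continuity correction), \code{"ranksum_exact"}, \code{"signedrank"}.
#' @slot eaScale \code{"linear"} or \code{"log2"}: scale on which the
#'   evolved-versus-parent differences are taken.
#' @slot correlationMethod \code{"pearson"} or \code{"spearman"}.
#' @slot tuRule TU summarization rule: \code{"majority"}, \code{"any"},
#'   or \code{"all"}.
#' @slot tieTolerance non-negative slack when comparing consecutive
#'   time-course differences in the monotone classifier.
#' @slot adjust multiple-testing adjustment for DEG calls:
#'   \code{"none"} (the published procedure) or \code{"BH"}.
#' @slot seed integer random seed for derived streams.
#' @export
setClass("PipelineConfig",
    representation(fcThreshold = "numeric", alpha = "numeric",
                   eaMinRelDiff = "numeric", detectionThreshold = "numeric",
                   rankTest = "character", eaScale = "character",
                   correlationMethod = "character", tuRule = "character",
                   tieTolerance = "numeric", adjust = "character",
                   seed = "integer"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (object@fcThreshold <= 1) msg <- c(msg, "fcThreshold must be > 1")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must be in (0, 1)")
    if (object@eaMinRelDiff <= 0) msg <- c(msg, "eaMinRelDiff must be > 0")
    if (object@tieTolerance < 0) msg <- c(msg, "tieTolerance must be >= 0")
    if (!object@rankTest %in% c("ranksum", "ranksum_exact", "signedrank"))
        msg <- c(msg, "unknown rankTest")
    if (!object@eaScale %in% c("linear", "log2"))
        msg <- c(msg, "unknown eaScale")
    if (!object@correlationMethod %in% c("pearson", "spearman"))
        msg <- c(msg, "unknown correlationMethod")
    if (!object@tuRule %in% c("majority", "any", "all"))
        msg <- c(msg, "unknown tuRule")
    if (!object@adjust %in% c("none", "BH"))
        msg <- c(msg, "unknown adjust")
    if (length(msg)) msg else TRUE
})

#' @rdname PipelineConfig-class
#' @param fcThreshold,alpha,eaMinRelDiff,detectionThreshold,rankTest,eaScale
#'   see slots.
#' @param correlationMethod,tuRule,tieTolerance,adjust,seed see slots.
#' @export
pipelineConfig <- function(fcThreshold = 1.2, alpha = 0.05,
                           eaMinRelDiff = 0.20, detectionThreshold = 4,
                           rankTest = "ranksum", eaScale = "linear",
                           correlationMethod = "pearson",
                           tuRule = "majority", tieTolerance = 0,
                           adjust = "none", seed = 1L) {
    new("PipelineConfig", fcThreshold = fcThreshold, alpha = alpha,
        eaMinRelDiff = eaMinRelDiff, detectionThreshold = detectionThreshold,
        rankTest = rankTest, eaScale = eaScale,
        correlationMethod = correlationMethod, tuRule = tuRule,
        tieTolerance = tieTolerance, adjust = adjust,
        seed = as.integer(seed))
}
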