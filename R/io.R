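#' @include AllClasses.R
NULL

.readTSV <- function(path, ...) {
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE, ...)
}

.writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
}

#' Read and write expression studies
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column of gene ids; the metadata file is a TSV keyed by a
#' \code{sample} column.  Row and column order are preserved.  Values are
#' written with 15 significant digits so write/read round trips are
#' lossless well past 12 digits.
#'
#' @param matrixPath,metadataPath paths to the two TSV files.
#' @return \code{readExpressionStudy}: a validated
#'   \linkS4class{ExpressionStudy}.
#' @export
readExpressionStudy <- function(matrixPath, metadataPath) {
    m <- .readTSV(matrixPath)
    if (ncol(m) < 2L) stop("matrix file has no sample columns: ", matrixPath)
    genes <- as.character(m[[1L]])
    if (anyDuplicated(genes))
        stop("duplicated gene id(s) in ", matrixPath, ": ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    values <- as.matrix(m[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- genes
    md <- .readTSV(metadataPath)
    if (!("sample" %in% colnames(md)))
        stop("metadata file must have a 'sample' column: ", metadataPath)
    if (anyDuplicated(md$sample))
        stop("duplicated sample id(s) in metadata: ",
             paste(unique(md$sample[duplicated(md$sample)]), collapse = ", "))
    missing <- setdiff(md$sample, colnames(values))
    if (length(missing))
        stop("metadata sample(s) missing from matrix: ",
             paste(missing, collapse = ", "))
    missing2 <- setdiff(colnames(values), md$sample)
    if (length(missing2))
        stop("matrix sample(s) missing from metadata: ",
             paste(missing2, collapse = ", "))
    rownames(md) <- md$sample
    md <- md[colnames(values), setdiff(colnames(md), "sample"), drop = FALSE]
    ExpressionStudy(values, md)
}

#' @rdname readExpressionStudy
#' @param study an \linkS4class{ExpressionStudy}.
#' @export
writeExpressionStudy <- function(study, matrixPath, metadataPath) {
    v <- exprValues(study)
    df <- data.frame(gene = rownames(v),
                     signif(v, 15), check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTSV(df, matrixPath)
    md <- sampleData(study)
    md <- data.frame(sample = rownames(md), md, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .writeTSV(md, metadataPath)
    invisible(c(matrixPath, metadataPath))
}

#' Read and write contrast designs
#'
#' One row per contrast: \code{contrast}, comma-separated
#' \code{treatment} and \code{control} sample ids, and \code{ethanol}.
#'
#' @param path TSV path.
#' @return list of \linkS4class{ContrastDesign}.
#' @export
readContrasts <- function(path) {
    df <- .readTSV(path)
    lapply(seq_len(nrow(df)), function(i) contrastDesign(
        df$contrast[i],
        strsplit(df$treatment[i], ",", fixed = TRUE)[[1L]],
        strsplit(df$control[i], ",", fixed = TRUE)[[1L]],
        if ("ethanol" %in% colnames(df)) df$ethanol[i] else NA_real_))
}

#' @rdname readContrasts
#' @param contrasts list of \linkS4class{ContrastDesign}.
#' @export
writeContrasts <- function(contrasts, path) {
    df <- data.frame(
        contrast = vapply(contrasts, contrastId, ""),
        treatment = vapply(contrasts, function(x)
            paste(treatmentSamples(x), collapse = ","), ""),
        control = vapply(contrasts, function(x)
            paste(controlSamples(x), collapse = ","), ""),
        ethanol = vapply(contrasts, contrastEthanol, 0),
        stringsAsFactors = FALSE)
    .writeTSV(df, path)
    invisible(path)
}

#' Read and write gene-set collections (GMT dialect)
#'
#' Each GMT line is: set name, category tag (in the description field),
#' then tab-separated gene ids.  Per-gene direction annotations live in
#' an optional side table (TSV with columns \code{set}, \code{gene},
#' \code{direction}).  Empty sets are retained with a warning.
#'
#' @param path GMT file path.
#' @param directionPath optional direction side-table path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path, directionPath = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list(); category <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 2L)
            stop("malformed GMT line ", i, " in ", path,
                 " (need at least name and description)")
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (!length(genes))
            warning("empty gene set '", f[1L], "' at line ", i, " (retained)")
        sets[[f[1L]]] <- genes
        category[f[1L]] <- if (nzchar(f[2L]) && f[2L] != "na")
            f[2L] else NA_character_
    }
    direction <- NULL
    if (!is.null(directionPath)) {
        dd <- .readTSV(directionPath)
        direction <- lapply(split(dd, dd$set), function(d)
            setNames(d$direction, d$gene))
    }
    GeneSetCollection(sets, category, direction)
}

#' @rdname readGeneSets
#' @param collection a \linkS4class{GeneSetCollection}.
#' @export
writeGeneSets <- function(collection, path, directionPath = NULL) {
    cat0 <- setCategory(collection)
    lines <- vapply(names(collection), function(nm) {
        paste(c(nm, ifelse(is.na(cat0[nm]), "na", cat0[nm]),
                geneSets(collection)[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    if (!is.null(directionPath)) {
        rows <- do.call(rbind, lapply(names(collection), function(nm) {
            d <- setDirections(collection, nm)
            if (!length(d)) return(NULL)
            data.frame(set = nm, gene = names(d), direction = unname(d),
                       stringsAsFactors = FALSE)
        }))
        if (is.null(rows))
            rows <- data.frame(set = character(), gene = character(),
                               direction = character())
        .writeTSV(rows, directionPath)
    }
    invisible(path)
}

#' Read and write regulatory networks
#'
#' Two-section tab-delimited file.  Lines \code{edge<TAB>tf<TAB>tu<TAB>
#' sign[<TAB>ebp]} define signed TF-to-TU regulation (the optional fifth
#' field marks ethanol-binding-protein TFs); lines
#' \code{member<TAB>tu<TAB>gene} assign genes to TUs.
#'
#' @param path network file path.
#' @return a validated \linkS4class{RegulatoryNetwork}.
#' @export
readNetwork <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    kind <- vapply(parts, `[[`, "", 1L)
    bad <- which(!(kind %in% c("edge", "member")))
    if (length(bad))
        stop("malformed network line ", bad[1L], " in ", path)
    ep <- parts[kind == "edge"]; mp <- parts[kind == "member"]
    edges <- data.frame(
        tf = vapply(ep, `[[`, "", 2L),
        tu = vapply(ep, `[[`, "", 3L),
        sign = vapply(ep, `[[`, "", 4L),
        stringsAsFactors = FALSE)
    ebp <- vapply(ep, function(p) length(p) >= 5L && p[[5L]] == "ebp",
                  logical(1))
    isEBP <- tapply(ebp, edges$tf, any)
    members <- data.frame(
        tu = vapply(mp, `[[`, "", 2L),
        gene = vapply(mp, `[[`, "", 3L),
        stringsAsFactors = FALSE)
    RegulatoryNetwork(edges, members, isEBP = setNames(as.logical(isEBP),
                                                       names(isEBP)))
}

#' @rdname readNetwork
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @export
writeNetwork <- function(network, path) {
    e <- tfEdges(network)
    eLines <- paste("edge", e$tf, e$tu, e$sign,
                    ifelse(network@isEBP[e$tf], "ebp", "."), sep = "\t")
    m <- network@members
    mLines <- paste("member", m$tu, m$gene, sep = "\t")
    writeLines(c(eLines, mLines), path)
    invisible(path)
}

#' Read a pipeline configuration from a YAML key/value file
#'
#' Unknown keys are rejected; omitted keys fall back to the defaults of
#' \code{\link{pipelineConfig}}.
#'
#' @param path YAML file path.
#' @return a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
        stop("invalid config key(s): ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, vals)
}
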