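#' @include AllClasses.R accessors.R
NULL

#' Round half away from zero
#'
#' Display rounding used for every reported percentage: halves round away
#' from zero (76.92 -> 77, 92.3 -> 92, -20.5 -> -21), unlike base
#' \code{round}'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

#' DEG proportions per gene set and contrast
#'
#' For every set and every contrast present in the DEG table, counts the
#' set members with an up or down call among the expressed members and
#' reports the proportions.  Genes called \code{not_expressed} (and set
#' members absent from the DEG table) never enter a denominator.  Sets
#' with no expressed member in a contrast are flagged undefined and are
#' excluded from downstream correlations.
#'
#' @param deg DEG data.frame (from \code{\link{callDegNEA}} /
#'   \code{\link{callDegEA}} or row-bound tables).
#' @param sets a \linkS4class{GeneSetCollection}.
#' @return data.frame with one row per (set, contrast): counts
#'   \code{n_expressed}, \code{n_up}, \code{n_down}; fractions
#'   \code{prop_up}, \code{prop_down}; display percentages \code{pct_up},
#'   \code{pct_down} (integers, half away from zero); logical
#'   \code{defined}.
#' @export
setDegProportions <- function(deg, sets) {
    contrasts <- unique(deg$contrast)
    rows <- list()
    for (nm in names(sets)) {
        members <- geneSets(sets)[[nm]]
        for (ct in contrasts) {
            d <- deg[deg$contrast == ct & deg$gene %in% members, , drop = FALSE]
            d <- d[d$call != "not_expressed", , drop = FALSE]
            nExpr <- nrow(d)
            nUp <- sum(d$call == "up"); nDown <- sum(d$call == "down")
            defined <- nExpr > 0L
            rows[[length(rows) + 1L]] <- data.frame(
                set = nm, contrast = ct, n_expressed = nExpr,
                n_up = nUp, n_down = nDown,
                prop_up = if (defined) nUp / nExpr else NA_real_,
                prop_down = if (defined) nDown / nExpr else NA_real_,
                pct_up = if (defined) roundHalfUp(100 * nUp / nExpr)
                         else NA_real_,
                pct_down = if (defined) roundHalfUp(100 * nDown / nExpr)
                           else NA_real_,
                defined = defined, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Per-contrast response level of a gene set
#'
#' Summarizes a set's expression change in each contrast by one scalar:
#' \describe{
#'   \item{mean_lfc}{mean log2 fold change over expressed set members.}
#'   \item{prop_up_minus_down}{difference of DEG proportions, in
#'     [-1, 1].}
#'   \item{mean_expression}{mean log2 level of expressed set members in
#'     the treatment group (needs \code{study} and \code{contrasts}).}
#'   \item{percent_change}{percent change of the set's mean linear-scale
#'     level, treatment versus control (needs \code{study} and
#'     \code{contrasts}); a parent level of 100 and an evolved level of
#'     80 gives -20.}
#' }
#'
#' @param deg DEG data.frame.
#' @param set character vector of gene ids.
#' @param method one of the methods above.
#' @param study,contrasts required for the expression-based methods:
#'   the study and the list of \linkS4class{ContrastDesign} whose ids
#'   appear in \code{deg}.
#' @return named numeric vector, one value per contrast (NA where
#'   undefined).
#' @export
setResponseLevel <- function(deg, set,
                             method = c("mean_lfc", "prop_up_minus_down",
                                        "mean_expression", "percent_change"),
                             study = NULL, contrasts = NULL) {
    method <- match.arg(method)
    cts <- unique(deg$contrast)
    if (method %in% c("mean_expression", "percent_change")) {
        if (is.null(study) || is.null(contrasts))
            stop("method '", method, "' needs study and contrasts")
        byId <- setNames(contrasts, vapply(contrasts, contrastId, ""))
    }
    out <- setNames(rep(NA_real_, length(cts)), cts)
    for (ct in cts) {
        d <- deg[deg$contrast == ct & deg$gene %in% set &
                 deg$call != "not_expressed", , drop = FALSE]
        if (!nrow(d)) next
        out[ct] <- switch(method,
            mean_lfc = mean(log2(d$fc)),
            prop_up_minus_down = (sum(d$call == "up") -
                                  sum(d$call == "down")) / nrow(d),
            mean_expression = {
                v <- exprValues(study)
                mean(v[d$gene, treatmentSamples(byId[[ct]]), drop = FALSE])
            },
            percent_change = {
                v <- 2^exprValues(study)
                tMean <- mean(v[d$gene, treatmentSamples(byId[[ct]]),
                                drop = FALSE])
                cMean <- mean(v[d$gene, controlSamples(byId[[ct]]),
                                drop = FALSE])
                100 * (tMean - cMean) / cMean
            })
    }
    out
}

#' Correlate per-contrast response levels with a covariate
#'
#' Pearson (default) or Spearman correlation between a set's response
#' levels and a per-contrast covariate such as the ethanol concentration.
#' Needs at least 3 complete pairs; a constant vector yields an NA
#' coefficient with a warning (flagged, never silently zero).
#'
#' @param levels,covariate paired numeric vectors.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return one-row data.frame: \code{method}, \code{n} (pairs used),
#'   \code{r}, \code{defined}.
#' @export
correlateWithCovariate <- function(levels, covariate,
                                   method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (length(levels) != length(covariate))
        stop("levels and covariate must have equal length")
    ok <- is.finite(levels) & is.finite(covariate)
    n <- sum(ok)
    if (n < 3L) stop("need at least 3 complete pairs, got ", n)
    x <- levels[ok]; y <- covariate[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant input vector: correlation undefined")
        return(data.frame(method = method, n = n, r = NA_real_,
                          defined = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(method = method, n = n,
               r = stats::cor(x, y, method = method), defined = TRUE,
               stringsAsFactors = FALSE)
}

#' Correlate two process response profiles
#'
#' Same contract as \code{\link{correlateWithCovariate}}, for comparing
#' two gene sets' per-contrast response profiles (e.g. whether decreased
#' biosynthesis tracks decreased DNA replication).
#'
#' @param profileA,profileB paired numeric vectors.
#' @inheritParams correlateWithCovariate
#' @return one-row data.frame as for \code{\link{correlateWithCovariate}}.
#' @export
correlateProcesses <- function(profileA, profileB,
                               method = c("pearson", "spearman")) {
    correlateWithCovariate(profileA, profileB, method)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail probability of observing at least the
#' realized overlap between a DEG list and each set, against a universe
#' of expressed genes, with optional Benjamini-Hochberg adjustment across
#' sets.  Sets are intersected with the universe first.
#'
#' @param degGenes character vector of DEG ids; must be a subset of
#'   \code{universe}.
#' @param universe character vector of background gene ids (typically all
#'   expressed genes).
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param correction \code{"none"} or \code{"BH"}.
#' @return data.frame per set: \code{set}, \code{n_set} (in-universe set
#'   size), \code{n_overlap}, \code{p}, \code{p_adj}.
#' @export
enrichGeneSets <- function(degGenes, universe, sets,
                           correction = c("BH", "none")) {
    correction <- match.arg(correction)
    if (!length(universe)) stop("empty universe")
    if (anyDuplicated(universe)) universe <- unique(universe)
    outside <- setdiff(degGenes, universe)
    if (length(outside))
        stop("DEG gene(s) absent from universe: ",
             paste(outside, collapse = ", "))
    degGenes <- unique(degGenes)
    N <- length(universe); nDraw <- length(degGenes)
    rows <- lapply(names(sets), function(nm) {
        inUniv <- intersect(geneSets(sets)[[nm]], universe)
        K <- length(inUniv)
        k <- length(intersect(inUniv, degGenes))
        p <- stats::phyper(k - 1, K, N - K, nDraw, lower.tail = FALSE)
        data.frame(set = nm, n_set = K, n_overlap = k, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- if (correction == "BH")
        stats::p.adjust(out$p, method = "BH") else out$p
    out
}
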