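#' @include AllClasses.R accessors.R io.R deg.R response.R aberrancy.R
#' @include trends.R synthesis.R
NULL

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> DEG calling -> set response ->
#' TU aberrancy -> evolution trends in dependency order, writing every
#' stage table as TSV plus a machine-readable run manifest (config echo,
#' package version, seed, per-stage row counts, md5 digest of every
#' output file, accumulated warnings).  A failing stage stops the run
#' with the stage named.  Reruns with the same config and seed produce
#' byte-identical outputs.
#'
#' The YAML config has two optional sections: \code{synth} (overrides
#' for \code{\link{synthConfig}}; used when no \code{inputs} section is
#' given) and \code{pipeline} (overrides for
#' \code{\link{pipelineConfig}}), plus an optional top-level \code{seed}
#' shorthand.  Alternatively pass a list with the same structure.
#'
#' @param config path to a YAML config file, or an equivalent list.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    unknown <- setdiff(names(config), c("seed", "synth", "pipeline"))
    if (length(unknown))
        stop("invalid config key(s): ", paste(unknown, collapse = ", "))
    synthArgs <- config$synth
    if (!is.null(config$seed)) synthArgs$seed <- config$seed
    scfg <- .stage("config", do.call(synthConfig, as.list(synthArgs)))
    pArgs <- config$pipeline
    if (is.null(pArgs$detectionThreshold))
        pArgs$detectionThreshold <- scfg$detectionThreshold
    pcfg <- .stage("config", do.call(pipelineConfig, as.list(pArgs)))
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", outDir)
    warningsSeen <- character()
    keep <- function(expr) withCallingHandlers(expr, warning = function(w) {
        warningsSeen <<- c(warningsSeen, conditionMessage(w))
        invokeRestart("muffleWarning")
    })
    rowCounts <- list()
    p <- function(...) file.path(outDir, ...)

    ## simulate
    suite <- .stage("simulate", {
        s <- generateFixtureSuite(scfg)
        writeFixtures(s, p("fixtures"))
        s
    })
    ## deg
    degNea <- .stage("deg", keep(
        callDegAll(suite$nea$study, suite$nea$contrasts, pcfg)))
    .writeTSV(degNea, p("deg_nea.tsv"))
    rowCounts$deg_nea <- nrow(degNea)
    eaMd <- sampleData(suite$ea$study)
    postTimes <- sort(unique(eaMd$time[eaMd$condition == "evolved"]))
    degEa <- .stage("deg", keep(do.call(rbind, lapply(postTimes, function(tp)
        callDegEA(suite$ea$study, "parent",
                  rownames(eaMd)[eaMd$condition == "evolved" &
                                 eaMd$time == tp],
                  pcfg, contrast = sprintf("ea_h%d", tp))))))
    .writeTSV(degEa, p("deg_ea.tsv"))
    rowCounts$deg_ea <- nrow(degEa)

    ## response
    profile <- .stage("response", keep(setDegProportions(degNea, suite$sets)))
    .writeTSV(profile, p("response_profile.tsv"))
    rowCounts$response_profile <- nrow(profile)
    conc <- vapply(suite$nea$contrasts, contrastEthanol, 0)
    names(conc) <- vapply(suite$nea$contrasts, contrastId, "")
    corRows <- .stage("response", keep(do.call(rbind, lapply(
        names(suite$sets), function(nm) {
            lv <- setResponseLevel(degNea, geneSets(suite$sets)[[nm]],
                                   "mean_lfc")
            if (sum(is.finite(lv[names(conc)])) < 3L) return(NULL)
            cc <- correlateWithCovariate(lv[names(conc)], conc,
                                         pcfg@correlationMethod)
            data.frame(set = nm, covariate = "ethanol", cc,
                       stringsAsFactors = FALSE)
        }))))
    if (!is.null(corRows)) .writeTSV(corRows, p("response_correlations.tsv"))
    rowCounts$response_correlations <-
        if (is.null(corRows)) 0L else nrow(corRows)

    ## aberrancy
    abRep <- .stage("aberrancy", keep(
        aberrancyReport(suite$network, degNea, config = pcfg)))
    .writeTSV(abRep$perTF, p("aberrancy_per_tf.tsv"))
    .writeTSV(abRep$perTU, p("aberrancy_per_tu.tsv"))
    rowCounts$aberrancy_per_tf <- nrow(abRep$perTF)

    ## trends
    trends <- .stage("trends", keep(trendTable(suite$ea$study, pcfg)))
    .writeTSV(trends, p("trend_table.tsv"))
    rowCounts$trend_table <- nrow(trends)
    tally <- .stage("trends", monotoneTally(trends))
    tallyDf <- rbind(tally$perStrain,
                     data.frame(strain = "pooled",
                                n = sum(tally$perStrain$n),
                                pct_monotone = tally$pooled))
    .writeTSV(tallyDf, p("trend_tallies.tsv"))
    finalCt <- sprintf("ea_h%d", max(postTimes))
    degGenes <- degEa$gene[degEa$contrast == finalCt &
                           degEa$call %in% c("up", "down")]
    concRes <- .stage("trends", keep(
        concordanceWithAnnotation(trends, suite$ea$sets, degGenes)))
    .writeTSV(data.frame(percent = concRes$percent, n = concRes$n,
                         defined = concRes$defined),
              p("concordance.tsv"))
    onset <- scfg$regionOnsetTime
    prior <- max(postTimes[postTimes < onset])
    regionRes <- .stage("trends", keep(
        regionShiftTest(suite$ea$study, suite$ea$truth$region$gene,
                        prior, onset, suite$ea$truth$regionStrain, pcfg)))
    .writeTSV(regionRes, p("region_test.tsv"))

    ## manifest
    outFiles <- sort(list.files(outDir, recursive = TRUE))
    outFiles <- setdiff(outFiles, "manifest.json")
    digests <- tools::md5sum(file.path(outDir, outFiles))
    manifest <- list(
        package_version = as.character(utils::packageVersion("regustress")),
        seed = scfg$seed,
        synth_config = unclass(scfg),
        pipeline_config = list(
            fcThreshold = pcfg@fcThreshold, alpha = pcfg@alpha,
            eaMinRelDiff = pcfg@eaMinRelDiff,
            detectionThreshold = pcfg@detectionThreshold,
            rankTest = pcfg@rankTest, eaScale = pcfg@eaScale,
            correlationMethod = pcfg@correlationMethod,
            tuRule = pcfg@tuRule, tieTolerance = pcfg@tieTolerance,
            adjust = pcfg@adjust),
        row_counts = rowCounts,
        warnings = warningsSeen,
        digests = as.list(setNames(unname(digests), outFiles)))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Build consolidated report tables from pipeline outputs
#'
#' Reads the stage TSVs in a pipeline output directory and writes report
#' tables: per-set response heat-map data (display percentages per set
#' and contrast), per-TF aberrancy levels, and trend tallies.  Every
#' report number is re-derivable from the stage TSVs alone.  A missing
#' optional stage output is omitted with a warning.
#'
#' @param outDir a directory produced by \code{\link{runPipeline}}.
#' @return invisibly, a list of the report data.frames.
#' @export
buildReport <- function(outDir) {
    p <- function(...) file.path(outDir, ...)
    out <- list()
    if (file.exists(p("response_profile.tsv"))) {
        prof <- .readTSV(p("response_profile.tsv"))
        rep1 <- prof[, c("set", "contrast", "n_expressed", "pct_up",
                         "pct_down")]
        .writeTSV(rep1, p("report_set_response.tsv"))
        out$set_response <- rep1
    } else warning("response stage output missing; section omitted")
    if (file.exists(p("aberrancy_per_tf.tsv"))) {
        ab <- .readTSV(p("aberrancy_per_tf.tsv"))
        ab$percent_aberrant <- roundHalfUp(ab$percent_aberrant, 1)
        rep2 <- ab[, c("tf", "contrast", "n_sole_tus", "n_scored",
                       "n_aberrant", "percent_aberrant")]
        .writeTSV(rep2, p("report_aberrancy.tsv"))
        out$aberrancy <- rep2
    } else warning("aberrancy stage output missing; section omitted")
    if (file.exists(p("trend_tallies.tsv"))) {
        t1 <- .readTSV(p("trend_tallies.tsv"))
        t1$pct_monotone <- roundHalfUp(t1$pct_monotone, 1)
        .writeTSV(t1, p("report_trends.tsv"))
        out$trends <- t1
    } else warning("trends stage output missing; section omitted")
    invisible(out)
}
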