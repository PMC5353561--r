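#' @include AllClasses.R accessors.R io.R
NULL

#' Synthetic-study configuration
#'
#' Defaults emulate the real study design: seven treatment-versus-control
#' contrasts at ethanol concentrations 2.5, 5, 3 and four times 15
#' percent v/v with replicate groups 3+3, 8+4, 8+4 and four times 3+3;
#' an adaptive-evolution arm of six strains sampled at 384, 744, 1224,
#' 1824 and 2496 hours against one parent; 4,305 genes (the coverage of
#' the smallest array); planted log2 effects of 1.0 with Gaussian log2
#' noise of sd 0.25 for the acute contrasts; per-step increments of 0.2
#' log2 units with sd 0.05 for the replicate-averaged evolution arrays;
#' and a planted tolerance-annotation concordance of 0.91.
#'
#' @param nGenes total genes.
#' @param notExpressedFraction fraction of background genes generated
#'   below the detection threshold.
#' @param baselineRange,lowRange log2 baseline ranges for expressed and
#'   not-expressed genes.
#' @param detectionThreshold log2 expression gate the generated data are
#'   calibrated against.
#' @param nSets,setSizeRange number of gene sets and their size range.
#' @param nTFs,tusPerTF,genesPerTU regulatory-network shape.
#' @param soleRegulatorFraction fraction of TUs with a single regulator.
#' @param activationFraction fraction of activating edges.
#' @param neaEthanol,neaTreatReps,neaCtrlReps per-contrast ethanol
#'   concentration (percent v/v) and replicate counts; equal lengths.
#' @param eaStrains,eaTimes evolution-arm design (times in hours; the
#'   first time point is the parent's).
#' @param effectSize planted log2 fold change of acute DEGs.
#' @param degFraction fraction of background genes planted as DEGs.
#' @param nDoseSets,doseSlope sets given a dose response, linear in
#'   ethanol percent on the log2 scale (log2 units per percent).
#' @param aberrantFraction fraction of sole-regulator TUs planted
#'   aberrant.
#' @param nToleranceGenes tolerance-annotated genes in the evolution arm.
#' @param concordantFraction planted fraction of tolerance genes whose
#'   trend matches their annotation.
#' @param monotoneFraction fraction of unannotated background genes given
#'   a monotone trajectory in the evolution arm.
#' @param stepIncrement per-time-step log2 increment of monotone
#'   trajectories.
#' @param nRegionGenes,regionShift,regionOnsetTime duplication-region
#'   emulation: genes shifted up by \code{regionShift} log2 units in one
#'   strain from \code{regionOnsetTime} onward.
#' @param noiseSd,eaNoiseSd log2 noise sd for the acute and evolution
#'   arms.
#' @param noiseModel \code{"gaussian"} or \code{"t5"} (variance-matched
#'   t with 5 df, for robustness checks).
#' @param seed integer seed; fixes all randomness.
#' @return a validated list of class \code{SynthConfig}.
#' @export
synthConfig <- function(nGenes = 4305,
                        notExpressedFraction = 0.05,
                        baselineRange = c(6, 12), lowRange = c(1, 3),
                        detectionThreshold = 4,
                        nSets = 20, setSizeRange = c(10, 30),
                        nTFs = 10, tusPerTF = 5, genesPerTU = 3,
                        soleRegulatorFraction = 0.8,
                        activationFraction = 0.6,
                        neaEthanol = c(2.5, 5, 3, 15, 15, 15, 15),
                        neaTreatReps = c(3, 8, 8, 3, 3, 3, 3),
                        neaCtrlReps = c(3, 4, 4, 3, 3, 3, 3),
                        eaStrains = 6,
                        eaTimes = c(0, 384, 744, 1224, 1824, 2496),
                        effectSize = 1.0, degFraction = 0.1,
                        nDoseSets = 2, doseSlope = 0.05,
                        aberrantFraction = 0.3,
                        nToleranceGenes = 100,
                        concordantFraction = 0.91,
                        monotoneFraction = 0.2, stepIncrement = 0.2,
                        nRegionGenes = 20, regionShift = 1.0,
                        regionOnsetTime = 1824,
                        noiseSd = 0.25, eaNoiseSd = 0.05,
                        noiseModel = "gaussian", seed = 1L) {
    cfg <- as.list(environment())
    cfg$seed <- as.integer(seed)
    counts <- c(cfg$nGenes, cfg$nSets, cfg$nTFs, cfg$tusPerTF,
                cfg$genesPerTU, cfg$eaStrains, cfg$neaTreatReps,
                cfg$neaCtrlReps)
    if (any(counts < 1)) stop("all counts must be positive")
    fracs <- c(cfg$notExpressedFraction, cfg$soleRegulatorFraction,
               cfg$activationFraction, cfg$degFraction,
               cfg$aberrantFraction, cfg$concordantFraction,
               cfg$monotoneFraction)
    if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
    if (length(cfg$neaEthanol) != length(cfg$neaTreatReps) ||
        length(cfg$neaEthanol) != length(cfg$neaCtrlReps))
        stop("neaEthanol, neaTreatReps and neaCtrlReps lengths must match")
    if (!cfg$noiseModel %in% c("gaussian", "t5"))
        stop("unknown noiseModel")
    nNetGenes <- cfg$nTFs * (1 + cfg$tusPerTF * cfg$genesPerTU)
    if (nNetGenes >= cfg$nGenes)
        stop("infeasible configuration: network needs ", nNetGenes,
             " genes but nGenes = ", cfg$nGenes)
    structure(cfg, class = "SynthConfig")
}

.noise <- function(n, sd, model) {
    if (model == "gaussian") stats::rnorm(n, 0, sd)
    else sd * stats::rt(n, df = 5) / sqrt(5 / 3)
}

## Deterministic identifier layout shared by all generators.
.geneLayout <- function(config) {
    tfs <- sprintf("tf%02d", seq_len(config$nTFs))
    nMembers <- config$nTFs * config$tusPerTF * config$genesPerTU
    members <- sprintf("g%05d", seq_len(nMembers))
    nBg <- config$nGenes - config$nTFs - nMembers
    background <- sprintf("b%05d", seq_len(nBg))
    list(tfs = tfs, members = members, background = background,
         genes = c(tfs, members, background))
}

#' Generate a synthetic regulatory network
#'
#' Builds a TF-to-TU network with the configured shape: each TF owns
#' \code{tusPerTF} TUs of \code{genesPerTU} genes; a configured fraction
#' of TUs keep their owner as sole regulator, the rest receive a second
#' edge from another TF; edge signs are activation with the configured
#' probability.  All TFs are flagged as ethanol-binding proteins (the
#' generator emulates the EBP-TF subnetwork that aberrancy scoring
#' consumes).  Deterministic given the seed.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param seed integer seed (default: the config's).
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
generateNetwork <- function(config, seed = config$seed) {
    set.seed(seed)
    lay <- .geneLayout(config)
    edges <- list(); membersList <- list()
    m <- 0L
    for (i in seq_len(config$nTFs)) {
        tf <- lay$tfs[i]
        for (j in seq_len(config$tusPerTF)) {
            tu <- sprintf("%s_tu%02d", tf, j)
            sgn <- if (stats::runif(1) < config$activationFraction)
                "activation" else "repression"
            edges[[length(edges) + 1L]] <- data.frame(
                tf = tf, tu = tu, sign = sgn, stringsAsFactors = FALSE)
            if (config$nTFs > 1L &&
                stats::runif(1) >= config$soleRegulatorFraction) {
                other <- sample(setdiff(lay$tfs, tf), 1L)
                sgn2 <- if (stats::runif(1) < config$activationFraction)
                    "activation" else "repression"
                edges[[length(edges) + 1L]] <- data.frame(
                    tf = other, tu = tu, sign = sgn2,
                    stringsAsFactors = FALSE)
            }
            gidx <- m + seq_len(config$genesPerTU)
            m <- m + config$genesPerTU
            membersList[[length(membersList) + 1L]] <- data.frame(
                tu = tu, gene = lay$members[gidx], stringsAsFactors = FALSE)
        }
    }
    RegulatoryNetwork(do.call(rbind, edges), do.call(rbind, membersList),
                      isEBP = setNames(rep(TRUE, config$nTFs), lay$tfs))
}

#' Generate synthetic gene sets
#'
#' Draws \code{nSets} sets from the background genes with sizes uniform
#' in \code{setSizeRange}, cycling categories over regulon,
#' stress_response and pathway.  Deterministic given the seed.
#'
#' @inheritParams generateNetwork
#' @return a \linkS4class{GeneSetCollection}.
#' @export
generateGeneSets <- function(config, seed = config$seed + 1L) {
    set.seed(seed)
    lay <- .geneLayout(config)
    cats <- rep(c("regulon", "stress_response", "pathway"),
                length.out = config$nSets)
    sets <- list()
    for (i in seq_len(config$nSets)) {
        sz <- sample(config$setSizeRange[1L]:config$setSizeRange[2L], 1L)
        sets[[sprintf("set%02d", i)]] <- sample(lay$background, sz)
    }
    GeneSetCollection(sets, setNames(cats, names(sets)))
}

#' Generate the acute-stress (treatment-versus-control) study
#'
#' Draws log2 baselines uniform on \code{baselineRange} (a configured
#' fraction of background genes below the detection gate instead), then
#' plants: per-TF states (up with probability 1/2), sole-regulator-TU
#' member shifts that are consistent with or aberrant to the TF state
#' given the edge sign, background DEGs at the configured effect size and
#' fraction, and, when a gene-set collection is supplied, dose-responsive
#' sets whose members shift proportionally to the contrast's ethanol
#' concentration.  Adds i.i.d. log2 noise.  Deterministic given the seed.
#'
#' @inheritParams generateNetwork
#' @param network a \linkS4class{RegulatoryNetwork} from
#'   \code{\link{generateNetwork}} with the same config.
#' @param sets optional \linkS4class{GeneSetCollection}; the first
#'   \code{nDoseSets} sets become dose-responsive.
#' @return list: \code{study} (\linkS4class{ExpressionStudy}),
#'   \code{contrasts} (list of \linkS4class{ContrastDesign}),
#'   \code{truth} (list of data.frames: \code{deg}, \code{aberrant},
#'   \code{dose}, \code{tfState}, \code{notExpressed}).
#' @export
generateNEAStudy <- function(config, network, sets = NULL,
                             seed = config$seed + 2L) {
    set.seed(seed)
    lay <- .geneLayout(config)
    genes <- lay$genes
    nG <- length(genes)
    baseline <- stats::runif(nG, config$baselineRange[1L],
                             config$baselineRange[2L])
    names(baseline) <- genes
    nLow <- round(config$notExpressedFraction * length(lay$background))
    lowGenes <- if (nLow > 0) sample(lay$background, nLow) else character()
    baseline[lowGenes] <- stats::runif(nLow, config$lowRange[1L],
                                       config$lowRange[2L])

    ## TF states and TU planting
    tfUp <- stats::runif(config$nTFs) < 0.5
    names(tfUp) <- lay$tfs
    shift <- setNames(rep(0, nG), genes)
    shift[lay$tfs[tfUp]] <- config$effectSize
    edges <- tfEdges(network)
    aberrantRows <- list()
    for (tf in lay$tfs) {
        for (tu in soleRegulatorTUs(network, tf)) {
            sgn <- edges$sign[edges$tf == tf & edges$tu == tu][1L]
            aberrant <- stats::runif(1) < config$aberrantFraction
            up <- tfUp[[tf]]
            memberShift <-
                if (sgn == "activation") {
                    if (up && !aberrant) config$effectSize
                    else if (!up && aberrant) -config$effectSize
                    else 0
                } else {
                    if (up && !aberrant) -config$effectSize
                    else if (aberrant) config$effectSize
                    else 0
                }
            shift[tuMembers(network, tu)] <- memberShift
            aberrantRows[[length(aberrantRows) + 1L]] <- data.frame(
                tf = tf, tu = tu, sign = sgn,
                tf_state = if (up) "up" else "ns",
                planted_verdict = if (aberrant) "aberrant" else "consistent",
                stringsAsFactors = FALSE)
        }
    }

    ## Dose-responsive sets (members excluded from plain DEG planting)
    doseGenes <- character(); doseRows <- list()
    if (!is.null(sets) && config$nDoseSets > 0) {
        pick <- utils::head(names(sets), config$nDoseSets)
        for (nm in pick) {
            doseGenes <- union(doseGenes, geneSets(sets)[[nm]])
            doseRows[[length(doseRows) + 1L]] <- data.frame(
                set = nm, slope = config$doseSlope,
                stringsAsFactors = FALSE)
        }
    }

    ## Background DEGs
    eligible <- setdiff(lay$background, c(lowGenes, doseGenes))
    planted <- eligible[stats::runif(length(eligible)) < config$degFraction]
    plantedDir <- sample(c(1, -1), length(planted), replace = TRUE)
    shift[planted] <- plantedDir * config$effectSize

    contrastIds <- sprintf("nea%02d", seq_along(config$neaEthanol))
    degRows <- list()
    truthGenes <- names(shift)[shift != 0]
    for (ct in contrastIds)
        degRows[[ct]] <- data.frame(
            gene = truthGenes, contrast = rep(ct, length(truthGenes)),
            direction = ifelse(shift[truthGenes] > 0, "up", "down"),
            effect = abs(shift[truthGenes]), stringsAsFactors = FALSE)

    ## Assemble matrix
    cols <- list(); md <- list(); contrasts <- list()
    for (i in seq_along(config$neaEthanol)) {
        conc <- config$neaEthanol[i]
        nT <- config$neaTreatReps[i]; nC <- config$neaCtrlReps[i]
        doseShift <- setNames(rep(0, nG), genes)
        doseShift[doseGenes] <- config$doseSlope * conc
        tIds <- sprintf("%s_t%d", contrastIds[i], seq_len(nT))
        cIds <- sprintf("%s_c%d", contrastIds[i], seq_len(nC))
        for (k in seq_len(nT)) {
            cols[[tIds[k]]] <- baseline + shift + doseShift +
                .noise(nG, config$noiseSd, config$noiseModel)
            md[[tIds[k]]] <- data.frame(
                condition = "treatment", replicate = k, strain = "NEA",
                time = NA_real_, ethanol = conc, stringsAsFactors = FALSE)
        }
        for (k in seq_len(nC)) {
            cols[[cIds[k]]] <- baseline +
                .noise(nG, config$noiseSd, config$noiseModel)
            md[[cIds[k]]] <- data.frame(
                condition = "control", replicate = k, strain = "NEA",
                time = NA_real_, ethanol = 0, stringsAsFactors = FALSE)
        }
        contrasts[[i]] <- contrastDesign(contrastIds[i], tIds, cIds, conc)
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    mdDf <- do.call(rbind, md)
    rownames(mdDf) <- colnames(values)
    study <- ExpressionStudy(values, mdDf)
    truth <- list(
        deg = do.call(rbind, degRows),
        aberrant = if (length(aberrantRows)) do.call(rbind, aberrantRows)
                   else data.frame(),
        dose = if (length(doseRows)) do.call(rbind, doseRows)
               else data.frame(),
        tfState = data.frame(tf = lay$tfs,
                             state = ifelse(tfUp, "up", "ns"),
                             stringsAsFactors = FALSE),
        notExpressed = data.frame(gene = lowGenes,
                                  stringsAsFactors = FALSE))
    list(study = study, contrasts = contrasts, truth = truth)
}

#' Generate the adaptive-evolution time course
#'
#' One parent sample plus \code{eaStrains} strains sampled once at each
#' post-zero time point.  Tolerance-annotated genes receive monotone
#' trajectories (per-step increment \code{stepIncrement}); a planted
#' fraction \code{concordantFraction} trend in their annotated direction
#' and the rest in the opposite direction.  A further
#' \code{monotoneFraction} of unannotated background genes get monotone
#' trajectories of random direction.  One strain carries a
#' duplication-region emulation: \code{nRegionGenes} genes shifted up by
#' \code{regionShift} from \code{regionOnsetTime} onward.  Deterministic
#' given the seed.
#'
#' @inheritParams generateNetwork
#' @return list: \code{study}, \code{sets} (a tolerance
#'   \linkS4class{GeneSetCollection} with direction annotations),
#'   \code{truth} (data.frames \code{monotone}, \code{region}; scalar
#'   \code{regionStrain}).
#' @export
generateEATimecourse <- function(config, seed = config$seed + 3L) {
    set.seed(seed)
    lay <- .geneLayout(config)
    genes <- lay$genes; nG <- length(genes)
    baseline <- stats::runif(nG, config$baselineRange[1L],
                             config$baselineRange[2L])
    names(baseline) <- genes
    nLow <- round(config$notExpressedFraction * length(lay$background))
    lowGenes <- if (nLow > 0) sample(lay$background, nLow) else character()
    baseline[lowGenes] <- stats::runif(nLow, config$lowRange[1L],
                                       config$lowRange[2L])

    bg <- setdiff(lay$background, lowGenes)
    tolGenes <- sample(bg, min(config$nToleranceGenes, length(bg)))
    annotation <- sample(c("overexpression_tolerant", "knockout_tolerant"),
                         length(tolGenes), replace = TRUE)
    ## exact-count planting: the concordant fraction is a design
    ## parameter, not a random rate
    concordant <- rep(FALSE, length(tolGenes))
    concordant[sample(length(tolGenes),
                      round(config$concordantFraction *
                            length(tolGenes)))] <- TRUE
    expectedDir <- ifelse(annotation == "overexpression_tolerant", 1, -1)
    plantedDir <- ifelse(concordant, expectedDir, -expectedDir)

    rest <- setdiff(bg, tolGenes)
    otherMono <- rest[stats::runif(length(rest)) < config$monotoneFraction]
    otherDir <- sample(c(1, -1), length(otherMono), replace = TRUE)

    slope <- setNames(rep(0, nG), genes)
    slope[tolGenes] <- plantedDir * config$stepIncrement
    slope[otherMono] <- otherDir * config$stepIncrement

    regionGenes <- sample(setdiff(rest, otherMono),
                          min(config$nRegionGenes,
                              length(setdiff(rest, otherMono))))
    strains <- LETTERS[seq_len(config$eaStrains)]
    regionStrain <- strains[min(3L, length(strains))]

    times <- config$eaTimes
    postTimes <- times[times > 0]
    cols <- list(); md <- list()
    cols[["parent"]] <- baseline +
        .noise(nG, config$eaNoiseSd, config$noiseModel)
    md[["parent"]] <- data.frame(condition = "parent", replicate = 1,
                                 strain = "parent", time = 0, ethanol = 5,
                                 stringsAsFactors = FALSE)
    for (st in strains) {
        for (k in seq_along(postTimes)) {
            tp <- postTimes[k]
            id <- sprintf("%s_h%d", st, tp)
            val <- baseline + slope * k +
                .noise(nG, config$eaNoiseSd, config$noiseModel)
            if (st == regionStrain && tp >= config$regionOnsetTime)
                val[regionGenes] <- val[regionGenes] + config$regionShift
            cols[[id]] <- val
            md[[id]] <- data.frame(condition = "evolved", replicate = 1,
                                   strain = st, time = tp, ethanol = 5,
                                   stringsAsFactors = FALSE)
        }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    mdDf <- do.call(rbind, md)
    rownames(mdDf) <- colnames(values)
    study <- ExpressionStudy(values, mdDf)
    sets <- GeneSetCollection(
        list(tolerance = tolGenes),
        setNames("tolerance", "tolerance"),
        list(tolerance = setNames(annotation, tolGenes)))
    truth <- list(
        monotone = data.frame(
            gene = c(tolGenes, otherMono),
            direction = ifelse(c(plantedDir, otherDir) > 0,
                               "monotone_up", "monotone_down"),
            annotated = c(rep(TRUE, length(tolGenes)),
                          rep(FALSE, length(otherMono))),
            concordant = c(concordant, rep(NA, length(otherMono))),
            stringsAsFactors = FALSE),
        region = data.frame(gene = regionGenes, stringsAsFactors = FALSE),
        regionStrain = regionStrain)
    list(study = study, sets = sets, truth = truth)
}

#' Generate a complete fixture suite
#'
#' Runs all generators with derived seeds (network: \code{seed}; sets:
#' \code{seed + 1}; acute study: \code{seed + 2}; evolution arm:
#' \code{seed + 3}) and returns every artifact the pipeline consumes.
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list: \code{config}, \code{network}, \code{sets}, \code{nea},
#'   \code{ea}.
#' @export
generateFixtureSuite <- function(config = synthConfig()) {
    network <- generateNetwork(config)
    sets <- generateGeneSets(config)
    nea <- generateNEAStudy(config, network, sets)
    ea <- generateEATimecourse(config)
    list(config = config, network = network, sets = sets,
         nea = nea, ea = ea)
}

#' Write a fixture suite to disk
#'
#' Writes every artifact in the formats the readers consume (expression
#' and metadata TSVs, contrasts TSV, GMT gene sets with a direction side
#' table, the network edge/membership file, truth tables as TSV) plus a
#' \code{manifest.json} recording the full config and seed.
#'
#' @param suite output of \code{\link{generateFixtureSuite}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeFixtures <- function(suite, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", dir)
    p <- function(...) file.path(dir, ...)
    writeExpressionStudy(suite$nea$study, p("nea_expression.tsv"),
                         p("nea_metadata.tsv"))
    writeContrasts(suite$nea$contrasts, p("nea_contrasts.tsv"))
    writeExpressionStudy(suite$ea$study, p("ea_expression.tsv"),
                         p("ea_metadata.tsv"))
    writeGeneSets(suite$sets, p("sets.gmt"))
    writeGeneSets(suite$ea$sets, p("tolerance.gmt"),
                  p("tolerance_directions.tsv"))
    writeNetwork(suite$network, p("network.tsv"))
    for (nm in names(suite$nea$truth)) {
        tab <- suite$nea$truth[[nm]]
        if (is.data.frame(tab) && nrow(tab))
            .writeTSV(tab, p(sprintf("truth_nea_%s.tsv", nm)))
    }
    .writeTSV(suite$ea$truth$monotone, p("truth_ea_monotone.tsv"))
    .writeTSV(suite$ea$truth$region, p("truth_ea_region.tsv"))
    manifest <- list(
        config = unclass(suite$config),
        seed = suite$config$seed,
        region_strain = suite$ea$truth$regionStrain,
        files = sort(list.files(dir)))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(p("manifest.json"))
}
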