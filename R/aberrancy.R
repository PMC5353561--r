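#' @include AllClasses.R accessors.R
NULL

#' Summarize member-gene DEG calls to a TU-level call
#'
#' A transcription unit's call is derived from its member genes' calls.
#' Under the default \code{majority} rule the TU takes the direction held
#' by more than half of its expressed members, otherwise \code{ns};
#' \code{any} requires at least one member in a direction and none in the
#' other; \code{all} requires every expressed member to agree.  A TU with
#' no expressed member is \code{not_expressed}.
#'
#' @param deg DEG data.frame restricted to one contrast (or a named
#'   character vector of calls).
#' @param members character vector of the TU's gene ids.
#' @param rule \code{"majority"}, \code{"any"} or \code{"all"}.
#' @return single call string.
#' @export
summarizeTU <- function(deg, members, rule = c("majority", "any", "all")) {
    rule <- match.arg(rule)
    calls <- if (is.data.frame(deg)) {
        if (length(unique(deg$contrast)) > 1L)
            stop("summarizeTU expects calls from a single contrast")
        setNames(deg$call, deg$gene)[members]
    } else deg[members]
    calls <- calls[!is.na(calls)]
    calls <- calls[calls != "not_expressed"]
    if (!length(calls)) return("not_expressed")
    nUp <- sum(calls == "up"); nDown <- sum(calls == "down")
    n <- length(calls)
    switch(rule,
        majority = if (nUp > n / 2) "up" else if (nDown > n / 2) "down"
                   else "ns",
        any = if (nUp >= 1L && nDown == 0L) "up"
              else if (nDown >= 1L && nUp == 0L) "down" else "ns",
        all = if (nUp == n) "up" else if (nDown == n) "down" else "ns")
}

#' Classify a TU as aberrantly or consistently expressed
#'
#' Applies the four-case regulatory-consistency rule comparing the TF's
#' own differential-expression state with the TU's state given the edge
#' sign.  An activated TU is aberrant when the TF is unchanged but the TU
#' is down-regulated, or the TF is up-regulated but the TU is not (i.e.
#' the TU is \code{ns} or \code{down}).  A repressed TU is aberrant when
#' the TF is unchanged but the TU is up-regulated, or both TF and TU are
#' up-regulated.  The rule enumerates only \code{ns}/\code{up} TF states;
#' a down-regulated TF (and a \code{not_expressed} TU) is classified
#' \code{indeterminate} rather than silently scored.
#'
#' @param tfCall,tuCall call strings (vectorized): \code{up}, \code{down}
#'   or \code{ns} (\code{not_expressed} allowed for \code{tuCall}).
#' @param sign edge sign: \code{activation} or \code{repression}
#'   (vectorized, recycled).
#' @return character vector of verdicts: \code{aberrant},
#'   \code{consistent} or \code{indeterminate}.
#' @export
classifyAberrant <- function(tfCall, tuCall, sign) {
    n <- max(length(tfCall), length(tuCall), length(sign))
    tfCall <- rep_len(tfCall, n); tuCall <- rep_len(tuCall, n)
    sign <- rep_len(sign, n)
    bad <- !(sign %in% .SIGNS)
    if (any(bad)) stop("unknown sign token: ", unique(sign[bad])[1L])
    verdict <- character(n)
    for (i in seq_len(n)) {
        verdict[i] <- if (tfCall[i] == "down" ||
                          tuCall[i] == "not_expressed") {
            "indeterminate"
        } else if (sign[i] == "activation") {
            if ((tfCall[i] == "ns" && tuCall[i] == "down") ||
                (tfCall[i] == "up" && tuCall[i] != "up"))
                "aberrant" else "consistent"
        } else {
            if ((tfCall[i] == "ns" && tuCall[i] == "up") ||
                (tfCall[i] == "up" && tuCall[i] == "up"))
                "aberrant" else "consistent"
        }
    }
    verdict
}

#' Aberrancy level of one TF's sole-regulator TUs
#'
#' Restricts to TUs whose only incoming regulatory edge is from the given
#' TF, summarizes each TU's member calls, classifies each against the
#' TF's own call, and reports the percentage aberrant.  Indeterminate TUs
#' are excluded from both numerator and denominator; a TF with no
#' scorable sole-regulator TU is flagged undefined.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param deg DEG data.frame for one contrast (must contain the TF's own
#'   gene).
#' @param tf TF identifier (its gene id).
#' @param config a \linkS4class{PipelineConfig} (\code{tuRule}).
#' @return list with \code{summary} (one-row data.frame: \code{tf},
#'   \code{n_sole_tus}, \code{n_scored}, \code{n_aberrant},
#'   \code{percent_aberrant}, \code{defined}) and \code{tuVerdicts}
#'   (per-TU data.frame).
#' @export
aberrancyLevel <- function(network, deg, tf, config = pipelineConfig()) {
    if (!(tf %in% networkTFs(network)))
        stop("TF not in network: ", tf)
    if (length(unique(deg$contrast)) > 1L)
        stop("aberrancyLevel expects calls from a single contrast")
    tfRow <- deg[deg$gene == tf, , drop = FALSE]
    if (!nrow(tfRow)) stop("TF gene absent from DEG table: ", tf)
    tfCall <- tfRow$call[1L]
    sole <- soleRegulatorTUs(network, tf)
    edges <- tfEdges(network)
    tuRows <- lapply(sole, function(tu) {
        tuCall <- summarizeTU(deg, tuMembers(network, tu), config@tuRule)
        sgn <- edges$sign[edges$tf == tf & edges$tu == tu][1L]
        verdict <- if (tfCall == "not_expressed") "indeterminate"
                   else classifyAberrant(tfCall, tuCall, sgn)
        data.frame(tf = tf, tu = tu, sign = sgn, tf_call = tfCall,
                   tu_call = tuCall, verdict = verdict,
                   stringsAsFactors = FALSE)
    })
    tuVerdicts <- if (length(tuRows)) do.call(rbind, tuRows) else
        data.frame(tf = character(), tu = character(), sign = character(),
                   tf_call = character(), tu_call = character(),
                   verdict = character(), stringsAsFactors = FALSE)
    scored <- tuVerdicts$verdict != "indeterminate"
    nScored <- sum(scored)
    nAb <- sum(tuVerdicts$verdict == "aberrant")
    summary <- data.frame(
        tf = tf, n_sole_tus = length(sole), n_scored = nScored,
        n_aberrant = nAb,
        percent_aberrant = if (nScored > 0) 100 * nAb / nScored
                           else NA_real_,
        defined = nScored > 0, stringsAsFactors = FALSE)
    list(summary = summary, tuVerdicts = tuVerdicts)
}

#' Aberrancy report across TFs
#'
#' Runs \code{\link{aberrancyLevel}} for each TF (by default the
#' ethanol-binding-protein TFs, the only ones whose regulatory function
#' ethanol is hypothesized to alter) and per contrast in the DEG table.
#'
#' @inheritParams aberrancyLevel
#' @param deg DEG data.frame, one or more contrasts.
#' @param tfs TF ids to score; default all EBP-flagged TFs in the
#'   network.
#' @return list with \code{perTF} and \code{perTU} data.frames.
#' @export
aberrancyReport <- function(network, deg, tfs = NULL,
                            config = pipelineConfig()) {
    if (is.null(tfs)) tfs <- networkTFs(network, ebpOnly = TRUE)
    perTF <- list(); perTU <- list()
    for (ct in unique(deg$contrast)) {
        d <- deg[deg$contrast == ct, , drop = FALSE]
        for (tf in tfs) {
            res <- aberrancyLevel(network, d, tf, config)
            res$summary$contrast <- ct
            if (nrow(res$tuVerdicts)) res$tuVerdicts$contrast <- ct
            perTF[[length(perTF) + 1L]] <- res$summary
            perTU[[length(perTU) + 1L]] <- res$tuVerdicts
        }
    }
    list(perTF = do.call(rbind, perTF), perTU = do.call(rbind, perTU))
}
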