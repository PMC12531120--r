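## Monotonic dysregulation calling across ordered histology stages,
## signature scores, single-sample enrichment, and Fisher pathway
## enrichment.

#' Per-analyte stage effects and significance versus controls
#'
#' For each analyte and each histology group g (NU_LGIN, HGIN, UC):
#' effect e(g) = mean log abundance in the group minus the control mean
#' (missing values excluded pairwise), with a two-sided Wilcoxon rank-sum
#' test against the controls; Benjamini-Hochberg adjustment is applied
#' within each group across analytes.
#'
#' @param omics an \linkS4class{OmicsMatrix} (needs at least one control
#'   and at least 2 samples per histology group).
#' @return \link[S4Vectors]{DataFrame} per analyte: \code{e_<group>},
#'   \code{p_<group>}, \code{q_<group>} for the three groups.
#' @export
stageEffects <- function(omics) {
    m <- abundanceMatrix(omics)
    role <- sampleRoles(omics)
    grp <- sampleGroups(omics)
    ctrl <- m[, role == "control", drop = FALSE]
    present <- intersect(GROUP_LEVELS, unique(grp[role == "map_field"]))
    missing <- setdiff(GROUP_LEVELS, present)
    if (length(missing))
        stop("missing histology group(s): ",
             paste(missing, collapse = ", "),
             " (present: ", paste(present, collapse = ", "), ")")
    out <- DataFrame(analyte_id = rownames(m))
    for (g in GROUP_LEVELS) {
        gm <- m[, role == "map_field" & grp == g, drop = FALSE]
        if (ncol(gm) < 2)
            stop("group ", g, " has fewer than 2 samples")
        e <- rowMeans(gm, na.rm = TRUE) - rowMeans(ctrl, na.rm = TRUE)
        p <- vapply(seq_len(nrow(m)), function(i) {
            x <- gm[i, ][!is.na(gm[i, ])]
            y <- ctrl[i, ][!is.na(ctrl[i, ])]
            if (length(x) < 2 || length(y) < 1) return(NA_real_)
            if (length(unique(c(x, y))) == 1) return(1)  # all tied
            suppressWarnings(stats::wilcox.test(x, y)$p.value)
        }, numeric(1))
        e[is.nan(e)] <- NA
        q <- rep(NA_real_, length(p))
        q[!is.na(p)] <- bhFdr(p[!is.na(p)])
        out[[paste0("e_", g)]] <- unname(e)
        out[[paste0("p_", g)]] <- p
        out[[paste0("q_", g)]] <- q
    }
    rownames(out) <- rownames(m)
    out
}

#' Call monotonically dysregulated analytes and assign waves
#'
#' Monotone-up: e(NU_LGIN) <= e(HGIN) + tau <= e(UC) + 2*tau with
#' e(UC) > 0 and q(UC) < qCut (mirrored for down). Wave 1 when already
#' significant in NU_LGIN; wave 2 when first significant in HGIN.
#'
#' @param effects result of \code{\link{stageEffects}}.
#' @param qCut significance cut; default 0.05.
#' @param tau monotonicity tolerance (log units); default 0.
#' @return \link[S4Vectors]{DataFrame} per analyte: \code{direction}
#'   (up/down/none), \code{monotone}, \code{wave} (1, 2 or NA), plus the
#'   input effect and q columns.
#' @export
callMonotonic <- function(effects, qCut = 0.05, tau = 0) {
    e1 <- effects$e_NU_LGIN; e2 <- effects$e_HGIN; e3 <- effects$e_UC
    q1 <- effects$q_NU_LGIN; q2 <- effects$q_HGIN; q3 <- effects$q_UC
    ok <- !is.na(e1) & !is.na(e2) & !is.na(e3) & !is.na(q3)
    up <- ok & e1 <= e2 + tau & e2 <= e3 + tau & e3 > 0 & q3 < qCut
    down <- ok & e1 >= e2 - tau & e2 >= e3 - tau & e3 < 0 & q3 < qCut
    monotone <- unname(up | down)
    direction <- unname(ifelse(up, "up", ifelse(down, "down", "none")))
    wave <- rep(NA_integer_, length(e1))
    wave[monotone & !is.na(q1) & q1 < qCut] <- 1L
    wave[monotone & is.na(wave) & !is.na(q2) & q2 < qCut] <- 2L
    out <- DataFrame(analyte_id = effects$analyte_id,
                     direction = direction, monotone = monotone,
                     wave = wave)
    out <- cbind(out, effects[, setdiff(colnames(effects), "analyte_id"),
                              drop = FALSE])
    rownames(out) <- rownames(effects)
    out
}

#' Signature score from up/down marker sets
#'
#' Per-sample mean z-score of the up-set members minus the mean z of the
#' down-set members, z computed per analyte against the control mean and
#' SD. An empty down set contributes 0.
#'
#' @param omics an \linkS4class{OmicsMatrix}.
#' @param upSet,downSet character vectors of analyte ids.
#' @return named numeric vector (one score per sample).
#' @export
signatureScore <- function(omics, upSet, downSet = character()) {
    m <- abundanceMatrix(omics)
    role <- sampleRoles(omics)
    upSet <- intersect(upSet, rownames(m))
    downSet <- intersect(downSet, rownames(m))
    if (!length(upSet) && !length(downSet))
        stop("no set member is present in the matrix")
    ctrl <- m[, role == "control", drop = FALSE]
    mu <- rowMeans(ctrl, na.rm = TRUE)
    sd0 <- apply(ctrl, 1, stats::sd, na.rm = TRUE)
    sd0[is.na(sd0) | sd0 == 0] <- 1
    z <- (m - mu) / sd0
    partMean <- function(set) {
        if (!length(set)) return(rep(0, ncol(m)))
        colMeans(z[set, , drop = FALSE], na.rm = TRUE)
    }
    score <- partMean(upSet) - partMean(downSet)
    names(score) <- colnames(m)
    score
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum statistic: analytes are ranked by expression
#' (descending) and both the in-set and out-set cumulative distributions
#' are weighted by rank^alpha; the score is the signed area between them
#' (default) or their maximum deviation, in [-1, 1] either way.
#' Deterministic and invariant under strictly monotone transforms of the
#' expression vector; the area convention has a null mean within
#' Monte-Carlo error of zero for random sets.
#'
#' @param expr named numeric vector of expression values for one sample.
#' @param geneSet character vector of analyte ids.
#' @param alpha rank weight exponent; default 0.75.
#' @param conv \code{"area"} (default) or \code{"maxdev"}.
#' @return the enrichment score.
#' @export
ssgseaEs <- function(expr, geneSet, alpha = 0.75,
                     conv = c("area", "maxdev")) {
    conv <- match.arg(conv)
    expr <- expr[!is.na(expr)]
    if (length(expr) < 10)
        stop("need at least 10 analytes")
    inSet <- names(expr) %in% geneSet
    if (!any(inSet)) stop("gene set does not intersect the analytes")
    if (all(inSet)) stop("gene set covers every analyte")
    ord <- order(expr, decreasing = TRUE)
    inSet <- inSet[ord]
    n <- length(expr)
    w <- (n - seq_len(n) + 1)^alpha  # weight by rank from the top
    win <- w; win[!inSet] <- 0
    wout <- w; wout[inSet] <- 0
    d <- cumsum(win) / sum(win) - cumsum(wout) / sum(wout)
    if (conv == "area") mean(d) else d[which.max(abs(d))]
}

#' One-sided Fisher (hypergeometric) pathway enrichment
#'
#' Upper-tail hypergeometric p per gene set for an observed hit list,
#' with Benjamini-Hochberg adjustment across sets.
#'
#' @param hits character vector of hit genes (must be a subset of
#'   \code{universe}).
#' @param universe character vector, the tested universe.
#' @param geneSets named list of character vectors.
#' @return \link[S4Vectors]{DataFrame} per set: \code{set}, \code{size}
#'   (in-universe), \code{overlap}, \code{p}, \code{q}.
#' @export
pathwayEnrichment <- function(hits, universe, geneSets) {
    hits <- unique(hits)
    universe <- unique(universe)
    if (!all(hits %in% universe))
        stop("hits must be a subset of the universe")
    N <- length(universe)
    n <- length(hits)
    res <- lapply(names(geneSets), function(nm) {
        set <- intersect(geneSets[[nm]], universe)
        K <- length(set)
        k <- length(intersect(hits, set))
        p <- if (K == 0) 1 else
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set = nm, size = K, overlap = k, p = p)
    })
    out <- do.call(rbind, res)
    out$q <- bhFdr(out$p)
    rownames(out) <- out$set
    DataFrame(out)
}

#' RNA/protein concordantly dysregulated analytes
#'
#' Analytes called monotone in both layers with the same direction.
#'
#' @param callsRna,callsProtein results of \code{\link{callMonotonic}}
#'   (matched on \code{analyte_id}).
#' @return \link[S4Vectors]{DataFrame}: \code{analyte_id},
#'   \code{direction}; attribute \code{counts} holds shared/concordant
#'   totals.
#' @export
rnaProteinConcordance <- function(callsRna, callsProtein) {
    shared <- intersect(callsRna$analyte_id, callsProtein$analyte_id)
    if (!length(shared)) stop("no shared analyte identifiers")
    r <- callsRna[match(shared, callsRna$analyte_id), ]
    p <- callsProtein[match(shared, callsProtein$analyte_id), ]
    conc <- r$monotone & p$monotone & r$direction == p$direction
    out <- DataFrame(analyte_id = shared[conc],
                     direction = r$direction[conc])
    attr(out, "counts") <- c(shared = length(shared),
                             concordant = sum(conc))
    out
}
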