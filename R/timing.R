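## Mutation ages and selection coefficients from a clock-calibrated
## branching-process surrogate on the parsimony tree, plus the
## dormant/progressive phase partition.

#' Root a field tree at the hypothetical all-zero ancestor
#'
#' The tree is rooted next to the field with the fewest present mutations
#' (the most-normal field), the cheapest parsimony attachment point for a
#' mutation-free ancestor; the root node then stands for "node 0", the
#' hypothetical beginning of the process.
#'
#' @param tree unrooted \code{phylo} over field ids.
#' @param chars binary character matrix (fields x mutations).
#' @return a rooted \code{phylo}.
#' @export
rootOrganTree <- function(tree, chars) {
    base <- rownames(chars)[which.min(rowSums(chars))]
    if (!base %in% tree$tip.label) base <- tree$tip.label[1]
    if (ape::is.rooted(tree)) return(tree)
    ape::root(tree, outgroup = base, resolve.root = TRUE)
}

## logical clade membership matrix: (nTip + nNode) x nTip
cladeMembership <- function(tree) {
    ed <- tree$edge
    nTip <- length(tree$tip.label)
    nAll <- max(ed)
    M <- matrix(FALSE, nAll, nTip)
    M[cbind(seq_len(nTip), seq_len(nTip))] <- TRUE
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (i in seq_len(nrow(po)))
        M[po[i, 1], ] <- M[po[i, 1], ] | M[po[i, 2], ]
    colnames(M) <- tree$tip.label
    M
}

#' Place each mutation on a tree edge
#'
#' A mutation is assigned to the edge above the smallest clade containing
#' all fields in which it is present (its MRCA edge). Mutations whose
#' presence set is not exactly a clade are flagged homoplastic but still
#' placed on the MRCA edge. Mutations present in every field sit on the
#' root stem (edge index 0).
#'
#' @param tree rooted \code{phylo} over field ids.
#' @param chars binary matrix fields x mutations (columns named by
#'   mutation id).
#' @return \link[S4Vectors]{DataFrame}: \code{mutation_id}, \code{node}
#'   (MRCA), \code{edge} (row of \code{tree$edge}; 0 = root stem),
#'   \code{terminal}, \code{homoplasy}, \code{n_present}.
#' @export
assignEdges <- function(tree, chars) {
    chars <- chars[tree$tip.label, , drop = FALSE]
    nPresent <- colSums(chars)
    if (any(nPresent == 0)) stop("mutation absent from every field")
    M <- cladeMembership(tree)
    sizes <- rowSums(M)
    cover <- (M %*% chars) == rep(nPresent, each = nrow(M))
    sizeMat <- matrix(sizes, nrow(M), ncol(chars))
    sizeMat[!cover] <- Inf
    mrca <- max.col(-t(sizeMat), ties.method = "first")
    edge <- match(mrca, tree$edge[, 2])
    edge[is.na(edge)] <- 0L  # root
    nTip <- length(tree$tip.label)
    out <- DataFrame(mutation_id = colnames(chars), node = mrca,
                     edge = edge, terminal = mrca <= nTip,
                     homoplasy = sizes[mrca] != nPresent,
                     n_present = nPresent)
    rownames(out) <- colnames(chars)
    out
}

## per-node forward times: t(v) = T * d(v) / (d(v) + h(v)) with d the raw
## root distance and h the mean raw distance to the node's descendant
## leaves; every root-to-leaf path then spans exactly (0, T).
nodeTimes <- function(tree, rawLen, T_total) {
    ed <- tree$edge
    nTip <- length(tree$tip.label)
    nAll <- max(ed)
    root <- setdiff(ed[, 1], ed[, 2])[1]
    d <- numeric(nAll)
    pre <- ape::reorder.phylo(tree, "postorder")$edge
    for (i in rev(seq_len(nrow(pre))))
        d[pre[i, 2]] <- d[pre[i, 1]] + rawLen[match(
            paste(pre[i, 1], pre[i, 2]),
            paste(ed[, 1], ed[, 2]))]
    hsum <- numeric(nAll)
    hcnt <- numeric(nAll)
    hcnt[seq_len(nTip)] <- 1
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (i in seq_len(nrow(po))) {
        p <- po[i, 1]; c <- po[i, 2]
        len <- rawLen[match(paste(p, c), paste(ed[, 1], ed[, 2]))]
        hsum[p] <- hsum[p] + hcnt[c] * len + hsum[c]
        hcnt[p] <- hcnt[p] + hcnt[c]
    }
    h <- ifelse(hcnt > 0, hsum / pmax(hcnt, 1), 0)
    t <- ifelse(d + h > 0, T_total * d / (d + h), 0)
    t[seq_len(nTip)] <- T_total
    t[root] <- 0
    t
}

#' Calibrate a time clock on the field tree and date every mutation
#'
#' Edge time spans come from a neutral-mutation clock: the raw length of
#' an edge is the number of neutral (alpha-class) mutations assigned to it
#' plus a pseudocount, and node times are rescaled so that every
#' root-to-leaf path spans the full organ history \code{T_total}.
#' Mutations on an edge are placed at uniform quantiles of its span
#' (VAF-descending, so higher-frequency variants date older); with
#' \code{placement = "midpoint"} all mutations on an edge take its
#' midpoint. Ages are years before observation.
#'
#' When \code{sweepAware} is TRUE (default), internal edges carrying at
#' least \code{cloneMinMut} shared mutations are treated as clonal
#' expansions that postdate the divergence of the field lineages: such
#' clones are re-dated into the progressive window (most recent
#' \code{progressiveWindow} years), ordered by their median present VAF
#' (successive clones show increasing VAFs), with the window partitioned
#' in proportion to clone mutation counts.
#'
#' @param tree rooted \code{phylo} (see \code{\link{rootOrganTree}}).
#' @param mut a \linkS4class{MutationTable}.
#' @param neutralIds mutation ids used as the neutral clock (typically the
#'   alpha class); must be non-empty.
#' @param assign optional result of \code{\link{assignEdges}}.
#' @param T_total organ history in years (calibration input); default 30.
#' @param progressiveWindow duration of the progressive phase used for
#'   sweep-aware clone dating (calibration input, like \code{T_total});
#'   default 5.
#' @param pseudo edge pseudocount; default 0.5.
#' @param placement \code{"quantile"} (default) or \code{"midpoint"}.
#' @param sweepAware re-date clone edges into the progressive window;
#'   default TRUE.
#' @param cloneMinMut minimum shared mutations for a clone edge; default 5.
#' @param includeHomoplastic date homoplastic mutations too (default);
#'   otherwise their age is NA.
#' @param threshold presence threshold; default 0.01.
#' @return \link[S4Vectors]{DataFrame} per mutation: \code{mutation_id},
#'   \code{edge}, \code{terminal}, \code{homoplasy}, \code{clone_edge},
#'   \code{age} (years before observation). Attribute \code{edgeTimes}
#'   holds the per-edge spans.
#' @export
calibrateClock <- function(tree, mut, neutralIds, assign = NULL,
                           T_total = 30, progressiveWindow = 5,
                           pseudo = 0.5, placement = c("quantile",
                                                       "midpoint"),
                           sweepAware = TRUE, cloneMinMut = 5,
                           includeHomoplastic = TRUE, threshold = 0.01) {
    placement <- match.arg(placement)
    if (!length(neutralIds)) stop("neutralIds must be non-empty")
    chars <- characterMatrix(mut, threshold)
    if (is.null(assign)) assign <- assignEdges(tree, chars)
    ed <- tree$edge
    if (nrow(ed) < 2) stop("degenerate tree")
    neut <- assign[assign$mutation_id %in% neutralIds, , drop = FALSE]
    cnt <- tabulate(neut$edge[neut$edge > 0], nbins = nrow(ed))
    rawLen <- cnt + pseudo
    t <- nodeTimes(tree, rawLen, T_total)
    idx <- pmax(assign$edge, 1L)
    lo <- ifelse(assign$edge > 0, t[ed[idx, 1]], 0)
    hi <- ifelse(assign$edge > 0, t[ed[idx, 2]], 0)
    ## private (terminal-edge) mutations arise along the field's whole
    ## lineage, root to observation: date them over the full (0, T) span
    lo[assign$terminal] <- 0

    v <- vafMatrix(mut)[assign$mutation_id, , drop = FALSE]
    vafTot <- rowSums(v)
    pos <- numeric(nrow(assign))
    for (e in unique(assign$edge)) {
        k <- which(assign$edge == e)
        if (placement == "midpoint") {
            pos[k] <- (lo[k] + hi[k]) / 2
        } else {
            ## VAF-descending: highest VAF earliest on the edge
            ord <- k[order(-vafTot[k])]
            q <- (seq_along(ord) - 0.5) / length(ord)
            pos[ord] <- lo[ord] + q * (hi[ord] - lo[ord])
        }
    }
    age <- T_total - pos
    cloneEdge <- rep(FALSE, nrow(assign))

    if (sweepAware) {
        nMutPerEdge <- table(assign$edge)
        isClone <- !assign$terminal &
            assign$edge %in%
                as.integer(names(nMutPerEdge)[nMutPerEdge >= cloneMinMut])
        cloneEdge <- isClone
        if (any(isClone)) {
            medv <- medianPresentVaf(v, threshold)
            edges <- unique(assign$edge[isClone])
            emed <- vapply(edges, function(e)
                stats::median(medv[assign$edge == e & isClone]),
                numeric(1))
            ecnt <- vapply(edges, function(e)
                sum(assign$edge == e & isClone), numeric(1))
            ## latest clone = highest VAF; partition the window by counts
            ord <- order(-emed)
            bounds <- c(0, cumsum(ecnt[ord])) / sum(ecnt) *
                progressiveWindow
            for (i in seq_along(ord)) {
                k <- which(assign$edge == edges[ord[i]] & isClone)
                ## within a clone, higher VAF dates older (upper bound)
                o <- k[order(vafTot[k])]
                q <- (seq_along(o) - 0.5) / length(o)
                age[o] <- bounds[i] + q * (bounds[i + 1] - bounds[i])
            }
        }
    }
    if (!includeHomoplastic) age[assign$homoplasy] <- NA_real_
    out <- DataFrame(mutation_id = assign$mutation_id,
                     edge = assign$edge, terminal = assign$terminal,
                     homoplasy = assign$homoplasy,
                     clone_edge = cloneEdge, age = age)
    rownames(out) <- assign$mutation_id
    et <- data.frame(edge = seq_len(nrow(ed)),
                     t_lo = t[ed[, 1]], t_hi = t[ed[, 2]],
                     raw_len = rawLen)
    attr(out, "edgeTimes") <- et
    out
}

#' Mutant cell mass from per-field VAFs
#'
#' m = sum over fields of 2 * VAF * cells-per-field (heterozygous
#' variants: cell fraction is twice the allele fraction).
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param nCellsField cells per mucosal field; default 1e6.
#' @return numeric vector of cell masses (floored at 1).
#' @export
mutantCellMass <- function(mut, nCellsField = 1e6) {
    pmax(2 * rowSums(vafMatrix(mut)) * nCellsField, 1)
}

#' Selection coefficient by exponential-growth inversion
#'
#' Inverts m = exp(r0 (1 + s) a): s = max(0, ln(m) / (r0 * a) - 1).
#' Ages below \code{ageFloor} are clamped for the inversion only; the
#' growth inversion diverges as a -> 0 and the floor regularizes very
#' young variants.
#'
#' @param mass mutant cell mass (>= 1).
#' @param age age in years before observation (> 0).
#' @param r0 baseline net growth rate per year; default 1.
#' @param ageFloor clamp (years) for the inversion; default 1.
#' @return numeric vector of selection coefficients (>= 0).
#' @export
#' @examples
#' selectionCoefficient(exp(5), 5)       # neutral growth: 0
#' selectionCoefficient(exp(10), 5)      # twice the neutral rate: 1
selectionCoefficient <- function(mass, age, r0 = 1, ageFloor = 1) {
    if (any(is.na(age)) || any(age <= 0))
        stop("ages must be positive")
    if (any(mass < 1)) stop("mass must be >= 1")
    pmax(0, log(mass) / (r0 * pmax(age, ageFloor)) - 1)
}

#' Dormant/progressive change-point of the mutation arrival process
#'
#' Models mutation origination times as a Poisson process with one rate
#' change; the change-point maximizes the two-rate log-likelihood over
#' candidate cuts at observed times. Significance is Monte-Carlo
#' calibrated against constant-rate histories of the same size (a raw
#' chi-square cut is anti-conservative for a scan maximized over cuts).
#'
#' @param ages numeric vector of mutation ages (years before observation);
#'   at least 20.
#' @param T_total history span; default 30.
#' @param minFrac minimum fraction of events on each side of the cut
#'   (guards against spurious boundary cuts); default 0.05.
#' @param nullSims Monte-Carlo null replicates for the p-value; default
#'   199 (0 skips calibration).
#' @param seed integer seed for the calibration.
#' @return list: \code{changepoint} (forward time of the rate change),
#'   \code{changepointAge} (T_total - changepoint), \code{dormantRate},
#'   \code{progressiveRate} (events/year), \code{llGain}, \code{p},
#'   \code{significant} (p < 0.05), \code{n}.
#' @export
phaseChangepoint <- function(ages, T_total = 30, minFrac = 0.05,
                             nullSims = 199, seed = 1) {
    ages <- ages[!is.na(ages)]
    if (length(ages) < 20)
        stop("need at least 20 ages for change-point estimation")
    scan <- function(tt) {
        tt <- sort(pmin(pmax(tt, 1e-9), T_total - 1e-9))
        n <- length(tt)
        i <- seq_len(n - 1)
        cut <- tt[i]
        ok <- cut > 0 & cut < T_total &
            i >= minFrac * n & (n - i) >= minFrac * n
        n1 <- i[ok]; cut <- cut[ok]
        n2 <- n - n1
        ll <- n1 * log(n1 / cut) + n2 * log(n2 / (T_total - cut)) - n
        ll0 <- n * log(n / T_total) - n
        best <- which.max(ll)
        list(cut = cut[best], n1 = n1[best], n2 = n2[best],
             gain = ll[best] - ll0)
    }
    tObs <- T_total - ages
    obs <- scan(tObs)
    n <- length(tObs)
    p <- NA_real_
    if (nullSims > 0) {
        p <- withSeed(seed, {
            gains <- vapply(seq_len(nullSims), function(i)
                scan(stats::runif(n, 0, T_total))$gain, numeric(1))
            (1 + sum(gains >= obs$gain)) / (nullSims + 1)
        })
    }
    list(changepoint = obs$cut, changepointAge = T_total - obs$cut,
         dormantRate = obs$n1 / obs$cut,
         progressiveRate = obs$n2 / (T_total - obs$cut),
         llGain = obs$gain, p = p,
         significant = !is.na(p) && p < 0.05, n = n)
}

#' Full clone timeline for a mutation table
#'
#' Convenience wrapper: builds (or takes) the parsimony tree, roots it at
#' the all-zero ancestor, assigns mutations to edges, calibrates the
#' clock (alpha-class mutations as the neutral set), inverts growth for
#' selection coefficients, and partitions history into dormant and
#' progressive phases.
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param assignment optional result of \code{\link{classifyMutations}}.
#' @param tree optional unrooted \code{phylo}; built by
#'   \code{\link{searchTree}} when NULL.
#' @param T_total,progressiveWindow,r0 model calibration inputs.
#' @param nCellsField cells per field; default 1e6.
#' @param threshold presence threshold; default 0.01.
#' @param restarts tree-search restarts when the tree is built here.
#' @param seed integer seed.
#' @param ... passed to \code{\link{calibrateClock}}.
#' @return list: \code{timeline} (DataFrame per mutation: edge, age,
#'   mass, selection, phase, ...), \code{partition} (from
#'   \code{\link{phaseChangepoint}}), \code{tree} (rooted).
#' @export
buildCloneTimeline <- function(mut, assignment = NULL, tree = NULL,
                               T_total = 30, progressiveWindow = 5,
                               r0 = 1, nCellsField = 1e6,
                               threshold = 0.01, restarts = 3, seed = 1,
                               ...) {
    if (is.null(assignment))
        assignment <- classifyMutations(mut, threshold = threshold)
    chars <- characterMatrix(mut, threshold)
    if (is.null(tree))  # pure descent: plateau walking is for small trees
        tree <- searchTree(chars, restarts = restarts, seed = seed,
                           plateau = 0L)
    rooted <- rootOrganTree(tree, chars)
    neutralIds <- assignment$mutation_id[
        assignment$greek_class == "alpha"]
    clock <- calibrateClock(rooted, mut, neutralIds = neutralIds,
                            T_total = T_total,
                            progressiveWindow = progressiveWindow,
                            threshold = threshold, ...)
    mass <- mutantCellMass(mut, nCellsField)[clock$mutation_id]
    sel <- selectionCoefficient(mass, clock$age, r0 = r0)
    part <- phaseChangepoint(clock$age, T_total = T_total, seed = seed)
    phase <- ifelse(clock$age <= part$changepointAge, "progressive",
                    "dormant")
    tl <- clock
    tl$mass <- mass
    tl$selection <- sel
    tl$phase <- phase
    tl$greek_class <- assignment[tl$mutation_id, "greek_class"]
    list(timeline = tl, partition = part, tree = rooted)
}
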