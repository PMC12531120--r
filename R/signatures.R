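## 96-context spectra, non-negative least-squares refitting against a
## reference catalog, bootstrap significance, and substitution-class
## comparisons between sample groups.

#' Trinucleotide context spectrum of a mutation subset
#'
#' Counts SNVs over the 96 canonical contexts; insertions and deletions
#' are ignored.
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param subset mutation ids (default: all).
#' @param label grouping label stored on the result.
#' @return named integer vector of length 96 (canonical order) with
#'   attribute \code{label}.
#' @export
contextSpectrum <- function(mut, subset = rownames(mut), label = "all") {
    if (!length(subset)) stop("empty mutation subset")
    bad <- setdiff(subset, rownames(mut))
    if (length(bad))
        stop("unknown mutation id(s): ", paste(utils::head(bad, 3),
                                               collapse = ", "))
    info <- mutationInfo(mut)[subset, , drop = FALSE]
    ctx <- info$context[info$mtype == "SNV"]
    if (!length(ctx))
        stop("subset contains no SNVs")
    counts <- table(factor(ctx, levels = contexts96()))
    out <- as.integer(counts)
    names(out) <- contexts96()
    attr(out, "label") <- label
    out
}

#' Refit a spectrum against a reference signature catalog
#'
#' Solves the non-negative least-squares problem catalog %*% w ~ spectrum
#' (spectrum normalized to sum 1), then renormalizes the weights to sum 1.
#'
#' @param spectrum numeric vector of length 96 (counts or proportions).
#' @param catalog a \linkS4class{SignatureCatalog}.
#' @return list with \code{weights} (named, non-negative, sum 1),
#'   \code{residual} (Euclidean norm of the fit residual).
#' @export
fitSignatureWeights <- function(spectrum, catalog) {
    m <- signatureMatrix(catalog)
    if (length(spectrum) != nrow(m))
        stop("spectrum length ", length(spectrum),
             " does not match the 96-context catalog")
    tot <- sum(spectrum)
    if (tot <= 0) stop("spectrum total must be positive")
    target <- as.numeric(spectrum) / tot
    fit <- pracma::lsqnonneg(m, target)
    w <- fit$x
    if (sum(w) == 0) w <- rep(1 / ncol(m), ncol(m)) else w <- w / sum(w)
    names(w) <- colnames(m)
    list(weights = w,
         residual = sqrt(sum((m %*% fit$x - target)^2)))
}

#' Bootstrap significance of signature weights
#'
#' Resamples the SNV subset with replacement \code{B} times, refits, and
#' reports for each signature the fraction of replicates in which its
#' weight effectively vanishes (at or below \code{wMin}). Signatures with
#' p below \code{pCut} are flagged significant.
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param catalog a \linkS4class{SignatureCatalog}.
#' @param subset mutation ids (default all).
#' @param B bootstrap replicates; at least 100 (p resolution for the
#'   0.005 cut); default 1000.
#' @param wMin vanishing-weight threshold; default 0.01.
#' @param pCut significance cut; default 0.005.
#' @param seed integer seed.
#' @return \link[S4Vectors]{DataFrame} per signature: \code{weight}
#'   (point fit), \code{p}, \code{significant}.
#' @export
bootstrapSignatures <- function(mut, catalog, subset = rownames(mut),
                                B = 1000, wMin = 0.01, pCut = 0.005,
                                seed = 1) {
    if (B < 100)
        stop("B must be at least 100 for p resolution at the 0.005 cut")
    info <- mutationInfo(mut)[subset, , drop = FALSE]
    ids <- subset[info$mtype == "SNV"]
    if (length(ids) < 50)
        warning("fewer than 50 SNVs; bootstrap p-values are unstable")
    point <- fitSignatureWeights(contextSpectrum(mut, ids), catalog)
    withSeed(seed, {
        K <- ncol(signatureMatrix(catalog))
        vanish <- numeric(K)
        ctx <- mutationInfo(mut)[ids, "context"]
        for (b in seq_len(B)) {
            res <- sample(ctx, length(ctx), replace = TRUE)
            spec <- as.integer(table(factor(res, levels = contexts96())))
            w <- fitSignatureWeights(spec, catalog)$weights
            vanish <- vanish + (w <= wMin)
        }
        p <- vanish / B
        out <- DataFrame(signature = names(point$weights),
                         weight = unname(point$weights), p = p,
                         significant = p < pCut)
        rownames(out) <- out$signature
        out
    })
}

#' Compare six-class substitution frequencies between groups
#'
#' For each field (map sample) and grouping level, computes the fraction
#' of its present SNVs in each of the six pyrimidine-normalized
#' substitution classes, then compares every class between each pair of
#' groups with the Wilcoxon rank-sum test (mid-ranks; exact when sample
#' sizes permit) and adjusts with Benjamini-Hochberg across the six
#' classes within each pair.
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param grouping either \code{"group"} (histology NU_LGIN/HGIN/UC) or a
#'   named vector mapping mutation ids to classes (e.g. greek classes or
#'   dormant/progressive phases); in the latter case the per-field
#'   fractions are computed within each mutation class.
#' @param threshold presence threshold; default 0.01.
#' @return list with \code{fractions} (per sample-by-class six-class
#'   fractions, long DataFrame) and \code{tests} (per pair and class:
#'   p and BH q). Pairs where a group has fewer than 2 samples are
#'   skipped with a warning.
#' @export
substitutionClassComparison <- function(mut, grouping = "group",
                                        threshold = 0.01) {
    v <- vafMatrix(mut)
    info <- mutationInfo(mut)
    snv <- info$mtype == "SNV"
    pres <- v >= threshold
    fm <- mutFieldMap(mut)
    groups <- fieldGroups(fm)

    fracRows <- list()
    if (identical(grouping, "group")) {
        for (f in colnames(v)) {
            sel <- snv & pres[, f]
            if (!any(sel)) next
            tab <- prop.table(table(factor(info$substitution[sel],
                                           SUB_CLASSES)))
            fracRows[[f]] <- data.frame(sample = f, class = groups[[f]],
                                        substitution = SUB_CLASSES,
                                        fraction = as.numeric(tab))
        }
    } else {
        lv <- unique(grouping[!is.na(grouping)])
        for (cl in lv) {
            members <- names(grouping)[which(grouping == cl)]
            rows <- rownames(mut) %in% members & snv
            for (f in colnames(v)) {
                sel <- rows & pres[, f]
                if (!any(sel)) next
                tab <- prop.table(table(factor(info$substitution[sel],
                                               SUB_CLASSES)))
                fracRows[[paste(f, cl)]] <-
                    data.frame(sample = f, class = cl,
                               substitution = SUB_CLASSES,
                               fraction = as.numeric(tab))
            }
        }
    }
    fr <- do.call(rbind, fracRows)
    lv <- unique(fr$class)
    if (length(lv) < 2) stop("need at least 2 groups to compare")
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    tests <- list()
    for (pr in pairs) {
        res <- lapply(SUB_CLASSES, function(s) {
            x <- fr$fraction[fr$class == pr[1] & fr$substitution == s]
            y <- fr$fraction[fr$class == pr[2] & fr$substitution == s]
            if (length(x) < 2 || length(y) < 2) return(NULL)
            p <- if (length(unique(c(x, y))) == 1) 1  # all tied
            else suppressWarnings(stats::wilcox.test(x, y)$p.value)
            data.frame(group1 = pr[1], group2 = pr[2], substitution = s,
                       p = p)
        })
        res <- do.call(rbind, res)
        if (is.null(res)) {
            warning("comparison ", pr[1], " vs ", pr[2],
                    " skipped: a group has fewer than 2 samples")
            next
        }
        res$q <- bhFdr(res$p)
        tests[[paste(pr, collapse = "_vs_")]] <- res
    }
    list(fractions = DataFrame(fr),
         tests = DataFrame(do.call(rbind, tests)))
}
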