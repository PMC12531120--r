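## Spatial classification of mutations by spread and VAF (alpha/beta/gamma),
## VAF-distribution shape diagnostics, and the group-distribution statistics.

#' Spread class from a presence vector
#'
#' Bins a mutation by the number of fields in which it is present:
#' private (1), regional (2-10 or 11-20), widespread (21-30 or >30).
#'
#' @param presence logical vector over fields (VAF at or above the
#'   presence threshold), or a logical matrix (mutations x fields).
#' @return character vector of spread classes.
#' @export
#' @examples
#' spreadClass(c(TRUE, rep(FALSE, 36)))
spreadClass <- function(presence) {
    n <- if (is.matrix(presence)) rowSums(presence) else sum(presence)
    if (any(n == 0))
        stop("mutation absent from every field")
    cut(n, c(0, 1, 10, 20, 30, Inf), labels = SPREAD_LEVELS,
        right = TRUE) |> as.character()
}

#' Greek class (alpha/beta/gamma) from per-field VAFs
#'
#' alpha if present in fewer than \code{minClusterFields} fields;
#' otherwise beta when the median VAF over present fields is below
#' \code{clonalVaf}, else gamma.
#'
#' @param vafs numeric vector of per-field VAFs, or a matrix (mutations x
#'   fields).
#' @param minClusterFields minimum fields for the clustered (beta/gamma)
#'   classes; default 3.
#' @param clonalVaf clonal VAF threshold; default 0.20.
#' @param threshold presence threshold; default 0.01.
#' @return character vector of greek classes.
#' @export
#' @examples
#' assignGreek(c(0.05, rep(0, 36)))
assignGreek <- function(vafs, minClusterFields = 3, clonalVaf = 0.20,
                        threshold = 0.01) {
    if (!is.matrix(vafs)) vafs <- matrix(vafs, nrow = 1)
    pres <- vafs >= threshold
    n <- rowSums(pres)
    if (any(n == 0)) stop("mutation absent from every field")
    med <- medianPresentVaf(vafs, threshold)
    ifelse(n < minClusterFields, "alpha",
           ifelse(med < clonalVaf, "beta", "gamma"))
}

medianPresentVaf <- function(vafs, threshold = 0.01) {
    pres <- vafs >= threshold
    n <- rowSums(pres)
    med <- rep(NA_real_, nrow(vafs))
    one <- which(n == 1)  # fast path: private mutations dominate
    if (length(one))
        med[one] <- vafs[cbind(one, max.col(vafs[one, , drop = FALSE]))]
    rest <- which(n > 1)
    med[rest] <- vapply(rest, function(i)
        stats::median(vafs[i, pres[i, ]]), numeric(1))
    med
}

sampleSkewness <- function(x) {
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) return(0)
    mean((x - m)^3) / s^3
}

#' Shape of a VAF distribution
#'
#' Classifies a collection of VAFs as \code{right_skewed} (the cumulative
#' count M(f) of variants above frequency f is linear in 1/f, the neutral
#' expectation, with positive skew), \code{binomial_clonal} (a single mode
#' in [0.15, 0.5] with dispersion consistent with binomial sampling at the
#' sequencing depth), \code{uniform} (Kolmogorov-Smirnov against
#' Uniform(min, max)), else \code{indeterminate}. Fewer than \code{nMin}
#' values is always indeterminate.
#'
#' @param vafs numeric vector of VAFs (present fields only).
#' @param nMin minimum number of values; default 8.
#' @param depth sequencing depth used for the binomial dispersion check;
#'   default 300.
#' @param r2Min minimum R-squared for the 1/f linearity; default 0.9.
#' @param skewMin minimum sample skewness for the right-skew call; default
#'   0.5 (a 0 cutoff fires on symmetric samples half the time).
#' @param modeRange VAF window for the clonal mode; default c(0.15, 0.5).
#' @return one of \code{"right_skewed"}, \code{"binomial_clonal"},
#'   \code{"uniform"}, \code{"indeterminate"}.
#' @export
vafShape <- function(vafs, nMin = 8, depth = 300, r2Min = 0.9,
                     skewMin = 0.5, modeRange = c(0.15, 0.5)) {
    vafs <- vafs[!is.na(vafs)]
    if (length(vafs) < nMin || stats::sd(vafs) == 0)
        return("indeterminate")
    v <- sort(unique(vafs))
    M <- vapply(v, function(f) sum(vafs >= f), numeric(1))
    fit <- stats::lm(M ~ I(1 / v))
    r2 <- summary(fit)$r.squared
    if (r2 >= r2Min && sampleSkewness(vafs) > skewMin)
        return("right_skewed")
    dens <- stats::density(vafs)
    mode <- dens$x[which.max(dens$y)]
    m <- mean(vafs)
    binomSd <- sqrt(m * (1 - m) / depth)
    if (mode >= modeRange[1] && mode <= modeRange[2] &&
        stats::sd(vafs) <= 2 * binomSd)
        return("binomial_clonal")
    ks <- suppressWarnings(
        stats::ks.test(vafs, "punif", min(vafs), max(vafs)))
    if (ks$p.value > 0.05) return("uniform")
    "indeterminate"
}

#' Exact test for equal distribution over the three histology groups
#'
#' Fisher's exact test on a 2 x 3 table of presence counts over
#' NU_LGIN/HGIN/UC. Exact (full conditional enumeration) when the table
#' total is at most \code{exactMax}; otherwise a seeded Monte Carlo
#' p-value with \code{B} draws.
#'
#' @param tab non-negative integer 2 x 3 matrix.
#' @param exactMax largest total for the exact path; default 500.
#' @param B Monte Carlo draws; default 1e5.
#' @param seed seed for the Monte Carlo path.
#' @return the p-value.
#' @export
#' @examples
#' groupDistributionTest(rbind(c(5, 5, 5), c(5, 5, 5)))
groupDistributionTest <- function(tab, exactMax = 500, B = 1e5,
                                  seed = 1) {
    tab <- as.matrix(tab)
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be non-negative integers")
    if (sum(tab) <= exactMax)
        stats::fisher.test(tab)$p.value
    else
        withSeed(seed,
                 stats::fisher.test(tab, simulate.p.value = TRUE,
                                    B = B)$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_i = min over ranks j >= rank(i) of
#' m * p_(j) / j.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))
bhFdr <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Classify every mutation in a table
#'
#' Runs \code{\link{spreadClass}}, \code{\link{assignGreek}} and
#' \code{\link{vafShape}} over a \linkS4class{MutationTable} and adds the
#' per-group presence counts.
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param threshold presence threshold; default 0.01.
#' @param minClusterFields,clonalVaf see \code{\link{assignGreek}}.
#' @param drivers optional character vector of driver genes (or
#'   \code{gene:context} variants) to flag.
#' @param byVariant if TRUE, match drivers on exact variants
#'   (\code{gene|context}) instead of genes.
#' @return a \link[S4Vectors]{DataFrame}, one row per mutation: columns
#'   \code{n_fields_present}, \code{spread_class}, \code{greek_class},
#'   \code{median_present_vaf}, \code{shape}, \code{cosmic_driver}, and
#'   presence counts per group.
#' @export
classifyMutations <- function(mut, threshold = 0.01, minClusterFields = 3,
                              clonalVaf = 0.20, drivers = character(),
                              byVariant = FALSE) {
    v <- vafMatrix(mut)
    pres <- v >= threshold
    n <- rowSums(pres)
    if (any(n == 0))
        stop(sum(n == 0), " mutation(s) absent from every field")
    groups <- fieldGroups(mutFieldMap(mut))
    presByGroup <- vapply(GROUP_LEVELS, function(g)
        rowSums(pres[, groups == g, drop = FALSE]), numeric(nrow(v)))
    shapes <- vapply(seq_len(nrow(v)), function(i) {
        x <- v[i, pres[i, ]]
        vafShape(x)
    }, character(1))
    key <- if (byVariant)
        paste(mutationInfo(mut)$gene, mutationInfo(mut)$context, sep = "|")
    else mutationInfo(mut)$gene
    out <- DataFrame(
        mutation_id = rownames(mut),
        n_fields_present = n,
        spread_class = spreadClass(pres),
        greek_class = assignGreek(v, minClusterFields, clonalVaf,
                                  threshold),
        median_present_vaf = medianPresentVaf(v, threshold),
        shape = shapes,
        cosmic_driver = key %in% drivers)
    out <- cbind(out, DataFrame(presByGroup))
    rownames(out) <- rownames(mut)
    out
}

mutFieldMap <- function(mut) {
    cd <- as.data.frame(colData(mut))
    FieldMap(cd$field_id, cd$row, cd$col, cd$grade)
}

#' Fraction of driver-flagged mutations per greek class
#'
#' @param assignment output of \code{\link{classifyMutations}} (needs
#'   \code{greek_class} and \code{cosmic_driver}), or any data.frame-like
#'   with those columns.
#' @return named numeric vector over alpha, beta, gamma.
#' @export
driverProportions <- function(assignment) {
    if (nrow(assignment) == 0) stop("empty assignment")
    vapply(GREEK_LEVELS, function(g) {
        k <- assignment$greek_class == g
        if (!any(k)) return(NA_real_)
        mean(assignment$cosmic_driver[k])
    }, numeric(1))
}
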