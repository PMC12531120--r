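## Synthetic whole-organ generator. Emulates the structure of a mapped
## cystectomy: a histology grid, private neutral alpha mutations, regional
## low-VAF beta clones, one widespread high-VAF gamma clone, class-specific
## context spectra, and omics layers with monotone stage effects.

withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

#' Plant a histologic map on a rectangular grid
#'
#' Places one contiguous carcinoma (UC) block in the grid interior, an HGIN
#' ring of the given width around it, a single ring of LGIN beyond that,
#' and NU elsewhere.
#'
#' @param nrow,ncol grid dimensions.
#' @param uc integer pair, the UC block dimensions (rows, cols); NULL for
#'   no focus (all NU).
#' @param ring HGIN ring width in fields (0 for none).
#' @return a \linkS4class{FieldMap}, fields in row-major order.
#' @export
#' @examples
#' table(fieldGrades(plantHistology(5, 8, uc = c(2, 2), ring = 1)))
plantHistology <- function(nrow, ncol, uc = c(3, 4), ring = 1) {
    if (nrow < 1 || ncol < 1) stop("grid dimensions must be positive")
    grid <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))
    grid <- grid[order(grid$row, grid$col), ]
    grade <- rep("NU", nrow * ncol)
    if (!is.null(uc)) {
        if (uc[1] + 2 * ring > nrow || uc[2] + 2 * ring > ncol)
            stop("UC focus plus ring does not fit the grid")
        r0 <- ring + 1L
        c0 <- ring + 1L
        ucRows <- r0:(r0 + uc[1] - 1L)
        ucCols <- c0:(c0 + uc[2] - 1L)
        ## Chebyshev distance to the UC block decides the rings
        dr <- pmax(ucRows[1] - grid$row, grid$row - ucRows[length(ucRows)], 0)
        dc <- pmax(ucCols[1] - grid$col, grid$col - ucCols[length(ucCols)], 0)
        d <- pmax(dr, dc)
        grade[d == 0] <- "UC"
        if (ring > 0) grade[d > 0 & d <= ring] <- "HGIN"
        grade[d == ring + 1] <- "LGIN"
    }
    FieldMap(sprintf("F%02d", seq_len(nrow * ncol)),
             row = grid$row, col = grid$col, grade = grade)
}

#' Default synthetic 96-context signature catalog
#'
#' A deterministic five-signature catalog used by the generator and the
#' examples. The signatures are synthetic stand-ins shaped like the
#' dominant processes reported for urothelium: S1 concentrates C>T at
#' NpCpG (clock-like deamination), S6 spreads C>T over non-CpG contexts
#' (mismatch-repair-like), S12 is T>C-heavy, S20 is C>A-heavy and S24
#' covers T>A/T>G; each has a 2% flat floor.
#'
#' @return a \linkS4class{SignatureCatalog} (96 x 5).
#' @export
defaultSignatureCatalog <- function() {
    ctx <- contexts96()
    sub <- parseSubstitution(ctx)
    third <- substr(ctx, 7, 7)
    peak <- function(sel) {  # small flat floor keeps signatures separable
        p <- rep(0.02 / 96, 96)
        p[sel] <- p[sel] + 0.98 / sum(sel)
        p
    }
    probs <- cbind(
        S1  = peak(sub == "C>T" & third == "G"),
        S6  = peak(sub == "C>T" & third != "G"),
        S12 = peak(sub == "T>C"),
        S20 = peak(sub == "C>A"),
        S24 = peak(sub %in% c("T>A", "T>G")))
    rownames(probs) <- ctx
    SignatureCatalog(probs)
}

#' Default marker gene sets for stage scores
#'
#' Reads the editable GMT shipped with the package: basal and luminal
#' urothelial markers, EMT up/down, OXPHOS, citric-acid cycle, glycolysis,
#' immune infiltration and T-cell exhaustion sets built around the named
#' markers of the field (KRT6A/KRT14/KRT16 basal; UPK3B, FOXA1, PAX8
#' luminal; LDHA glycolysis; ...). Membership is user-configurable by
#' editing or replacing the GMT.
#'
#' @return named list of character vectors.
#' @export
defaultScoreSets <- function() {
    readGmt(system.file("extdata", "score_sets.gmt",
                        package = "fieldcanceR", mustWork = TRUE))
}

#' Generator configuration for the synthetic organ
#'
#' Defaults reproduce the mapped-cystectomy study conditions: a 5 x 8 grid
#' (12 UC, 18 HGIN, 10 NU/LGIN fields), a 30-year history with a 5-year
#' progressive window and gamma arising in the last 2 years, 12,431 alpha
#' mutations (11,698 SNV / 448 INS / 285 DEL), 54 beta mutations over 3
#' clones, 324 gamma mutations in one widespread clone, 45 shared loci,
#' class-specific signature mixtures (beta/gamma enriched for S1), and
#' omics layers with 30% monotone analytes at log2 effects (1, 2, 3) and
#' noise sigma 0.5.
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   \code{rna = list(nAnalytes = 200)}).
#' @return a named list of generator parameters.
#' @export
organConfig <- function(...) {
    cfg <- list(
        gridRows = 5L, gridCols = 8L, uc = c(3L, 4L), ring = 1L,
        T_total = 30, progressiveWindow = 5, gammaWindow = 2,
        r0 = 1, nCellsField = 1e6,
        nAlpha = 12431L, alphaTypes = c(SNV = 11698L, INS = 448L, DEL = 285L),
        alphaVafRange = c(0.01, 0.25),
        betaClones = 3L, betaTypes = c(SNV = 51L, INS = 1L, DEL = 2L),
        betaSpan = c(3L, 20L), betaVafRange = c(0.02, 0.18),
        gammaTypes = c(SNV = 315L, INS = 2L, DEL = 7L),
        gammaMinSpan = 21L, gammaVafMean = 0.35, gammaVafSd = 0.05,
        gammaVafRange = c(0.2, 0.5),
        lociShared = 45L, silentFrac = 0.25,
        presenceThreshold = 0.01,
        nGenes = 5000L, nDriverGenes = 50L,
        driverFrac = c(alpha = 0.02, beta = 0.15, gamma = 0.40),
        alphaMix = NULL,   # NULL = flat over catalog signatures
        betaMix = c(S1 = 0.5), gammaMix = c(S1 = 0.8),
        rna = list(nAnalytes = 2000L, monotoneFrac = 0.30, sigma = 0.5,
                   effects = c(1, 2, 3), waveFracs = c(wave1 = 0.3, wave2 = 0.1),
                   missingFrac = 0, nControls = 3L),
        protein = list(nAnalytes = 2000L, monotoneFrac = 0.30, sigma = 0.5,
                       effects = c(1, 2, 3),
                       waveFracs = c(wave1 = 0.3, wave2 = 0.1),
                       missingFrac = 0.10, nControls = 3L, nSharedRna = 500L),
        metabolite = list(nAnalytes = 91L, monotoneFrac = 0.30, sigma = 0.5,
                          effects = c(1, 2, 3),
                          waveFracs = c(wave1 = 0.3, wave2 = 0.1),
                          missingFrac = 0.05, nControls = 3L))
    ov <- list(...)
    for (i in seq_along(ov)) {     # duplicates apply in order, last wins
        nm <- names(ov)[i]
        if (is.list(ov[[i]]) && is.list(cfg[[nm]]))
            cfg[[nm]][names(ov[[i]])] <- ov[[i]]
        else cfg[[nm]] <- ov[[i]]
    }
    if (any(unlist(cfg[c("nAlpha", "betaClones", "lociShared")]) < 0) ||
        cfg$silentFrac < 0 || any(cfg$driverFrac < 0))
        stop("negative rates/counts in generator config")
    cfg
}

## neutral VAF law f(v) ~ 1/v^2 on [a, b]: inverse-CDF sampler; the
## cumulative count above frequency f is then linear in 1/f.
rNeutralVaf <- function(n, range) {
    a <- range[1]; b <- range[2]
    u <- stats::runif(n)
    1 / (1 / a - u * (1 / a - 1 / b))
}

rTruncNorm <- function(n, mean, sd, lo, hi) {
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## contiguous region of `size` fields grown by 4-neighborhood BFS
growRegion <- function(fieldMap, size, start = NULL) {
    co <- gridCoords(fieldMap)
    n <- nrow(co)
    if (size > n) stop("region larger than the grid")
    key <- paste(co$row, co$col)
    idx <- seq_len(n)
    if (is.null(start)) start <- sample(idx, 1)
    region <- start
    frontier <- start
    while (length(region) < size) {
        nb <- unique(unlist(lapply(frontier, function(i) {
            cand <- paste(c(co$row[i] + 1, co$row[i] - 1, co$row[i],
                            co$row[i]),
                          c(co$col[i], co$col[i], co$col[i] + 1,
                            co$col[i] - 1))
            idx[match(cand, key, nomatch = 0)]
        })))
        nb <- setdiff(nb, region)
        if (!length(nb)) break  # grid exhausted around the region
        take <- min(length(nb), size - length(region))
        add <- if (length(nb) == 1) nb else sample(nb, take)
        region <- c(region, add)
        frontier <- add
    }
    sort(region)
}

mixOver <- function(mix, sigs) {
    p <- rep(0, length(sigs)); names(p) <- sigs
    if (is.null(mix)) return(rep(1 / length(sigs), length(sigs)))
    p[names(mix)] <- mix
    rest <- setdiff(sigs, names(mix))
    p[rest] <- (1 - sum(mix)) / length(rest)
    p
}

sampleContexts <- function(n, mix, catalog) {
    m <- signatureMatrix(catalog)
    sig <- sample(colnames(m), n, replace = TRUE,
                  prob = mixOver(mix, colnames(m)))
    ctx <- character(n)
    for (s in unique(sig)) {
        k <- sig == s
        ctx[k] <- sample(rownames(m), sum(k), replace = TRUE, prob = m[, s])
    }
    list(context = ctx, signature = sig)
}

genOmicsLayer <- function(lcfg, fieldMap, markers = NULL, prefix = "GENE",
                          sharedIds = NULL, sharedDir = NULL) {
    nA <- lcfg$nAnalytes
    ids <- sprintf("%s%05d", prefix, seq_len(nA))
    dir <- rep(0L, nA)          # +1 up, -1 down, 0 null
    wave <- rep("none", nA)
    ## planted marker genes come first, with their biological direction
    if (!is.null(markers)) {
        if (nrow(markers) > nA)  # tiny layers keep what fits
            markers <- markers[seq_len(nA), , drop = FALSE]
        ids[seq_len(nrow(markers))] <- markers$gene
        dir[seq_len(nrow(markers))] <- markers$dir
        wave[seq_len(nrow(markers))] <- "wave1"
    }
    if (!is.null(sharedIds)) {
        free <- which(!(ids %in% sharedIds) & dir == 0)
        put <- setdiff(sharedIds, ids)
        ids[free[seq_along(put)]] <- put
        hit <- match(sharedIds, ids)
        dir[hit] <- sharedDir
        wave[hit][sharedDir != 0] <- "wave1"
    }
    nMono <- round(lcfg$monotoneFrac * nA)
    extra <- max(0, nMono - sum(dir != 0))
    pool <- which(dir == 0)
    pick <- pool[seq_len(min(extra, length(pool)))]
    dir[pick] <- rep_len(c(1L, -1L), length(pick))
    w <- sample(c("wave1", "wave2", "late"), length(pick), replace = TRUE,
                prob = c(lcfg$waveFracs["wave1"], lcfg$waveFracs["wave2"],
                         1 - sum(lcfg$waveFracs)))
    wave[pick] <- w
    wave[dir == 0] <- "none"
    ## stage-effect profiles (log2 units vs control) by wave of onset
    prof <- rbind(wave1 = lcfg$effects,
                  wave2 = c(0, lcfg$effects[2], lcfg$effects[3]),
                  late  = c(0.3 * lcfg$effects[1], 0.5 * lcfg$effects[2],
                            lcfg$effects[3]),
                  none  = c(0, 0, 0))
    groups <- fieldGroups(fieldMap)
    sampleIds <- c(names(groups), sprintf("CTRL%d", seq_len(lcfg$nControls)))
    role <- c(rep("map_field", length(groups)),
              rep("control", lcfg$nControls))
    base <- stats::rnorm(nA, 5, 2)
    eff <- prof[wave, , drop = FALSE] * dir
    colnames(eff) <- GROUP_LEVELS
    shift <- cbind(eff[, groups, drop = FALSE],
                   matrix(0, nA, lcfg$nControls))
    vals <- base + shift +
        matrix(stats::rnorm(nA * length(sampleIds), 0, lcfg$sigma),
               nA, length(sampleIds))
    if (lcfg$missingFrac > 0) {
        miss <- matrix(stats::runif(length(vals)) < lcfg$missingFrac,
                       nA, ncol(vals))
        ## keep controls complete so z-scoring stays defined
        miss[, role == "control"] <- FALSE
        vals[miss] <- NA
    }
    colnames(vals) <- sampleIds
    rownames(vals) <- ids
    om <- OmicsMatrix(vals, role = role, fieldMap = fieldMap)
    truth <- DataFrame(analyte_id = ids, monotone = dir != 0,
                       direction = c("down", "none", "up")[dir + 2L],
                       wave = wave,
                       e_NU_LGIN = eff[, 1], e_HGIN = eff[, 2],
                       e_UC = eff[, 3])
    rownames(truth) <- ids
    list(matrix = om, truth = truth)
}

#' Generate a synthetic whole-organ dataset with known truth
#'
#' Produces a field map, a mutation table (private alpha mutations with
#' neutral 1/v^2 VAFs, contiguous beta clones with low uniform VAFs, one
#' widespread high-VAF gamma clone covering all HGIN/UC fields), three
#' omics layers with monotone stage effects, and ground-truth tables
#' (per-mutation class, age, selection, clone, signature; per-analyte
#' direction and wave).
#'
#' Ages are years before observation: alpha ~ U(0, T), beta ~ U(2, 5),
#' gamma ~ U(0, 2) under the default two-phase history. True selection
#' coefficients for clonal (beta/gamma) mutations follow the exponential
#' growth closure s = ln(m)/(r0 * age) - 1 from the realized VAF mass m;
#' alpha mutations are neutral (s = 0).
#'
#' @param config list from \code{\link{organConfig}}.
#' @param seed integer seed; the same seed reproduces the dataset
#'   byte-identically.
#' @param catalog a \linkS4class{SignatureCatalog}; default
#'   \code{\link{defaultSignatureCatalog}()}.
#' @return a list with elements \code{fieldMap}, \code{mutations},
#'   \code{omics} (list rna/protein/metabolite), \code{catalog},
#'   \code{truth} (list mutations/rna/protein/metabolite), \code{config},
#'   \code{seed}.
#' @export
generateOrgan <- function(config = organConfig(), seed = 1,
                          catalog = defaultSignatureCatalog()) {
    withSeed(seed, {
        fm <- plantHistology(config$gridRows, config$gridCols,
                             uc = config$uc, ring = config$ring)
        nF <- length(fm)
        groups <- fieldGroups(fm)
        hginUc <- which(groups %in% c("HGIN", "UC"))
        if (length(hginUc) < config$gammaMinSpan && nF < 22)
            stop("gamma clone span below ", config$gammaMinSpan,
                 " is impossible on a grid of ", nF, " fields")

        nA <- config$nAlpha
        nB <- sum(config$betaTypes)
        nG <- sum(config$gammaTypes)
        nMut <- nA + nB + nG
        greek <- rep(GREEK_LEVELS, c(nA, nB, nG))

        ## --- spatial footprints and VAFs -------------------------------
        vaf <- matrix(0, nMut, nF, dimnames = list(NULL, fieldIds(fm)))
        aField <- sample.int(nF, nA, replace = TRUE)
        vaf[cbind(seq_len(nA), aField)] <-
            rNeutralVaf(nA, config$alphaVafRange)

        cloneId <- rep(NA_character_, nMut)
        cloneId[greek == "alpha"] <- sprintf("alpha_F%02d", aField)
        bSplit <- rep(seq_len(config$betaClones),
                      length.out = nB)  # mutations round-robin over clones
        bFoot <- lapply(seq_len(config$betaClones), function(i)
            growRegion(fm, sample(config$betaSpan[1]:config$betaSpan[2], 1)))
        for (i in seq_len(nB)) {
            rows <- nA + i
            foot <- bFoot[[bSplit[i]]]
            vaf[rows, foot] <- stats::runif(length(foot),
                                            config$betaVafRange[1],
                                            config$betaVafRange[2])
            cloneId[rows] <- sprintf("beta%d", bSplit[i])
        }
        gFoot <- hginUc
        if (length(gFoot) < config$gammaMinSpan) {
            extra <- setdiff(seq_len(nF), gFoot)
            gFoot <- sort(c(gFoot,
                            extra[seq_len(config$gammaMinSpan -
                                          length(gFoot))]))
        }
        gRows <- nA + nB + seq_len(nG)
        vaf[gRows, gFoot] <- rTruncNorm(nG * length(gFoot),
                                        config$gammaVafMean,
                                        config$gammaVafSd,
                                        config$gammaVafRange[1],
                                        config$gammaVafRange[2])
        cloneId[gRows] <- "gamma1"

        ## --- annotations ------------------------------------------------
        mtype <- c(sample(rep(MTYPE_LEVELS, config$alphaTypes)),
                   sample(rep(MTYPE_LEVELS, config$betaTypes)),
                   sample(rep(MTYPE_LEVELS, config$gammaTypes)))
        snv <- mtype == "SNV"
        context <- rep(NA_character_, nMut)
        signature <- rep(NA_character_, nMut)
        for (g in GREEK_LEVELS) {
            k <- snv & greek == g
            mix <- switch(g, alpha = config$alphaMix,
                          beta = config$betaMix, gamma = config$gammaMix)
            cs <- sampleContexts(sum(k), mix, catalog)
            context[k] <- cs$context
            signature[k] <- cs$signature
        }
        silent <- stats::runif(nMut) < config$silentFrac
        driverPool <- sprintf("DRV%03d", seq_len(config$nDriverGenes))
        genePool <- sprintf("GENE%05d", seq_len(config$nGenes))
        isDriver <- stats::runif(nMut) < config$driverFrac[greek]
        gene <- ifelse(isDriver,
                       sample(driverPool, nMut, replace = TRUE),
                       sample(genePool, nMut, replace = TRUE))
        ## loci: a configured number of locus collisions (two variant
        ## records at one genomic position)
        nLoci <- nMut - config$lociShared
        locus <- sprintf("L%05d", seq_len(nLoci))
        if (config$lociShared > 0) {
            dup <- sample(nLoci, config$lociShared)
            locus <- c(locus, locus[dup])
        }
        locus <- sample(locus)
        ids <- sprintf("M%05d", seq_len(nMut))
        rownames(vaf) <- ids
        info <- DataFrame(gene = gene, mtype = mtype,
                          substitution = parseSubstitution(context),
                          context = context, silent = silent, locus = locus)
        rownames(info) <- ids
        mut <- MutationTable(vaf, info, fm)

        ## --- ground-truth ages and selection ---------------------------
        Tt <- config$T_total
        W <- config$progressiveWindow
        Wg <- config$gammaWindow
        age <- numeric(nMut)
        age[greek == "alpha"] <- stats::runif(nA, 0, Tt)
        age[greek == "beta"] <- stats::runif(nB, Wg, W)
        age[greek == "gamma"] <- stats::runif(nG, 0, Wg)
        mass <- 2 * rowSums(vaf) * config$nCellsField
        sTrue <- ifelse(greek == "alpha", 0,
                        pmax(0, log(pmax(mass, 1)) /
                                 (config$r0 * pmax(age, 1e-9)) - 1))
        mutTruth <- DataFrame(mutation_id = ids, greek_class = greek,
                              true_age = age, true_selection = sTrue,
                              clone_id = cloneId, signature = signature,
                              driver = isDriver)
        rownames(mutTruth) <- ids

        ## --- omics layers ----------------------------------------------
        sets <- defaultScoreSets()
        markers <- rbind(
            data.frame(gene = unique(c(sets$BASAL_UP, sets$GLYCOLYSIS,
                                       sets$EMT_UP, sets$IMMUNE,
                                       sets$T_EXHAUSTION)), dir = 1L),
            data.frame(gene = unique(c(sets$LUMINAL, sets$OXPHOS, sets$TCA,
                                       sets$EMT_DOWN)), dir = -1L))
        markers <- markers[!duplicated(markers$gene), ]
        rna <- genOmicsLayer(config$rna, fm, markers = markers)
        shared <- rownames(rna$truth)[seq_len(
            min(config$protein$nSharedRna, config$rna$nAnalytes))]
        sharedDir <- c(down = -1L, none = 0L, up = 1L)[
            rna$truth[shared, "direction"]]
        protein <- genOmicsLayer(config$protein, fm, prefix = "PROT",
                                 sharedIds = shared, sharedDir = sharedDir)
        metab <- genOmicsLayer(config$metabolite, fm, prefix = "MET")

        list(fieldMap = fm, mutations = mut,
             omics = list(rna = rna$matrix, protein = protein$matrix,
                          metabolite = metab$matrix),
             catalog = catalog,
             truth = list(mutations = mutTruth, rna = rna$truth,
                          protein = protein$truth,
                          metabolite = metab$truth),
             config = config, seed = seed)
    })
}

#' Write synthetic supplementary-style tables at study scale
#'
#' Emits, into \code{dir}, synthetic stand-ins for the study's
#' supplementary tables: per-class mutation lists with per-field VAFs
#' (12,431 alpha / 54 beta / 324 gamma records over 12,764 loci), a
#' protein matrix with 8,475 analytes and a metabolite matrix with 91
#' analytes, plus the field map. File names are prefixed
#' \code{synthetic_}; the content is generated, not measured.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return invisibly, a named list of the file paths.
#' @export
syntheticSupplementaryTables <- function(dir, seed = 1) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    org <- generateOrgan(organConfig(
        rna = list(nAnalytes = 10L),          # not part of the bookkeeping
        protein = list(nAnalytes = 8475L, nSharedRna = 10L),
        metabolite = list(nAnalytes = 91L)), seed = seed)
    cls <- org$truth$mutations$greek_class
    paths <- list()
    paths$field_map <- file.path(dir, "synthetic_field_map.tsv")
    writeFieldMap(org$fieldMap, paths$field_map)
    for (g in GREEK_LEVELS) {
        p <- file.path(dir, sprintf("synthetic_%s_mutations.tsv", g))
        writeMutationTable(org$mutations[cls == g, ], p)
        paths[[paste0(g, "_mutations")]] <- p
    }
    paths$proteins <- file.path(dir, "synthetic_proteins.tsv")
    writeOmicsMatrix(org$omics$protein, paths$proteins)
    paths$metabolites <- file.path(dir, "synthetic_metabolites.tsv")
    writeOmicsMatrix(org$omics$metabolite, paths$metabolites)
    invisible(paths)
}
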