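## One-call orchestration: simulate (or read) -> classify -> signatures ->
## tree -> timeline -> omics, with a JSON run manifest for reproducibility.

logStage <- function(verbose, stage, ...) {
    if (verbose)
        message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                        stage, paste0(..., collapse = " ")))
}

#' Run the whole-organ analysis pipeline
#'
#' Stages: \code{simulate} (synthetic organ; otherwise mutation/field-map
#' TSVs are read from \code{inputs}), \code{classify}, \code{signatures},
#' \code{tree}, \code{timeline} (requires \code{tree}), \code{omics}.
#' Stage outputs are written to \code{outDir} as TSV/Newick plus a
#' \code{manifest.json} (parameters, seed, md5 checksums); a rerun with
#' the same config and seed reproduces identical outputs.
#'
#' @param outDir output directory.
#' @param seed integer seed used for every stochastic step.
#' @param config generator configuration (\code{\link{organConfig}}) when
#'   simulating.
#' @param inputs named list of paths (\code{fieldMap}, \code{mutations},
#'   optional \code{catalog}) used when \code{simulate} is FALSE.
#' @param stages character vector of stages to run.
#' @param thresholds named list: \code{presence} (0.01), \code{clonalVaf}
#'   (0.20), \code{minClusterFields} (3), \code{qCut} (0.05), \code{pSig}
#'   (0.005).
#' @param T_total,progressiveWindow,r0 timing calibration inputs.
#' @param restarts tree-search restarts; default 3.
#' @param B bootstrap replicates for signature significance; default 200.
#' @param verbose log stage progress to stderr; default TRUE.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
runOrganPipeline <- function(outDir, seed = 1, config = organConfig(),
                             inputs = list(),
                             stages = c("simulate", "classify",
                                        "signatures", "tree", "timeline",
                                        "omics"),
                             thresholds = list(),
                             T_total = 30, progressiveWindow = 5, r0 = 1,
                             restarts = 3, B = 200, verbose = TRUE) {
    th <- utils::modifyList(list(presence = 0.01, clonalVaf = 0.20,
                                 minClusterFields = 3, qCut = 0.05,
                                 pSig = 0.005), thresholds)
    stopifnot(th$presence > 0, th$presence < 1,
              th$clonalVaf > 0, th$clonalVaf < 1,
              th$minClusterFields >= 1, th$qCut > 0, th$qCut < 1,
              th$pSig > 0, th$pSig < 1)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    res <- list()
    out <- list()

    if ("simulate" %in% stages) {
        logStage(verbose, "simulate", "seed", seed)
        org <- generateOrgan(config, seed = seed)
        res$organ <- org
        out$field_map <- org$fieldMap
        out$mutations <- org$mutations
        out$truth_mutations <- org$truth$mutations
        catalog <- org$catalog
        fm <- org$fieldMap
        mut <- org$mutations
        omics <- org$omics
    } else {
        for (nm in c("fieldMap", "mutations"))
            if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]]))
                stop("simulation is off and input '", nm,
                     "' is missing: ",
                     if (is.null(inputs[[nm]])) "<unset>"
                     else inputs[[nm]])
        fm <- readFieldMap(inputs$fieldMap)
        mut <- readMutationTable(inputs$mutations, fm)
        catalog <- if (!is.null(inputs$catalog))
            readSignatureCatalog(inputs$catalog)
        else defaultSignatureCatalog()
        omics <- NULL
    }

    if ("classify" %in% stages) {
        logStage(verbose, "classify", nrow(mut), "mutations")
        res$assignment <- classifyMutations(
            mut, threshold = th$presence,
            minClusterFields = th$minClusterFields,
            clonalVaf = th$clonalVaf)
        out$class_assignment <- res$assignment
        summary <- as.data.frame(table(greek = res$assignment$greek_class,
                                       spread = res$assignment$spread_class))
        out$class_summary <- summary[summary$Freq > 0, ]
    }

    if ("signatures" %in% stages) {
        logStage(verbose, "signatures", "B =", B)
        res$signatures <- bootstrapSignatures(mut, catalog, B = B,
                                              pCut = th$pSig, seed = seed)
        out$signature_weights <- res$signatures
    }

    if ("tree" %in% stages) {
        logStage(verbose, "tree", "search with", restarts, "restarts")
        chars <- characterMatrix(mut, th$presence)
        res$tree <- searchTree(chars, restarts = restarts, seed = seed)
        res$branches <- branchClusters(res$tree, hammingMatrix(chars),
                                       k = 3)
        out$tree <- res$tree
        out$branch_clusters <- data.frame(field_id = names(res$branches),
                                          branch = unname(res$branches))
    }

    if ("timeline" %in% stages) {
        if (!"tree" %in% stages)
            stop("stage 'timeline' requires stage 'tree'")
        logStage(verbose, "timeline")
        res$timing <- buildCloneTimeline(
            mut, assignment = res$assignment, tree = res$tree,
            T_total = T_total, progressiveWindow = progressiveWindow,
            r0 = r0, threshold = th$presence, seed = seed)
        out$clone_timeline <- res$timing$timeline
        p <- res$timing$partition
        out$phase_partition <- data.frame(
            changepoint = p$changepoint, changepoint_age = p$changepointAge,
            dormant_rate = p$dormantRate,
            progressive_rate = p$progressiveRate,
            ll_gain = p$llGain, p = p$p)
    }

    if ("omics" %in% stages && !is.null(omics)) {
        res$omics <- list()
        for (layer in names(omics)) {
            logStage(verbose, "omics", layer)
            eff <- stageEffects(omics[[layer]])
            calls <- callMonotonic(eff, qCut = th$qCut)
            res$omics[[layer]] <- calls
            out[[paste0("monotonic_", layer)]] <- calls
        }
        sets <- defaultScoreSets()
        ## sign conventions: energy = oxidative metabolism (falls with
        ## progression); BLT < 0 = basal shift; EMT < 0 = EMT activation
        sc <- rbind(
            energy = signatureScore(omics$rna,
                                    upSet = c(sets$OXPHOS, sets$TCA),
                                    downSet = sets$GLYCOLYSIS),
            blt = signatureScore(omics$rna, upSet = sets$LUMINAL,
                                 downSet = sets$BASAL_UP),
            emt = signatureScore(omics$rna, upSet = sets$EMT_DOWN,
                                 downSet = sets$EMT_UP),
            immune = signatureScore(omics$rna, upSet = sets$IMMUNE),
            t_exhaustion = signatureScore(omics$rna,
                                          upSet = sets$T_EXHAUSTION))
        res$scores <- sc
        out$sample_scores <- data.frame(sample = colnames(sc), t(sc))
    }

    logStage(verbose, "write", outDir)
    res$manifest <- writeResults(
        outDir, out,
        params = c(th, list(T_total = T_total,
                            progressiveWindow = progressiveWindow,
                            r0 = r0, restarts = restarts, B = B,
                            stages = stages)),
        seed = seed)
    invisible(res)
}
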