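mkOmics <- function(effects, sigma = 0, nPerGroup = c(6, 6, 6),
                    nCtrl = 3, nAnalytes = nrow(effects), seed = 1) {
    ## effects: analytes x 3 matrix of group shifts (NU_LGIN, HGIN, UC)
    set.seed(seed)
    fm <- FieldMap(sprintf("F%02d", seq_len(sum(nPerGroup))),
                   row = rep(1:3, nPerGroup),
                   col = unlist(lapply(nPerGroup, seq_len)),
                   grade = rep(c("NU", "HGIN", "UC"), nPerGroup))
    groups <- fieldGroups(fm)
    shift <- effects[, match(groups, c("NU_LGIN", "HGIN", "UC")),
                     drop = FALSE]
    vals <- cbind(shift, matrix(0, nAnalytes, nCtrl)) +
        matrix(rnorm(nAnalytes * (length(groups) + nCtrl), 0, sigma),
               nAnalytes)
    colnames(vals) <- c(names(groups), paste0("CTRL", seq_len(nCtrl)))
    rownames(vals) <- sprintf("A%04d", seq_len(nAnalytes))
    OmicsMatrix(vals, role = c(rep("map_field", length(groups)),
                               rep("control", nCtrl)), fieldMap = fm)
}

test_that("stage effects are exact in the noiseless case", {
    eff <- rbind(c(2, 2, 2), c(0, 0, 0), c(-1, -2, -3))
    om <- mkOmics(eff, sigma = 0)
    se <- stageEffects(om)
    expect_equal(unname(se$e_NU_LGIN), eff[, 1])
    expect_equal(unname(se$e_UC), eff[, 3])
    ## flat analyte: all values tie with controls -> p ~ 1
    expect_gt(se$p_UC[2], 0.9)
})

test_that("monotone calling follows the ordered-effect rule and waves", {
    eff <- rbind(a = c(1, 2, 3),      # monotone up, wave 1
                 b = c(1, 2, 1.5),    # broken ordering
                 c = c(0.1, -2, -3),  # monotone down, wave 2
                 d = c(0, 0, 0))
    se <- S4Vectors::DataFrame(
        analyte_id = rownames(eff),
        e_NU_LGIN = eff[, 1], e_HGIN = eff[, 2], e_UC = eff[, 3],
        p_NU_LGIN = c(0.001, 0.5, 0.8, 0.9),
        p_HGIN = c(0.001, 0.5, 0.01, 0.9),
        p_UC = c(0.001, 0.01, 0.01, 0.9),
        q_NU_LGIN = c(0.01, 0.5, 0.8, 0.9),
        q_HGIN = c(0.01, 0.5, 0.04, 0.9),
        q_UC = c(0.01, 0.04, 0.04, 0.9))
    calls <- callMonotonic(se, qCut = 0.05, tau = 0)
    expect_identical(calls$direction, c("up", "none", "down", "none"))
    expect_identical(calls$wave, c(1L, NA, 2L, NA))
    ## idempotent and order-invariant
    calls2 <- callMonotonic(se[c(3, 1, 4, 2), ])
    expect_identical(calls2$direction, calls$direction[c(3, 1, 4, 2)])
})

test_that("noiseless planted monotone analytes are called perfectly", {
    org <- generateOrgan(smallOrganConfig(
        rna = list(nAnalytes = 400L, sigma = 0)), seed = 8)
    calls <- callMonotonic(stageEffects(org$omics$rna))
    truth <- org$truth$rna
    expect_identical(unname(calls$monotone), unname(truth$monotone))
    expect_identical(calls$direction[truth$monotone],
                     truth$direction[truth$monotone])
})

test_that("recall stays high at default noise", {
    rec <- prec <- numeric(3)
    for (i in 1:3) {
        org <- generateOrgan(smallOrganConfig(
            rna = list(nAnalytes = 500L)), seed = 100 + i)
        calls <- callMonotonic(stageEffects(org$omics$rna))
        truth <- org$truth$rna
        tp <- sum(calls$monotone & truth$monotone &
                  calls$direction == truth$direction)
        rec[i] <- tp / sum(truth$monotone)
        prec[i] <- tp / sum(calls$monotone)
    }
    expect_gte(mean(rec), 0.9)
    expect_gte(mean(prec), 0.9)
})

test_that("signature scores are zero at control baseline and scale in SD", {
    eff <- matrix(0, 10, 3)
    om <- mkOmics(eff, sigma = 0.5, seed = 4)
    m <- abundanceMatrix(om)
    ## a sample equal to the control means scores 0
    mu <- rowMeans(m[, sampleRoles(om) == "control"])
    m2 <- cbind(m, exactly_mu = mu)
    om2 <- OmicsMatrix(m2, role = c(sampleRoles(om), "map_field"),
                       group = c(sampleGroups(om), "UC"))
    sc <- signatureScore(om2, upSet = rownames(m2)[1:5])
    expect_equal(unname(sc[["exactly_mu"]]), 0)
    ## +1 SD on every up-set analyte scores 1
    sds <- apply(m[, sampleRoles(om) == "control"], 1, sd)
    m3 <- cbind(m, plus1 = mu + sds)
    om3 <- OmicsMatrix(m3, role = c(sampleRoles(om), "map_field"),
                       group = c(sampleGroups(om), "UC"))
    sc3 <- signatureScore(om3, upSet = rownames(m3)[1:5])
    expect_equal(unname(sc3[["plus1"]]), 1)
    expect_error(signatureScore(om3, upSet = "NOT_THERE"), "no set member")
})

test_that("planted OXPHOS loss drives the energy score down with stage", {
    org <- generateOrgan(smallOrganConfig(), seed = 77)
    sets <- defaultScoreSets()
    en <- signatureScore(org$omics$rna,
                         upSet = c(sets$OXPHOS, sets$TCA),
                         downSet = sets$GLYCOLYSIS)
    grp <- sampleGroups(org$omics$rna)
    mns <- tapply(en[!is.na(grp)], grp[!is.na(grp)], mean)
    expect_gt(mns[["NU_LGIN"]], mns[["HGIN"]])
    expect_gt(mns[["HGIN"]], mns[["UC"]])
    expect_lt(mns[["NU_LGIN"]], 0)  # field effect already below control
})

test_that("ssGSEA scores extremes, is rank-invariant and null-centered", {
    set.seed(12)
    v <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    top <- names(sort(v, decreasing = TRUE))[1:15]
    bottom <- names(sort(v))[1:15]
    expect_gt(ssgseaEs(v, top), 0)
    expect_lt(ssgseaEs(v, bottom), 0)
    ## invariance under strictly monotone transforms
    set.seed(13)
    gs <- sample(names(v), 20)
    expect_equal(ssgseaEs(v, gs), ssgseaEs(exp(v), gs))
    expect_equal(ssgseaEs(v, gs), ssgseaEs(rank(v), gs))
    expect_error(ssgseaEs(v, "absent"), "intersect")
    ## null calibration: mean ES of random sets near 0
    set.seed(14)
    es <- replicate(500, ssgseaEs(setNames(rnorm(100), names(v)[1:100]),
                                  sample(names(v)[1:100], 10)))
    expect_lt(abs(mean(es)), 0.025)
    expect_true(all(abs(es) <= 1))
})

test_that("hypergeometric enrichment matches the tail-sum oracle", {
    uni <- sprintf("g%04d", 1:1000)
    sets <- list(S = uni[1:50], T = uni[51:60])
    set.seed(15)
    hits <- sample(uni, 20)
    res <- pathwayEnrichment(hits, uni, sets)
    k <- length(intersect(hits, sets$S))
    expect_equal(res["S", "p"], hyperTailOracle(k, 50, 1000, 20),
                 tolerance = 1e-12)
    ## closed forms
    res2 <- pathwayEnrichment(uni[1:10], uni[1:100],
                              list(A = uni[1:10], B = uni[90:95]))
    expect_equal(res2["A", "p"], 1 / choose(100, 10), tolerance = 1e-12)
    expect_equal(res2["B", "p"], 1)
    expect_error(pathwayEnrichment(c("zzz"), uni, sets), "subset")
})

test_that("RNA/protein concordance recovers planted shared analytes", {
    org <- generateOrgan(smallOrganConfig(
        rna = list(nAnalytes = 300L, sigma = 0),
        protein = list(nAnalytes = 300L, sigma = 0, missingFrac = 0,
                       nSharedRna = 100L)), seed = 55)
    cr <- callMonotonic(stageEffects(org$omics$rna))
    cp <- callMonotonic(stageEffects(org$omics$protein))
    conc <- rnaProteinConcordance(cr, cp)
    shared <- intersect(cr$analyte_id, cp$analyte_id)
    planted <- sum(org$truth$rna[shared, "monotone"])
    expect_identical(nrow(conc), as.integer(planted))
    ## opposite directions never concordant
    cp2 <- cp
    cp2$direction <- ifelse(cp2$direction == "up", "down",
                            ifelse(cp2$direction == "down", "up", "none"))
    expect_identical(nrow(rnaProteinConcordance(cr, cp2)), 0L)
    expect_error(rnaProteinConcordance(cr[1:5, ], cp[200:210, ]),
                 "shared")
})
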