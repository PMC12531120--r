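test_that("context spectra count SNVs over the canonical 96 motifs", {
    mut <- tinyMutationTable()
    spec <- contextSpectrum(mut)
    expect_length(spec, 96)
    expect_identical(sum(spec), 2L)  # the DEL is ignored
    expect_identical(spec[["A[C>T]G"]], 1L)
    expect_error(contextSpectrum(mut, "m3"), "no SNVs")
    expect_error(contextSpectrum(mut, character(0)), "empty")

    fm <- tinyFieldMap()
    vaf <- matrix(0.1, 3, 4, dimnames = list(c("a", "b", "c"),
                                             fieldIds(fm)))
    info <- data.frame(gene = "G", mtype = "SNV", substitution = "C>T",
                       context = "A[C>T]A", silent = FALSE)
    mt <- MutationTable(vaf, info[rep(1, 3), ], fm)
    sp <- contextSpectrum(mt)
    expect_identical(sp[["A[C>T]A"]], 3L)
    expect_identical(sum(sp), 3L)
})

test_that("weight refitting is exact on pure and noiseless mixtures", {
    cat96 <- defaultSignatureCatalog()
    m <- signatureMatrix(cat96)
    w <- fitSignatureWeights(m[, "S6"], cat96)
    expect_equal(unname(w$weights),
                 as.numeric(colnames(m) == "S6"), tolerance = 1e-6)
    expect_lt(w$residual, 1e-9)

    mix <- 0.7 * m[, "S1"] + 0.3 * m[, "S6"]
    w2 <- fitSignatureWeights(mix, cat96)$weights
    expect_equal(unname(w2[c("S1", "S6")]), c(0.7, 0.3), tolerance = 1e-6)
    expect_error(fitSignatureWeights(rep(1, 50), cat96), "96")
})

test_that("weights are scale-invariant, non-negative and sum to one", {
    cat96 <- defaultSignatureCatalog()
    set.seed(17)
    for (i in 1:10) {
        spec <- rmultinom(1, 500, rexp(96))[, 1]
        w1 <- fitSignatureWeights(spec, cat96)$weights
        w2 <- fitSignatureWeights(spec * 37.5, cat96)$weights
        expect_equal(w1, w2, tolerance = 1e-9)
        expect_true(all(w1 >= 0))
        expect_equal(sum(w1), 1, tolerance = 1e-9)
    }
    ## degenerate single-motif spectrum
    one <- rep(0, 96); one[13] <- 5
    ws <- fitSignatureWeights(one, cat96)$weights
    expect_true(all(ws >= 0))
    expect_equal(sum(ws), 1, tolerance = 1e-9)
})

test_that("sampled two-signature mixtures are recovered within 0.05", {
    cat96 <- defaultSignatureCatalog()
    m <- signatureMatrix(cat96)
    mix <- 0.7 * m[, "S1"] + 0.3 * m[, "S6"]
    set.seed(23)
    err <- replicate(30, {
        spec <- rmultinom(1, 2000, mix)[, 1]
        w <- fitSignatureWeights(spec, cat96)$weights
        mean(abs(w[c("S1", "S6")] - c(0.7, 0.3)))
    })
    expect_lt(mean(err), 0.05)
})

test_that("bootstrap flags present signatures and dismisses absent ones", {
    cfg <- smallOrganConfig(gammaTypes = c(SNV = 2000L, INS = 0L, DEL = 0L),
                            gammaMix = c(S1 = 0.7, S6 = 0.3))
    org <- generateOrgan(cfg, seed = 3)
    ids <- rownames(org$mutations)[
        org$truth$mutations$greek_class == "gamma"]
    bs <- bootstrapSignatures(org$mutations, org$catalog, subset = ids,
                              B = 200, seed = 2)
    expect_equal(unname(bs["S1", "p"]), 0)
    expect_equal(unname(bs["S6", "p"]), 0)
    expect_gt(unname(bs["S20", "p"]), 0.95)   # absent from the truth
    expect_true(bs["S1", "significant"])
    expect_false(bs["S20", "significant"])
    expect_error(bootstrapSignatures(org$mutations, org$catalog, B = 50),
                 "at least 100")
    ## bit-exact under a fixed seed
    bs2 <- bootstrapSignatures(org$mutations, org$catalog, subset = ids,
                               B = 200, seed = 2)
    expect_identical(as.data.frame(bs), as.data.frame(bs2))
})

test_that("substitution-class comparison finds planted C>T shift in gamma", {
    cfg <- smallOrganConfig(
        alphaMix = c(S20 = 0.9),              # C>A-heavy background
        gammaTypes = c(SNV = 300L, INS = 0L, DEL = 0L),
        gammaMix = c(S1 = 0.95))              # C>T-heavy clone
    org <- generateOrgan(cfg, seed = 7)
    greek <- structure(org$truth$mutations$greek_class,
                       names = rownames(org$mutations))
    res <- substitutionClassComparison(org$mutations, grouping = greek)
    tt <- as.data.frame(res$tests)
    row <- tt[tt$substitution == "C>T" &
              ((tt$group1 == "alpha" & tt$group2 == "gamma") |
               (tt$group1 == "gamma" & tt$group2 == "alpha")), ]
    expect_lt(row$q, 0.05)
})

test_that("null groupings stay null and tiny groups are skipped", {
    org <- generateOrgan(smallOrganConfig(), seed = 19)
    cls <- org$truth$mutations$greek_class
    ids <- rownames(org$mutations)
    ## an arbitrary even/odd split of the alpha class carries no signal
    split <- ifelse(seq_along(ids) %% 2 == 0, "g1", "g2")
    split[cls != "alpha"] <- NA
    names(split) <- ids
    res <- substitutionClassComparison(org$mutations, grouping = split)
    expect_true(all(as.data.frame(res$tests)$q > 0.05))
    ## a class observed in a single field cannot be compared
    solo <- split
    info <- mutationInfo(org$mutations)
    soloId <- ids[cls == "alpha" & info$mtype == "SNV"][1]
    solo[] <- NA; solo[soloId] <- "solo"; solo[ids[cls == "gamma"]] <- "g"
    expect_warning(substitutionClassComparison(org$mutations,
                                               grouping = solo),
                   "fewer than 2")
})
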