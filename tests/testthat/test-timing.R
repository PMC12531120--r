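mkStarFixture <- function(nFields = 6, perField = 2) {
    ## star tree: one private mutation set per field, equal neutral counts
    fm <- FieldMap(sprintf("S%d", seq_len(nFields)),
                   row = rep(1, nFields), col = seq_len(nFields),
                   grade = rep("NU", nFields))
    nMut <- nFields * perField
    vaf <- matrix(0, nMut, nFields,
                  dimnames = list(sprintf("m%02d", seq_len(nMut)),
                                  fieldIds(fm)))
    for (f in seq_len(nFields))
        vaf[(f - 1) * perField + seq_len(perField), f] <- 0.1
    info <- data.frame(gene = "G", mtype = "SNV", substitution = "C>T",
                       context = "A[C>T]A", silent = FALSE)
    mut <- MutationTable(vaf, info[rep(1, nMut), ], fm)
    star <- ape::read.tree(text = paste0(
        "(", paste(fieldIds(fm), collapse = ","), ");"))
    list(mut = mut, star = star)
}

test_that("edge assignment places private, clade and universal mutations", {
    fx <- mkStarFixture()
    chars <- characterMatrix(fx$mut)
    asg <- assignEdges(fx$star, chars)
    expect_true(all(asg$terminal))
    expect_false(any(asg$homoplasy))
    ## private mutations land on their field's terminal edge
    tipOf <- fx$star$edge[asg$edge, 2]
    expect_identical(fx$star$tip.label[tipOf[1]], "S1")

    ## a universal mutation sits on the root stem (edge 0)
    v <- vafMatrix(fx$mut)
    v <- rbind(v, everywhere = rep(0.3, ncol(v)))
    info <- as.data.frame(mutationInfo(fx$mut))
    info <- rbind(info, info[1, ])
    mut2 <- MutationTable(v, info, fieldcanceR:::mutFieldMap(fx$mut))
    asg2 <- assignEdges(fx$star, characterMatrix(mut2))
    expect_identical(asg2["everywhere", "edge"], 0L)
    expect_false(asg2["everywhere", "terminal"])
})

test_that("star-tree clock dates every private mutation at T/2 (midpoint)", {
    fx <- mkStarFixture()
    clk <- calibrateClock(fx$star, fx$mut,
                          neutralIds = rownames(fx$mut),
                          placement = "midpoint", T_total = 30)
    expect_equal(unname(clk$age), rep(15, nrow(fx$mut)))
    ## quantile placement keeps the midpoint as the per-edge mean
    clk2 <- calibrateClock(fx$star, fx$mut,
                           neutralIds = rownames(fx$mut), T_total = 30)
    expect_equal(mean(clk2$age[clk2$edge == clk2$edge[1]]), 15)
    expect_error(calibrateClock(fx$star, fx$mut, neutralIds = character()),
                 "non-empty")
})

test_that("an edge holding all neutral mutations absorbs its path's time", {
    ## two-cherry tree; all neutral mutations private to field A
    fm <- FieldMap(c("A", "B", "C", "D"), row = c(1, 1, 2, 2),
                   col = c(1, 2, 1, 2), grade = rep("NU", 4))
    vaf <- matrix(0, 24, 4, dimnames = list(sprintf("m%02d", 1:24),
                                            fieldIds(fm)))
    vaf[1:20, "A"] <- 0.05          # the neutral clock, all on edge to A
    vaf[cbind(21:23, 2:4)] <- 0.05  # one private mutation per other field
    vaf[24, c("A", "B")] <- 0.10    # one clade mutation
    info <- data.frame(gene = "G", mtype = "SNV", substitution = "C>T",
                       context = "A[C>T]A", silent = FALSE)
    mut <- MutationTable(vaf, info[rep(1, 24), ], fm)
    tree <- ape::read.tree(text = "((A,B),(C,D));")
    clk <- calibrateClock(tree, mut, neutralIds = rownames(mut)[1:23],
                          T_total = 30, sweepAware = FALSE,
                          placement = "midpoint")
    et <- attr(clk, "edgeTimes")
    ed <- tree$edge
    tipA <- which(tree$tip.label == "A")
    spanA <- et$t_hi[ed[, 2] == tipA] - et$t_lo[ed[, 2] == tipA]
    ## with 20 of 21.5 raw units on A's edge, it absorbs ~all of its path
    expect_gt(spanA, 0.85 * 30)
})

test_that("ages are invariant to mutation order and field relabeling", {
    org <- generateOrgan(smallOrganConfig(), seed = 31)
    mut <- org$mutations
    chars <- characterMatrix(mut)
    tr <- rootOrganTree(searchTree(chars, restarts = 2, seed = 5,
                                   plateau = 0), chars)
    neutral <- rownames(mut)[org$truth$mutations$greek_class == "alpha"]
    clk1 <- calibrateClock(tr, mut, neutralIds = neutral)
    perm <- sample(nrow(mut))
    clk2 <- calibrateClock(tr, mut[perm, ], neutralIds = neutral)
    expect_equal(structure(clk2$age, names = clk2$mutation_id)[
        clk1$mutation_id], structure(clk1$age,
                                     names = clk1$mutation_id))
})

test_that("selection inversion has its closed forms and monotonicity", {
    expect_equal(selectionCoefficient(exp(5), 5), 0)
    expect_equal(selectionCoefficient(exp(10), 5), 1)
    expect_error(selectionCoefficient(exp(5), 0), "positive")
    expect_error(selectionCoefficient(0.5, 5), ">= 1")
    m <- seq(1e3, 1e7, length.out = 50)
    s <- selectionCoefficient(m, 5)
    expect_true(all(diff(s) >= 0))           # increasing in mass
    a <- seq(2, 30, length.out = 50)
    s2 <- selectionCoefficient(1e6, a)
    expect_true(all(diff(s2) <= 0))          # decreasing in age
})

test_that("the change-point finds a planted 10x rate shift", {
    set.seed(51)
    hits <- 0
    for (i in 1:5) {
        t <- c(runif(300, 0, 25), runif(700, 25, 30))  # 12 -> 140 per year
        fit <- phaseChangepoint(30 - t, T_total = 30, nullSims = 0)
        if (abs(fit$changepoint - 25) <= 2) hits <- hits + 1
    }
    expect_gte(hits, 4)
    expect_error(phaseChangepoint(runif(10, 0, 30)), "at least 20")
})

test_that("null calibration keeps the false-positive rate near nominal", {
    set.seed(61)
    fp <- mean(replicate(30, {
        fit <- phaseChangepoint(runif(300, 0, 30), T_total = 30,
                                nullSims = 99, seed = 7)
        fit$significant
    }))
    expect_lte(fp, 0.15)
})

test_that("dormant/progressive structure is recovered on the organ", {
    ## clone mutation load proportioned as at full scale so the rate
    ## change stays detectable at this reduced problem size
    org <- generateOrgan(smallOrganConfig(
        nAlpha = 2000L, alphaTypes = c(SNV = 1900L, INS = 60L, DEL = 40L),
        betaTypes = c(SNV = 48L, INS = 0L, DEL = 0L),
        gammaTypes = c(SNV = 300L, INS = 0L, DEL = 0L)),
        seed = 41)
    tl <- buildCloneTimeline(org$mutations, restarts = 2, seed = 41)
    truth <- org$truth$mutations
    cls <- truth$greek_class
    tr <- tl$timeline
    expect_gte(mean(tr$age[cls == "gamma"] <= 5), 0.9)
    qa <- quantile(tr$age[cls == "alpha"], c(0.05, 0.95))
    expect_gt(diff(qa), 15)
    expect_lte(abs(tl$partition$changepoint - 25), 3)
    ## selection ordering recovered
    sel <- tapply(tr$selection, cls, mean)
    expect_gt(sel[["gamma"]], sel[["beta"]])
    expect_gt(sel[["beta"]], sel[["alpha"]])
    ## phases consistent with the change-point
    expect_true(all(tr$phase[tr$age > tl$partition$changepointAge] ==
                    "dormant"))
})
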