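test_that("Hamming distances are exact, symmetric and metric", {
    expect_identical(hammingMatrix(rbind(a = c(0, 1, 1),
                                         b = c(0, 0, 1)))["a", "b"], 1L)
    x <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
    expect_identical(hammingMatrix(x)["a", "b"], 0L)
    y <- rbind(a = rep(0, 7), b = rep(1, 7))
    expect_identical(hammingMatrix(y)["a", "b"], 7L)
    set.seed(3)
    chars <- randomBinaryChars(10, 40)
    D <- hammingMatrix(chars)
    expect_identical(D, t(D))
    for (i in 1:10) for (j in 1:10) for (k in 1:10)
        expect_lte(D[i, k], D[i, j] + D[j, k])
})

test_that("the compiled parsimony kernel matches independent oracles", {
    set.seed(7)
    for (i in 1:20) {
        n <- sample(4:7, 1)
        chars <- randomBinaryChars(n, 12)
        tree <- ape::unroot(ape::rtree(n, tip.label = rownames(chars)))
        got <- fitchScore(tree, chars)
        ## plain recursive DP, one character at a time
        dp <- sum(vapply(seq_len(ncol(chars)), function(j)
            sankoffOracleTree(tree, chars[, j]), numeric(1)))
        expect_identical(got, as.integer(dp))
        ## independent implementation cross-check
        ph <- phangorn::parsimony(
            tree, phangorn::phyDat(chars, type = "USER",
                                   levels = c(0, 1)))
        expect_identical(got, as.integer(ph))
    }
    ## forced single change; constant characters are free
    tri <- ape::read.tree(text = "(f1,f2,f3);")
    expect_identical(fitchScore(tri, cbind(c(f1 = 1, f2 = 0, f3 = 0))), 1L)
    expect_identical(fitchScore(tri, cbind(c(f1 = 1, f2 = 1, f3 = 1))), 0L)
    other <- randomBinaryChars(3, 2)
    rownames(other) <- paste0("x", 1:3)
    expect_error(fitchScore(tri, other), "missing")
})

test_that("search equals the exhaustive optimum on small matrices", {
    topo <- list(`5` = allTopologies(5), `6` = allTopologies(6))
    expect_length(topo$`5`, 15)
    expect_length(topo$`6`, 105)
    set.seed(15)
    ok <- 0
    for (i in 1:20) {
        n <- sample(5:6, 1)
        chars <- randomBinaryChars(n, 20)
        heur <- attr(searchTree(chars, restarts = 5, seed = i), "score")
        exact <- exactParsimony(chars, topo[[as.character(n)]])
        expect_gte(heur, exact)
        if (heur == exact) ok <- ok + 1
    }
    expect_gte(ok, 19)
})

test_that("hill-climbing never worsens the NJ start", {
    set.seed(33)
    for (i in 1:5) {
        chars <- randomBinaryChars(9, 30)
        tr <- searchTree(chars, restarts = 3, seed = i)
        expect_lte(attr(tr, "score"), attr(tr, "startScore"))
    }
})

test_that("two-field matrices give the single-edge tree", {
    chars <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 1))
    tr <- searchTree(chars)
    expect_identical(sort(tr$tip.label), c("a", "b"))
    expect_identical(attr(tr, "score"), 3L)
    expect_error(searchTree(chars[1, , drop = FALSE]), "at least 2")
})

test_that("nested clone structure is recovered as a clade", {
    ## pure nested structure: gamma clone over alpha background
    org <- generateOrgan(smallOrganConfig(
        betaClones = 0L, betaTypes = c(SNV = 0L, INS = 0L, DEL = 0L)),
        seed = 21)
    chars <- characterMatrix(org$mutations)
    tr <- searchTree(chars, restarts = 3, seed = 1, plateau = 0)
    g <- fieldGroups(org$fieldMap)
    gammaFields <- names(g)[g %in% c("HGIN", "UC")]
    rooted <- rootOrganTree(tr, chars)
    M <- fieldcanceR:::cladeMembership(rooted)
    inClade <- M %*% (colnames(M) %in% gammaFields)
    sizes <- rowSums(M)
    ## some node's clade is exactly the gamma-bearing fields
    expect_true(any(inClade == length(gammaFields) &
                    sizes == length(gammaFields)))
})

test_that("branch clustering recovers planted partitions and edge cases", {
    ## three well-separated groups on a simple character matrix
    g <- function(on, m = 30) { x <- rep(0, m); x[on] <- 1; x }
    chars <- rbind(a1 = g(1:10), a2 = g(1:10), a3 = g(c(1:10, 25)),
                   b1 = g(11:20), b2 = g(11:20), b3 = g(c(11:20, 26)),
                   c1 = g(21:24), c2 = g(21:24), c3 = g(c(21:24, 27)))
    D <- hammingMatrix(chars)
    tr <- searchTree(chars, restarts = 3, seed = 2)
    cl <- branchClusters(tr, D, k = 3)
    expect_identical(length(unique(cl)), 3L)
    expect_identical(length(unique(cl[c("a1", "a2", "a3")])), 1L)
    expect_identical(length(unique(cl[c("b1", "b2", "b3")])), 1L)
    expect_identical(length(unique(cl[c("c1", "c2", "c3")])), 1L)
    expect_identical(unique(unname(branchClusters(tr, D, k = 1))), 1L)
    expect_error(branchClusters(tr, D, k = 99), "exceeds")
})

test_that("tree order is deterministic and orientation-invariant", {
    txt <- "((a,b),((c,d),(e,(f,g))));"
    tr <- ape::read.tree(text = txt)
    o1 <- treeOrder(tr)
    expect_identical(sort(o1), sort(tr$tip.label))
    expect_identical(treeOrder(tr), o1)
    ## mirrored child order
    tr2 <- ape::read.tree(text = "((((g,f),e),(d,c)),(b,a));")
    expect_identical(treeOrder(tr2), o1)
    ## caterpillar comes out in path order
    cat <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
    oc <- treeOrder(cat)
    expect_identical(oc[1:2], c("a", "b"))
    expect_identical(oc[6], "f")
})
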