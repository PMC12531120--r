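## Shared fixtures, built in code.

## a small organ: same grid and structure, fewer mutations/analytes;
## overrides in ... win over the small defaults (nested lists merged)
smallOrganConfig <- function(...) {
    base <- list(
        nAlpha = 400L, alphaTypes = c(SNV = 370L, INS = 18L, DEL = 12L),
        betaTypes = c(SNV = 16L, INS = 1L, DEL = 1L),
        gammaTypes = c(SNV = 28L, INS = 1L, DEL = 1L),
        lociShared = 5L,
        rna = list(nAnalytes = 300L),
        protein = list(nAnalytes = 300L, nSharedRna = 100L),
        metabolite = list(nAnalytes = 91L))
    ov <- list(...)
    for (nm in names(ov)) {
        if (is.list(ov[[nm]]) && is.list(base[[nm]]))
            base[[nm]][names(ov[[nm]])] <- ov[[nm]]
        else base[[nm]] <- ov[[nm]]
    }
    do.call(organConfig, base)
}

tinyFieldMap <- function() {
    FieldMap(c("A1", "A2", "B1", "B2"), row = c(1, 1, 2, 2),
             col = c(1, 2, 1, 2), grade = c("NU", "LGIN", "HGIN", "UC"))
}

tinyMutationTable <- function() {
    fm <- tinyFieldMap()
    vaf <- rbind(m1 = c(0.05, 0, 0, 0),
                 m2 = c(0.10, 0.12, 0.08, 0),
                 m3 = c(0.30, 0.35, 0.40, 0.38))
    colnames(vaf) <- fieldIds(fm)
    info <- data.frame(
        gene = c("TP53", "KMT2D", "GENE1"),
        mtype = c("SNV", "SNV", "DEL"),
        substitution = c("C>T", "T>C", NA),
        context = c("A[C>T]G", "C[T>C]A", NA),
        silent = c(FALSE, TRUE, FALSE))
    MutationTable(vaf, info, fm)
}

## independent step-up BH reimplementation (test oracle)
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in rev(seq_len(m))) {
        prev <- min(prev, m * p[o[i]] / i)
        q[o[i]] <- prev
    }
    q
}

## brute-force 2 x 3 Fisher exact p by enumerating all tables with the
## observed margins (test oracle)
fisher2x3Oracle <- function(tab) {
    r <- rowSums(tab); cs <- colSums(tab)
    logProb <- function(x) {
        sum(lgamma(r + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(x) + 1) -
            sum(lgamma(x + 1))
    }
    pObs <- logProb(tab)
    tot <- 0
    for (a in 0:min(r[1], cs[1])) for (b in 0:min(r[1] - a, cs[2])) {
        cc <- r[1] - a - b
        if (cc < 0 || cc > cs[3]) next
        x <- rbind(c(a, b, cc), cs - c(a, b, cc))
        if (any(x < 0)) next
        lp <- logProb(x)
        if (lp <= pObs + 1e-7) tot <- tot + exp(lp)
    }
    tot
}

## hypergeometric upper-tail by direct summation (test oracle)
hyperTailOracle <- function(k, K, N, n) {
    kk <- k:min(K, n)
    sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

## plain recursive Sankoff DP on an ape tree, one character (test oracle,
## independent of the compiled kernel)
sankoffOracleTree <- function(tree, states) {
    ed <- tree$edge
    nTip <- length(tree$tip.label)
    root <- setdiff(ed[, 1], ed[, 2])[1]
    cost <- function(v) {
        if (v <= nTip) {
            s <- states[tree$tip.label[v]]
            return(if (s == 0) c(0, Inf) else c(Inf, 0))
        }
        kids <- ed[ed[, 1] == v, 2]
        tot <- c(0, 0)
        for (k in kids) {
            ck <- cost(k)
            tot <- tot + c(min(ck[1], ck[2] + 1), min(ck[2], ck[1] + 1))
        }
        tot
    }
    min(cost(root))
}

randomBinaryChars <- function(n, m, p = 0.4) {
    matrix(stats::rbinom(n * m, 1, p), n, m,
           dimnames = list(paste0("f", seq_len(n)), paste0("m", seq_len(m))))
}
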