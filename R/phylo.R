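## Maximum-parsimony phylogeny of mucosal fields from binary mutation
## presence profiles: Hamming distances, an exact small-parsimony kernel
## (src/fitch.cpp), neighbor-joining + NNI hill-climbing search, branch
## clustering and a canonical leaf order.

#' Binary character matrix from a mutation table
#'
#' Fields in rows, mutations in columns; entry 1 when the field carries
#' the mutation at or above the presence threshold. All silent and
#' nonsilent mutations are used. Fields carrying no mutation at all are
#' dropped with a warning.
#'
#' @param mut a \linkS4class{MutationTable}.
#' @param threshold presence threshold; default 0.01.
#' @return integer 0/1 matrix, fields x mutations.
#' @export
characterMatrix <- function(mut, threshold = 0.01) {
    x <- t(vafMatrix(mut) >= threshold)
    storage.mode(x) <- "integer"
    empty <- rowSums(x) == 0
    if (any(empty)) {
        warning("dropping field(s) with no mutations: ",
                paste(rownames(x)[empty], collapse = ", "))
        x <- x[!empty, , drop = FALSE]
    }
    x
}

#' Hamming distance matrix between fields
#'
#' @param chars binary matrix fields x mutations.
#' @return symmetric integer matrix of pairwise Hamming distances.
#' @export
#' @examples
#' hammingMatrix(rbind(a = c(0, 1, 1), b = c(0, 0, 1)))
hammingMatrix <- function(chars) {
    if (nrow(chars) < 2) stop("need at least 2 fields")
    x <- chars
    storage.mode(x) <- "double"
    cross <- tcrossprod(x)
    rs <- rowSums(x)
    D <- outer(rs, rs, "+") - 2 * cross
    storage.mode(D) <- "integer"
    dimnames(D) <- list(rownames(chars), rownames(chars))
    D
}

postorderEdges <- function(tree) {
    po <- ape::reorder.phylo(tree, "postorder")
    storage.mode(po$edge) <- "integer"
    po$edge
}

tipStatesFor <- function(tree, chars) {
    miss <- setdiff(tree$tip.label, rownames(chars))
    if (length(miss))
        stop("tree leaves missing from the character matrix: ",
             paste(miss, collapse = ", "))
    x <- chars[tree$tip.label, , drop = FALSE]
    storage.mode(x) <- "integer"
    x
}

#' Parsimony score of a tree
#'
#' Sum over characters of the minimum number of presence/absence changes
#' on the (unrooted) tree.
#'
#' @param tree a \code{phylo} whose tip labels are field ids.
#' @param chars binary matrix fields x mutations.
#' @return integer parsimony score.
#' @export
fitchScore <- function(tree, chars) {
    .fitchScoreCpp(postorderEdges(tree), length(tree$tip.label),
                   tipStatesFor(tree, chars))
}

## split characters into parsimony-informative columns and the constant
## score contributed by the rest (count 1 or n-1 forces exactly 1 change)
informativeSplit <- function(chars) {
    n <- nrow(chars)
    cs <- colSums(chars)
    inf <- cs >= 2 & cs <= n - 2
    list(inf = chars[, inf, drop = FALSE],
         constant = sum(cs %in% c(1L, n - 1L)))
}

randomTopology <- function(labels) {
    ape::unroot(ape::rtree(length(labels), rooted = TRUE,
                           tip.label = sample(labels)))
}

#' Heuristic maximum-parsimony tree search
#'
#' Starts from the neighbor-joining tree on the Hamming distances, then
#' hill-climbs by nearest-neighbor interchange on the parsimony score
#' until no move improves; best of \code{restarts} starts (the first the
#' NJ tree, the rest random topologies) is returned. Only
#' parsimony-informative characters are rescored during the search; the
#' reported score covers all characters.
#'
#' @param chars binary matrix fields x mutations (at least 2 fields).
#' @param restarts number of starts; default 10.
#' @param seed integer seed (random restarts and tie-breaking).
#' @param plateau maximum consecutive sideways (equal-score) moves per
#'   start, an escape from parsimony plateaus; default 3 x the number of
#'   fields. Set 0 for pure descent (cheaper on large matrices).
#' @return an unrooted \code{phylo} with edge lengths set to per-edge
#'   parsimony changes and attributes \code{score} (total parsimony
#'   score) and \code{startScore} (score of the NJ start).
#' @export
searchTree <- function(chars, restarts = 10, seed = 1,
                       plateau = 3L * nrow(chars)) {
    n <- nrow(chars)
    if (n < 2) stop("need at least 2 fields")
    if (n == 2) {
        d <- hammingMatrix(chars)[1, 2]
        tr <- ape::read.tree(text = sprintf("(%s:%d,%s:%d);",
                                            rownames(chars)[1], d,
                                            rownames(chars)[2], 0L))
        attr(tr, "score") <- as.integer(d)
        attr(tr, "startScore") <- as.integer(d)
        return(tr)
    }
    withSeed(seed, {
        sp <- informativeSplit(chars)
        scoreOf <- function(tr) {
            if (ncol(sp$inf) == 0) return(0L)
            .fitchScoreCpp(postorderEdges(tr), n, tipStatesFor(tr, sp$inf))
        }
        D <- hammingMatrix(chars)
        njTree <- ape::unroot(ape::nj(stats::as.dist(D)))
        startScore <- scoreOf(njTree) + sp$constant
        best <- NULL
        bestScore <- Inf
        for (r in seq_len(restarts)) {
            cur <- if (r == 1) njTree else randomTopology(rownames(chars))
            curScore <- scoreOf(cur)
            if (n >= 4) {
                ## steepest descent with bounded sideways (plateau) moves
                flatLeft <- plateau
                repeat {
                    nb <- phangorn::nni(cur)
                    scores <- vapply(nb, scoreOf, integer(1))
                    if (min(scores) < curScore) {
                        cur <- nb[[which.min(scores)]]
                        curScore <- min(scores)
                        flatLeft <- plateau
                    } else if (min(scores) == curScore && flatLeft > 0L) {
                        flat <- which(scores == curScore)
                        cur <- nb[[flat[sample.int(length(flat), 1)]]]
                        flatLeft <- flatLeft - 1L
                    } else break
                }
            }
            if (curScore < bestScore) {
                bestScore <- curScore
                best <- cur
            }
        }
        ts <- tipStatesFor(best, chars)
        po <- ape::reorder.phylo(best, "postorder")
        storage.mode(po$edge) <- "integer"
        po$edge.length <- as.numeric(
            .fitchEdgeChangesCpp(po$edge, n, ts))
        attr(po, "score") <- as.integer(bestScore + sp$constant)
        attr(po, "startScore") <- as.integer(startScore)
        po
    })
}

## ---------------------------------------------------------------------
## Exhaustive topology enumeration (oracle-scale trees)
## ---------------------------------------------------------------------

#' Enumerate all unrooted binary topologies
#'
#' Stepwise addition: every labeled unrooted binary tree on \code{n}
#' leaves ((2n-5)!! of them). Intended for small n (<= 8).
#'
#' @param n number of leaves (3..8).
#' @return list of postorder edge matrices (1-based; tips 1..n).
#' @export
allTopologies <- function(n) {
    stopifnot(n >= 3, n <= 9)
    ## edges as 2-column matrices over labels: tips 1..n, internals n+1...
    base <- cbind(rep(n + 1L, 3), 1:3)
    trees <- list(base)
    if (n > 3) {
        for (tip in 4:n) {
            nextInternal <- n + tip - 2L
            trees <- unlist(lapply(trees, function(ed) {
                lapply(seq_len(nrow(ed)), function(e) {
                    a <- ed[e, 1]; b <- ed[e, 2]
                    rbind(ed[-e, , drop = FALSE],
                          c(a, nextInternal), c(nextInternal, b),
                          c(nextInternal, tip))
                })
            }), recursive = FALSE)
        }
    }
    lapply(trees, postorderFromEdges, n = n)
}

## orient an arbitrary edge list as rooted at internal node n+1 and return
## edges in postorder
postorderFromEdges <- function(ed, n) {
    nNode <- max(ed)
    adj <- vector("list", nNode)
    for (i in seq_len(nrow(ed))) {
        a <- ed[i, 1]; b <- ed[i, 2]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    root <- n + 1L
    parent <- integer(nNode)
    order <- integer(0)
    stack <- root
    visited <- logical(nNode)
    visited[root] <- TRUE
    while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        order <- c(order, v)
        for (w in adj[[v]]) if (!visited[w]) {
            visited[w] <- TRUE
            parent[w] <- v
            stack <- c(stack, w)
        }
    }
    ## reverse preorder = valid postorder of edges (child before parent use)
    nodes <- rev(order)[rev(order) != root]
    out <- cbind(parent[nodes], nodes)
    storage.mode(out) <- "integer"
    out
}

#' Exact minimum parsimony score by exhaustive enumeration
#'
#' Brute-force optimum over all unrooted topologies; feasible for up to 8
#' leaves.
#'
#' @param chars binary matrix fields x mutations (3..8 rows).
#' @param topologies optional pre-computed result of
#'   \code{\link{allTopologies}(nrow(chars))} to amortize enumeration.
#' @return integer: the global minimum parsimony score.
#' @export
exactParsimony <- function(chars, topologies = NULL) {
    n <- nrow(chars)
    if (is.null(topologies)) topologies <- allTopologies(n)
    x <- chars
    storage.mode(x) <- "integer"
    min(.fitchScoresManyCpp(topologies, n, x))
}

## ---------------------------------------------------------------------
## Branch clusters and leaf order
## ---------------------------------------------------------------------

componentsAfterCut <- function(tree, cutEdges) {
    ed <- tree$edge
    keep <- setdiff(seq_len(nrow(ed)), cutEdges)
    nNode <- max(ed)
    parent <- seq_len(nNode)
    findp <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (e in keep) {
        a <- findp(ed[e, 1]); b <- findp(ed[e, 2])
        if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_len(nNode), findp, integer(1))
    nTip <- length(tree$tip.label)
    split(seq_len(nTip), comp[seq_len(nTip)])
}

#' Partition fields into k tree branches
#'
#' Greedily removes k-1 edges, each chosen to maximize the minimum
#' inter-cluster Hamming distance (single-linkage separation) of the
#' resulting leaf partition; ties broken lexicographically on the sorted
#' leaf sets. Cuts that isolate a leafless component are not allowed.
#'
#' @param tree a \code{phylo}.
#' @param D Hamming distance matrix over the tree's leaves (from
#'   \code{\link{hammingMatrix}}).
#' @param k number of branches; default 3.
#' @return named integer vector: cluster index (1..k) per field.
#' @export
branchClusters <- function(tree, D, k = 3) {
    nTip <- length(tree$tip.label)
    if (k > nTip) stop("k exceeds the number of leaves")
    if (k == 1)
        return(structure(rep(1L, nTip), names = tree$tip.label))
    D <- D[tree$tip.label, tree$tip.label]
    minSep <- function(groups) {
        if (length(groups) < 2) return(Inf)
        prs <- utils::combn(length(groups), 2)
        min(apply(prs, 2, function(ij)
            min(D[groups[[ij[1]]], groups[[ij[2]]], drop = FALSE])))
    }
    cuts <- integer(0)
    for (step in seq_len(k - 1)) {
        cand <- setdiff(seq_len(nrow(tree$edge)), cuts)
        bestVal <- -Inf; bestKey <- NULL; bestE <- NA
        for (e in cand) {
            groups <- componentsAfterCut(tree, c(cuts, e))
            if (length(groups) != step + 1) next  # leafless component
            val <- minSep(groups)
            key <- paste(vapply(groups, function(g)
                paste(sort(tree$tip.label[g]), collapse = ","),
                character(1)), collapse = ";")
            if (val > bestVal || (val == bestVal && !is.null(bestKey) &&
                                  key < bestKey)) {
                bestVal <- val; bestKey <- key; bestE <- e
            }
        }
        if (is.na(bestE)) stop("cannot split the tree into ", k,
                               " leaf-bearing branches")
        cuts <- c(cuts, bestE)
    }
    groups <- componentsAfterCut(tree, cuts)
    out <- integer(nTip)
    ## deterministic cluster numbering: by smallest leaf label
    ord <- order(vapply(groups, function(g)
        min(tree$tip.label[g]), character(1)))
    for (i in seq_along(ord)) out[groups[[ord[i]]]] <- i
    names(out) <- tree$tip.label
    out
}

#' Canonical leaf order for genetic-distance heatmaps
#'
#' Deterministic, orientation-invariant leaf sequence: the tree is rooted
#' at its lexicographically smallest leaf and traversed with children
#' ordered by subtree size, then by smallest contained leaf label.
#'
#' @param tree a \code{phylo}.
#' @return character vector of leaf labels.
#' @export
treeOrder <- function(tree) {
    tips <- sort(tree$tip.label)
    rooted <- ape::root(tree, outgroup = tips[1], resolve.root = TRUE)
    ed <- rooted$edge
    nTip <- length(rooted$tip.label)
    kids <- split(ed[, 2], ed[, 1])
    info <- function(v) {
        if (v <= nTip)
            return(list(size = 1L, minLab = rooted$tip.label[v],
                        leaves = rooted$tip.label[v]))
        parts <- lapply(kids[[as.character(v)]], info)
        ord <- order(vapply(parts, `[[`, integer(1), "size"),
                     vapply(parts, `[[`, character(1), "minLab"))
        parts <- parts[ord]
        list(size = sum(vapply(parts, `[[`, integer(1), "size")),
             minLab = min(vapply(parts, `[[`, character(1), "minLab")),
             leaves = unlist(lapply(parts, `[[`, "leaves")))
    }
    root <- setdiff(ed[, 1], ed[, 2])[1]
    info(root)$leaves
}
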