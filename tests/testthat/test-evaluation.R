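test_that("rocAuc implements midrank Mann-Whitney ranking", {
    r <- rocAuc(c(0.9, 0.7, 0.8, 0.6), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(r$auc, 0.75)   # 3 of 4 concordant pairs
    expect_equal(rocAuc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
    expect_equal(rocAuc(rep(0.5, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                       FALSE))$auc, 0.5)
    expect_error(rocAuc(c(1, 2), c(TRUE, TRUE)), "positive")
    # curve starts at (0,0) and ends at (1,1)
    expect_equal(unlist(r$curve[1, c("fpr", "tpr")], use.names = FALSE),
                 c(0, 0))
    expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")],
                        use.names = FALSE), c(1, 1))
})

test_that("AUC is invariant under strictly monotone score transforms", {
    set.seed(71)
    for (rep in 1:10) {
        s <- runif(40)
        p <- runif(40) < 0.4
        if (!any(p) || all(p)) next
        a <- rocAuc(s, p)$auc
        expect_equal(rocAuc(exp(3 * s), p)$auc, a)
        expect_equal(rocAuc(rank(s), p)$auc, a)
    }
})

test_that("rocAuc agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(72)
    for (rep in 1:5) {
        s <- round(runif(60), 2)   # force some ties
        p <- runif(60) < 0.5
        if (!any(p) || all(p)) next
        a <- rocAuc(s, p)$auc
        b <- as.numeric(pROC::auc(pROC::roc(response = p, predictor = s,
                                            quiet = TRUE,
                                            direction = "<")))
        expect_equal(a, b)
    }
})

test_that("pairScores enumerates unordered pairs without self-pairs", {
    m <- matrix(c(1, .5, .2, .5, 1, .8, .2, .8, 1), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    p <- pairScores(m, c("F1", "F1", "F2"))
    expect_equal(nrow(p), 3L)
    expect_equal(p$positive, c(TRUE, FALSE, FALSE))
    expect_equal(p$score[p$id1 == "a" & p$id2 == "b"], 0.5)
})

test_that("neighbor joining recovers an additive metric exactly", {
    # tree ((A:1,B:2):1,(C:3,D:4)); pairwise path lengths below
    d <- matrix(c(0, 3, 5, 6,
                  3, 0, 6, 7,
                  5, 6, 0, 7,
                  6, 7, 7, 0), 4, 4,
                dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    nw <- njTree(d)
    tr <- ape::read.tree(text = nw)
    expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d)
    # permuting the input order yields the same unrooted topology
    set.seed(73)
    d6 <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
    d6[upper.tri(d6)] <- runif(15, 0.2, 1)
    d6 <- d6 + t(d6)
    t1 <- ape::read.tree(text = njTree(d6))
    p <- sample.int(6)
    t2 <- ape::read.tree(text = njTree(d6[p, p]))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
})

test_that("vertex removal deletes round(fraction * N) stems, half-up", {
    set.seed(74)
    g <- randomXiosGraph(10)
    expect_identical(removeVertices(g, 0), g)
    expect_equal(vertexCount(removeVertices(g, 0.3)), 7L)
    expect_equal(vertexCount(removeVertices(g, 0.25)), 7L)  # 2.5 -> 3
    expect_equal(vertexCount(removeVertices(g, 0.7)), 3L)
    # the result is an induced subgraph: no new relations appear
    g2 <- removeVertices(g, 0.3)
    expect_true(all(edgeTable(g2)$type %in% c("I", "O")))
})

test_that("pseudoknot-first removal eliminates O edges within budget", {
    set.seed(75)
    # no O edges: plain random removal of the budgeted count
    nest <- xiosFromArrangement(c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1,
                                  6, 7, 8, 8, 7, 6, 9, 10, 10, 9))
    expect_equal(vertexCount(removePseudoknots(nest, 0.3)), 7L)
    # a lone pseudoknot with budget >= 2: both vertices gone
    pk <- xiosFromArrangement(c(1, 2, 1, 2))
    expect_equal(vertexCount(removePseudoknots(pk, 1)), 0L)
    # light pseudoknot load: results are O-free
    for (rep in 1:20) {
        arr <- c(1, 2, 1, 2)                      # one crossing pair
        for (n in 3:10) {
            pos <- sample(length(arr) + 1L, 1L) - 1L
            arr <- xiosfp:::.relabelArrangement(append(arr, c(n, n),
                                                       after = pos))
        }
        g <- xiosFromArrangement(arr)
        nO <- sum(edgeTable(g)$type == "O")
        budget <- floor(0.5 * vertexCount(g) + 0.5)
        overt <- unique(unlist(edgeTable(g)[edgeTable(g)$type == "O",
                                            c("from", "to")]))
        if (length(overt) > budget) next
        out <- removePseudoknots(g, 0.5)
        expect_equal(sum(edgeTable(out)$type == "O"), 0L)
    }
})

test_that("decoy databases count connected 2-5 stem subgraphs exactly", {
    lib <- cachedLibrary(5)
    db <- buildDecoyDB(list(xiosFromArrangement(c(1, 2, 1, 2))), lib)
    e <- decoyEntries(db)
    expect_equal(e$motif_id, "1.2.o|")
    expect_equal(e$count, 1L)

    set.seed(76)
    gs <- lapply(1:3, function(i) randomXiosGraph(sample(6:8, 1L)))
    db1 <- buildDecoyDB(gs, lib)
    db2 <- buildDecoyDB(rev(gs), lib)
    e1 <- decoyEntries(db1)
    expect_equal(e1[order(e1$motif_id), ],
                 decoyEntries(db2)[order(decoyEntries(db2)$motif_id), ],
                 ignore_attr = TRUE)
    # total count equals the brute-force number of connected 2-5 subsets
    brute <- sum(vapply(gs, function(g)
        sum(vapply(2:5, function(k) length(bruteSubsetCodes(g, k)), 0L)),
        0L))
    expect_equal(sum(e1$count), brute)
})

test_that("graph expansion hits the target size and preserves motifs", {
    lib <- cachedLibrary(5)
    set.seed(77)
    gs <- lapply(1:3, function(i) randomXiosGraph(8))
    db <- buildDecoyDB(gs, lib)
    g <- randomXiosGraph(8)
    expect_identical(expandGraph(g, db, targetVertices = 8), g)
    for (rep in 1:10) {
        big <- expandGraph(g, db, targetVertices = 30)
        expect_equal(vertexCount(big), 30L)
        ins <- attr(big, "insertions")
        expect_gte(nrow(ins), 1L)
        for (k in seq_len(nrow(ins))) {
            sub <- xiosfp:::.inducedSubgraph(big, ins$vertices[[k]])
            expect_equal(canonicalCode(sub), ins$motif_id[k])
        }
    }
})

test_that("random topologies are uniform over connected arrangements", {
    set.seed(78)
    for (rep in 1:30) {
        g <- randomXiosGraph(2)
        expect_true(canonicalCode(g) %in% c("1.2.o|", "1.2.i|"))
    }
    g <- randomXiosGraph(12)
    expect_equal(length(ioComponents(g)), 1L)
})

test_that("unperturbed synthetic family members are identical to the seed", {
    lib <- cachedLibrary(5)
    set.seed(79)
    fam <- synthFamilies(2, 3, 8, 0, lib)
    fps <- lapply(fam$graphs, exhaustiveFingerprint, lib = lib,
                  subgraphSize = 5)
    m <- similarityMatrix(fps, "jaccard")
    within <- m[1:3, 1:3]
    expect_true(all(within == 1))
})
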