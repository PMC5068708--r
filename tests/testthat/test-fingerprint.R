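abstractGraph <- function(n, from, to, type, id = "abs")
    new("XIOSGraph", id = id, nVertices = as.integer(n),
        edges = data.frame(from = as.integer(from), to = as.integer(to),
                           type = type),
        arrangement = integer(),
        stems = data.frame(id = integer(), l1 = integer(), l2 = integer(),
                           r1 = integer(), r2 = integer()))

test_that("connected-subgraph sampling follows the growth rule", {
    set.seed(51)
    # 1-vertex graph: early break returns the single vertex
    g1 <- xiosFromArrangement(c(1, 1))
    expect_equal(vertexCount(sampleConnectedSubgraph(g1, 7)), 1L)

    # triangle of O edges, n = 2: both vertices and the induced O edge
    tri <- xiosFromArrangement(c(1, 2, 3, 1, 2, 3))
    for (k in 1:10) {
        s <- sampleConnectedSubgraph(tri, 2)
        expect_equal(vertexCount(s), 2L)
        expect_equal(edgeTable(s)$type, "O")
    }

    # I-edge path A-B-C: the only growth sequences cover the whole graph
    path <- abstractGraph(3, c(1, 2), c(2, 3), c("I", "I"))
    for (k in 1:10)
        expect_equal(vertexCount(sampleConnectedSubgraph(path, 3)), 3L)
})

test_that("a lone pseudoknot samples to a single motif", {
    lib <- cachedLibrary(5)
    g <- xiosFromArrangement(c(1, 2, 1, 2))
    fp <- simpleFingerprint(g, lib, subgraphSize = 5, seed = 1)
    expect_equal(motifIDs(fp), "1.2.o|")
    expect_equal(unname(motifCounts(fp)), iterationCount(fp))
    expect_equal(iterationCount(fp), 10L)   # stops exactly at minCount
})

test_that("a graph that IS a library motif fingerprints to itself", {
    lib <- cachedLibrary(5)
    set.seed(52)
    for (k in 1:5) {
        g <- randomXiosGraph(5)
        fp <- simpleFingerprint(g, lib, subgraphSize = 5)
        expect_equal(motifIDs(fp), canonicalCode(g))
    }
})

test_that("exhaustive enumeration counts distinct connected subsets", {
    lib <- cachedLibrary(5)
    g <- xiosFromArrangement(c(1, 2, 3, 2, 3, 1))
    fp <- exhaustiveFingerprint(g, lib, subgraphSize = 3)
    expect_equal(length(motifIDs(fp)), 1L)
    expect_equal(unname(motifCounts(fp)), 1L)

    # combn oracle on 6-8 vertex graphs and subgraph sizes 3/4
    set.seed(53)
    for (rep in 1:6) {
        n <- sample(6:8, 1L)
        k <- sample(3:4, 1L)
        g <- randomXiosGraph(n)
        fp <- exhaustiveFingerprint(g, lib, subgraphSize = k)
        oracle <- table(bruteSubsetCodes(g, k))
        expect_equal(motifCounts(fp),
                     vapply(sort(names(oracle)), function(id)
                         as.integer(oracle[[id]]), 0L))
    }
})

test_that("sampling finds the same motif set as exhaustive enumeration", {
    lib <- cachedLibrary(7)
    set.seed(54)
    for (rep in 1:15) {
        n <- sample(4:10, 1L)
        g <- randomXiosGraph(n)
        ex <- exhaustiveFingerprint(g, lib)
        sp <- simpleFingerprint(g, lib)
        expect_setequal(motifIDs(sp), motifIDs(ex))
    }
})

test_that("the sampled motif SET is seed-independent at termination", {
    lib <- cachedLibrary(7)
    set.seed(55)
    g <- randomXiosGraph(9)
    sets <- lapply(1:5, function(s)
        motifIDs(simpleFingerprint(g, lib, seed = s)))
    for (k in 2:5) expect_setequal(sets[[k]], sets[[1]])
})

test_that("fingerprints of multi-component graphs span 2..7 stem motifs", {
    lib <- cachedLibrary(7)
    # two components: a pseudoknot pair and a nested triple
    g <- xiosFromArrangement(c(1, 2, 1, 2, 3, 4, 5, 5, 4, 3))
    ex <- exhaustiveFingerprint(g, lib)
    ns <- vapply(motifIDs(ex), function(id)
        motifTable(lib)$n_stems[xiosfp:::.motifRow(lib, id)], 0L)
    expect_setequal(unname(ns), c(2L, 3L))
    # singleton components are discarded (2-stem ancestry floor)
    g2 <- xiosFromArrangement(c(1, 1, 2, 3, 2, 3))
    ex2 <- exhaustiveFingerprint(g2, lib)
    expect_equal(motifIDs(ex2), "1.2.o|")
})

test_that("extension adds exactly the ancestor closure, idempotently", {
    lib <- cachedLibrary(7)
    set.seed(56)
    # only 2-stem motifs: extension is a no-op
    pk <- exhaustiveFingerprint(xiosFromArrangement(c(1, 2, 1, 2)), lib)
    expect_equal(motifIDs(extendFingerprint(pk, lib)), motifIDs(pk))

    for (rep in 1:10) {
        g <- randomXiosGraph(sample(5:10, 1L))
        fp <- exhaustiveFingerprint(g, lib)
        ext <- extendFingerprint(fp, lib)
        expect_true(all(motifIDs(fp) %in% motifIDs(ext)))
        expect_gte(length(motifIDs(ext)), length(motifIDs(fp)))
        expect_equal(fingerprintKind(ext), "extended")
        # idempotent and ancestor-closed
        ext2 <- extendFingerprint(ext, lib)
        expect_setequal(motifIDs(ext2), motifIDs(ext))
        anc <- unique(unlist(lapply(motifIDs(ext), motifAncestors,
                                    lib = lib)))
        expect_true(all(anc %in% motifIDs(ext)))
        # added motifs carry count 0
        added <- setdiff(motifIDs(ext), motifIDs(fp))
        expect_true(all(motifCounts(ext)[added] == 0L))
    }
})
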