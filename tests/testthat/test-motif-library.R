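test_that("arrangement enumeration is exhaustive and non-redundant", {
    a2 <- enumerateArrangements(2)
    expect_equal(nrow(a2), 3L)
    key <- apply(a2, 1L, paste, collapse = "")
    expect_setequal(key, c("1122", "1212", "1221"))

    # independent oracle at n = 3: filter all 6! position permutations of
    # (1,1,2,2,3,3) down to first-occurrence-canonical sequences
    perms <- xiosfp:::.allPermutations(6L)
    seqs <- unique(apply(perms, 1L, function(p)
        paste(c(1L, 1L, 2L, 2L, 3L, 3L)[order(p)], collapse = "")))
    canon <- seqs[vapply(strsplit(seqs, ""), function(s) {
        v <- as.integer(s)
        !is.unsorted(match(1:3, v), strictly = TRUE)
    }, TRUE)]
    a3 <- apply(enumerateArrangements(3), 1L, paste, collapse = "")
    expect_equal(sort(a3), sort(canon))
    expect_equal(length(a3), 15L)   # (2n-1)!!

    expect_equal(nrow(enumerateArrangements(5)), 945L)
    expect_error(enumerateArrangements(8), "1..7")
    expect_error(enumerateArrangements(0), "1..7")
})

test_that("the R graph path and the batch library path agree", {
    for (n in 2:4) {
        arrs <- enumerateArrangements(n)
        batch <- xiosfp:::.arrangement_codes(arrs)
        slow <- vapply(seq_len(nrow(arrs)), function(i) {
            g <- xiosFromArrangement(arrs[i, ])
            if (!xiosfp:::.ioConnected(g)) NA_character_
            else canonicalCode(g)
        }, "")
        expect_equal(batch, slow)
    }
    set.seed(31)
    arrs <- t(replicate(50, randomArrangement(6L)))
    batch <- xiosfp:::.arrangement_codes(arrs)
    slow <- vapply(seq_len(nrow(arrs)), function(i) {
        g <- xiosFromArrangement(arrs[i, ])
        if (!xiosfp:::.ioConnected(g)) NA_character_
        else canonicalCode(g)
    }, "")
    expect_equal(batch, slow)
})

test_that("deduplication is independent of enumeration order", {
    set.seed(32)
    arrs <- enumerateArrangements(4)
    codes <- xiosfp:::.arrangement_codes(arrs)
    shuf <- xiosfp:::.arrangement_codes(arrs[sample.int(nrow(arrs)), ])
    expect_setequal(unique(codes[!is.na(codes)]),
                    unique(shuf[!is.na(shuf)]))
})

test_that("every motif's representative arrangement regenerates its key", {
    lib <- cachedLibrary(5)
    tab <- motifTable(lib)
    set.seed(33)
    pick <- sample(which(tab$n_stems >= 2L), 150L)
    for (k in pick) {
        g <- xiosFromArrangement(motifArrangement(lib, tab$motif_id[k]))
        expect_equal(canonicalCode(g), tab$motif_id[k])
    }
})

test_that("parents are the connected one-stem-deleted motifs", {
    lib <- cachedLibrary(5)
    tab <- motifTable(lib)
    m2 <- tab$motif_id[tab$n_stems == 2L]
    for (id in m2) expect_equal(motifParents(lib, id), "0")

    set.seed(34)
    pick <- sample(which(tab$n_stems >= 3L), 40L)
    for (k in pick) {
        parents <- motifParents(lib, tab$motif_id[k])
        expect_gte(length(parents), 1L)
        ns <- vapply(parents, function(p)
            tab$n_stems[xiosfp:::.motifRow(lib, p)], 0L)
        expect_true(all(ns == tab$n_stems[k] - 1L))
    }
})

test_that("children built by adding one stem report their parent", {
    lib <- cachedLibrary(5)
    tab <- motifTable(lib)
    set.seed(35)
    four <- sample(tab$motif_id[tab$n_stems == 4L], 10L)
    for (pid in four) {
        arr <- motifArrangement(lib, pid)
        # nest a fresh stem inside stem 1 (always IO-connected)
        pos <- match(1L, arr)
        child <- append(arr, c(5L, 5L), after = pos)
        child <- xiosfp:::.relabelArrangement(child)
        cid <- canonicalCode(xiosFromArrangement(child))
        expect_true(pid %in% motifParents(lib, cid))
    }
})

test_that("ancestors are the transitive closure floored at two stems", {
    lib <- cachedLibrary(5)
    tab <- motifTable(lib)
    m2 <- tab$motif_id[tab$n_stems == 2L]
    for (id in m2) expect_length(motifAncestors(lib, id), 0L)
    # a 3-stem motif's ancestors are exactly its 2-stem parents
    m3 <- tab$motif_id[tab$n_stems == 3L]
    for (id in m3)
        expect_setequal(motifAncestors(lib, id), motifParents(lib, id))
    # chains built by repeated stem addition have growing closures
    set.seed(36)
    arr <- c(1L, 2L, 1L, 2L)
    sizes <- integer()
    for (n in 3:5) {
        pos <- match(1L, arr)
        arr <- xiosfp:::.relabelArrangement(append(arr, c(n, n),
                                                   after = pos))
        id <- canonicalCode(xiosFromArrangement(arr))
        sizes <- c(sizes, length(motifAncestors(lib, id)))
    }
    expect_true(all(diff(sizes) > 0L))
})

test_that("library TSV round trips including memoized parents", {
    lib <- cachedLibrary(3)
    for (id in motifTable(lib)$motif_id) motifParents(lib, id)
    path <- tempfile(fileext = ".tsv")
    saveMotifLibrary(lib, path)
    lib2 <- loadMotifLibrary(path)
    expect_equal(motifTable(lib2), motifTable(lib))
    expect_equal(maxStems(lib2), 3L)
    for (id in motifTable(lib)$motif_id)
        expect_setequal(motifParents(lib2, id), motifParents(lib, id))
})
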