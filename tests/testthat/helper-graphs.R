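# shared fixtures, built in code

.libCache <- new.env()

# motif library memoized across test files (build once per run)
cachedLibrary <- function(maxStems) {
    key <- as.character(maxStems)
    if (is.null(.libCache[[key]]))
        .libCache[[key]] <- buildMotifLibrary(maxStems)
    .libCache[[key]]
}

# random connected edge-labeled graph (I with random direction, O, X);
# spanning tree plus extra random edges — exercises canonicalization on
# graphs the arrangement space cannot produce
randomLabeledGraph <- function(n, pExtra = 0.3, id = "rand") {
    from <- integer(); to <- integer(); type <- character()
    addEdge <- function(u, v) {
        lab <- sample(c("I", "Irev", "O", "X"), 1L)
        if (lab == "Irev") { tmp <- u; u <- v; v <- tmp; lab <- "I" }
        from <<- c(from, u); to <<- c(to, v); type <<- c(type, lab)
    }
    if (n > 1L) {
        for (v in 2:n) addEdge(sample.int(v - 1L, 1L), v)
        if (n > 2L) {
            for (u in 1:(n - 1L)) for (v in (u + 1L):n) {
                present <- any((from == u & to == v) | (from == v & to == u))
                if (!present && runif(1) < pExtra) addEdge(u, v)
            }
        }
    }
    new("XIOSGraph", id = id, nVertices = as.integer(n),
        edges = data.frame(from = from, to = to, type = type),
        arrangement = integer(),
        stems = data.frame(id = integer(), l1 = integer(), l2 = integer(),
                           r1 = integer(), r2 = integer()))
}

# relabel a graph's vertices by permutation p (new id of old vertex i is p[i])
permuteGraph <- function(g, p) {
    e <- edgeTable(g)
    e$from <- p[e$from]
    e$to <- p[e$to]
    new("XIOSGraph", id = graphID(g), nVertices = vertexCount(g),
        edges = e, arrangement = integer(),
        stems = data.frame(id = integer(), l1 = integer(), l2 = integer(),
                           r1 = integer(), r2 = integer()))
}

# random first-occurrence-canonical arrangement (uniform perfect matching)
randomArrangement <- function(n) {
    perm <- sample.int(2L * n)
    pairs <- matrix(perm, ncol = 2L, byrow = TRUE)
    ord <- order(pmin(pairs[, 1L], pairs[, 2L]))
    arr <- integer(2L * n)
    for (k in seq_len(n)) arr[pairs[ord[k], ]] <- k
    arr
}

# stems with real coordinates realizing an arrangement (each half-stem two
# bases wide); yields a consistent BasePairSet via stemsToPairs
stemsFromArrangement <- function(arr) {
    n <- length(arr) %/% 2L
    first <- match(seq_len(n), arr)
    second <- length(arr) + 1L - match(seq_len(n), rev(arr))
    data.frame(id = seq_len(n),
               l1 = 4L * first - 3L, l2 = 4L * first - 2L,
               r1 = 4L * second - 3L, r2 = 4L * second - 2L)
}

stemsToPairs <- function(stems) {
    len <- max(stems$r2)
    pairs <- rbind(cbind(stems$l1, stems$r2), cbind(stems$l2, stems$r1))
    new("BasePairSet", length = len,
        pairs = matrix(as.integer(pairs[order(pairs[, 1L]), ]), ncol = 2L,
                       dimnames = list(NULL, c("i", "j"))))
}

# fingerprint stub with a given motif set (for similarity arithmetic tests)
makeFp <- function(ids, kind = "simple", id = "fp") {
    counts <- rep(1L, length(ids))
    names(counts) <- ids
    new("Fingerprint", graphID = id, library = "test", motifCounts = counts,
        kind = kind, iterations = length(ids), seed = NA_integer_)
}

# brute-force table of connected induced k-subset motif codes (combn oracle)
bruteSubsetCodes <- function(g, k) {
    n <- vertexCount(g)
    if (n < k) return(character())
    subs <- utils::combn(n, k)
    codes <- character()
    for (c in seq_len(ncol(subs))) {
        sg <- xiosfp:::.inducedSubgraph(g, subs[, c])
        if (length(ioComponents(sg)) == 1L)
            codes <- c(codes, canonicalCode(sg))
    }
    codes
}
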