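#' ROC curve and AUC
#'
#' Ranks scores from high to low; pairs from the same family are positives.
#' The AUC is computed from the Mann-Whitney statistic with midranks, so
#' tied scores contribute 1/2; it is invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores numeric similarity scores, one per compared pair.
#' @param positive logical, TRUE for same-family pairs.
#' @return List with \code{auc} and \code{curve} (data.frame \code{fpr},
#'   \code{tpr}, \code{threshold}; one point per distinct score, descending).
#' @examples
#' rocAuc(c(0.9, 0.7, 0.8, 0.6), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
rocAuc <- function(scores, positive) {
    stopifnot(length(scores) == length(positive), !anyNA(scores),
              !anyNA(positive))
    positive <- as.logical(positive)
    n1 <- sum(positive)
    n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L)
        stop("need at least one positive and one negative pair")
    r <- rank(scores)   # midranks for ties
    auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    p <- positive[ord]
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(p)
    fp <- cumsum(!p)
    last <- !duplicated(grp, fromLast = TRUE)
    curve <- data.frame(fpr = c(0, fp[last] / n0),
                        tpr = c(0, tp[last] / n1),
                        threshold = c(Inf, s[last]))
    list(auc = auc, curve = curve)
}

#' Scores and labels for all unordered pairs
#'
#' @param simMatrix symmetric similarity matrix with dimnames.
#' @param families family assignment, one per row of \code{simMatrix}.
#' @return data.frame \code{id1}, \code{id2}, \code{score}, \code{positive}
#'   (same family); self-pairs excluded, each unordered pair once.
#' @export
pairScores <- function(simMatrix, families) {
    n <- nrow(simMatrix)
    stopifnot(n == ncol(simMatrix), length(families) == n)
    ids <- rownames(simMatrix)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    idx <- which(upper.tri(simMatrix), arr.ind = TRUE)
    data.frame(id1 = ids[idx[, 1L]], id2 = ids[idx[, 2L]],
               score = simMatrix[idx],
               positive = families[idx[, 1L]] == families[idx[, 2L]])
}

#' Family-classification AUC of a fingerprint set
#'
#' Convenience wrapper: similarity matrix, unordered pair scores, ROC AUC.
#'
#' @param fps list of [Fingerprint-class] objects.
#' @param families family assignment, parallel to \code{fps}.
#' @inheritParams fingerprintSimilarity
#' @return The AUC (numeric scalar).
#' @export
fingerprintAUC <- function(fps, families, method = "jaccard",
                           universe = XIOS_UNIVERSE_2_7) {
    m <- similarityMatrix(fps, method, universe)
    p <- pairScores(m, families)
    rocAuc(p$score, p$positive)$auc
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}); negative branch
#' lengths are clamped to 0. Use \code{1 - similarity} as the distance.
#'
#' @param d symmetric, zero-diagonal distance matrix.
#' @param labels tip labels (default: dimnames of \code{d}).
#' @return Newick string.
#' @export
njTree <- function(d, labels = NULL) {
    d <- as.matrix(d)
    stopifnot(nrow(d) == ncol(d), all(abs(diag(d)) < 1e-12))
    if (!is.null(labels)) rownames(d) <- colnames(d) <- labels
    if (is.null(rownames(d)))
        rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
    tr <- ape::nj(stats::as.dist(d))
    tr$edge.length[tr$edge.length < 0] <- 0
    ape::write.tree(tr)
}

# remove a given vertex index set (internal)
.dropVertices <- function(g, drop, allowEmpty = FALSE) {
    keep <- setdiff(seq_len(g@nVertices), drop)
    if (!length(keep)) {
        if (!allowEmpty) stop("vertex removal would empty the graph")
        return(new("XIOSGraph", id = g@id, nVertices = 0L,
                   edges = data.frame(from = integer(), to = integer(),
                                      type = character()),
                   arrangement = integer(),
                   stems = data.frame(id = integer(), l1 = integer(),
                                      l2 = integer(), r1 = integer(),
                                      r2 = integer())))
    }
    .inducedSubgraph(g, keep, id = g@id)
}

#' Randomly remove a fraction of stems
#'
#' Deletes round(fraction * N) uniformly chosen vertices (half-up rounding)
#' and their incident edges, emulating incomplete structure predictions.
#'
#' @param g a [XIOSGraph-class].
#' @param fraction in [0, 1).
#' @return The reduced [XIOSGraph-class] (possibly disconnected).
#' @export
removeVertices <- function(g, fraction) {
    stopifnot(is(g, "XIOSGraph"), fraction >= 0, fraction < 1)
    n <- g@nVertices
    k <- min(floor(fraction * n + 0.5), n - 1L)
    if (k < 1L) return(g)
    .dropVertices(g, sample.int(n, k))
}

#' Remove pseudoknot stems first, then random stems
#'
#' Deletes all vertices incident to an O edge, then continues deleting
#' uniformly chosen vertices until round(totalFraction * N) are gone. When
#' the pseudoknot stems alone exceed the budget, only a random subset of
#' them is removed (with a warning).
#'
#' @param g a [XIOSGraph-class].
#' @param totalFraction total fraction of vertices to remove (default 0.3).
#' @return The reduced [XIOSGraph-class]; free of O edges when the budget
#'   sufficed.
#' @export
removePseudoknots <- function(g, totalFraction = 0.3) {
    stopifnot(is(g, "XIOSGraph"), totalFraction >= 0, totalFraction <= 1)
    n <- g@nVertices
    budget <- min(floor(totalFraction * n + 0.5), n)
    if (budget < 1L) return(g)
    e <- g@edges
    overt <- sort(unique(c(e$from[e$type == "O"], e$to[e$type == "O"])))
    if (length(overt) > budget) {
        warning("pseudoknot stems (", length(overt),
                ") exceed the removal budget (", budget,
                "); removing a random subset")
        drop <- overt[sample.int(length(overt), budget)]
    } else {
        rest <- setdiff(seq_len(n), overt)
        extra <- budget - length(overt)
        drop <- c(overt,
                  if (extra > 0L) rest[sample.int(length(rest), extra)])
    }
    .dropVertices(g, drop, allowEmpty = TRUE)
}

#' Build a decoy motif database
#'
#' Exhaustively enumerates the connected induced subgraphs of 2 to 5
#' vertices in every source graph, canonicalizes them, and accumulates
#' occurrence counts — the background distribution of small motifs used to
#' pad graphs to uniform size.
#'
#' @param graphs list of [XIOSGraph-class] objects.
#' @param lib a [MotifLibrary-class] (supplies representative arrangements;
#'   must cover 5 stems).
#' @return A [DecoyDB-class].
#' @export
buildDecoyDB <- function(graphs, lib) {
    stopifnot(is(lib, "MotifLibrary"), maxStems(lib) >= 5L)
    counts <- integer()
    for (g in graphs) {
        rel <- .relMatrix(g)
        for (k in 2:5) {
            if (g@nVertices < k) next
            codes <- .esu_codes(rel, k)
            if (!length(codes)) next
            tab <- table(codes)
            for (code in names(tab)) {
                cur <- counts[code]
                counts[code] <- if (is.na(cur)) as.integer(tab[[code]])
                                else cur + as.integer(tab[[code]])
            }
        }
    }
    ids <- names(counts)
    entries <- data.frame(
        motif_id = ids,
        n_stems = vapply(ids, function(id)
            lib@motifs$n_stems[.motifRow(lib, id)], 0L),
        count = as.integer(counts),
        arrangement = vapply(ids, function(id)
            paste(motifArrangement(lib, id), collapse = ","), ""))
    rownames(entries) <- NULL
    new("DecoyDB", entries = entries)
}

#' Expand a graph to a target size with decoy motifs
#'
#' Repeatedly draws a motif from the decoy database (probability
#' proportional to count, restricted to sizes s with 2 <= s <= remaining and
#' remaining - s != 1) and splices its representative arrangement as a
#' contiguous block into the host arrangement at a uniformly chosen cut
#' point. The splice preserves the decoy's internal topology and the host
#' topology; inserted blocks land serial to or nested inside host stems.
#'
#' @param g a [XIOSGraph-class] carrying an arrangement, with at most
#'   \code{targetVertices} vertices.
#' @param db a [DecoyDB-class].
#' @param targetVertices final vertex count (default 30).
#' @return A [XIOSGraph-class] with exactly \code{targetVertices} vertices;
#'   the \code{"insertions"} attribute logs, per insertion, the motif id and
#'   the vertex labels it received in the result.
#' @export
expandGraph <- function(g, db, targetVertices = 30L) {
    stopifnot(is(g, "XIOSGraph"), is(db, "DecoyDB"))
    if (!nrow(db@entries)) stop("decoy database is empty")
    if (g@nVertices > targetVertices)
        stop("graph already larger than target")
    if (g@nVertices == targetVertices) return(g)
    if (!length(g@arrangement))
        stop("expandGraph needs a graph with an arrangement ",
             "(build from an arrangement or from X-free stems)")
    arr <- g@arrangement
    origin <- integer(length(arr))           # 0 = host block
    motifIDs <- character()
    nIns <- 0L
    n <- g@nVertices
    while (n < targetVertices) {
        remaining <- targetVertices - n
        ok <- db@entries$n_stems <= remaining &
              remaining - db@entries$n_stems != 1L
        if (!any(ok))
            stop("no decoy motif size fits the remaining budget of ",
                 remaining)
        cand <- db@entries[ok, ]
        pick <- cand[sample.int(nrow(cand), 1L, prob = cand$count), ]
        dec <- as.integer(strsplit(pick$arrangement, ",",
                                   fixed = TRUE)[[1L]])
        s <- pick$n_stems
        cut <- sample.int(length(arr) + 1L, 1L) - 1L   # 0..2n
        nIns <- nIns + 1L
        motifIDs <- c(motifIDs, pick$motif_id)
        arr <- append(arr, dec + n, after = cut)
        origin <- append(origin, rep(nIns, 2L * s), after = cut)
        n <- n + s
    }
    arr2 <- .relabelArrangement(arr)
    out <- xiosFromArrangement(arr2, id = g@id)
    ins <- lapply(seq_len(nIns), function(i) unique(arr2[origin == i]))
    attr(out, "insertions") <- data.frame(
        motif_id = motifIDs,
        vertices = I(ins))
    out
}
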