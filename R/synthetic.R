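#' Random IO-connected XIOS graph
#'
#' Draws an arrangement uniformly from the first-occurrence-canonical space
#' (equivalently, a uniform perfect matching of the 2n half-stem positions)
#' and rejects topologies that are not IO-connected.
#'
#' @param n number of stems.
#' @param id graph identifier.
#' @param maxTries rejection-sampling cap.
#' @return A [XIOSGraph-class] with an arrangement.
#' @export
randomXiosGraph <- function(n, id = "random", maxTries = 10000L) {
    stopifnot(n >= 1L)
    n <- as.integer(n)
    for (try in seq_len(maxTries)) {
        perm <- sample.int(2L * n)
        arr <- integer(2L * n)
        pairs <- matrix(perm, ncol = 2L, byrow = TRUE)
        ord <- order(pmin(pairs[, 1L], pairs[, 2L]))
        for (k in seq_len(n)) arr[pairs[ord[k], ]] <- k
        g <- xiosFromArrangement(arr, id = id)
        if (.ioConnected(g)) return(g)
    }
    stop("no IO-connected topology found in ", maxTries, " draws")
}

#' Synthetic labeled RNA topology families
#'
#' Generates \code{nFamilies} random seed topologies of \code{seedSize}
#' stems, then derives each family member by removing a fraction of the
#' seed's stems at random and re-expanding to \code{targetVertices} with
#' motifs drawn from a decoy database built from all seeds (background
#' motif distribution). At \code{perturbFraction = 0} members equal their
#' seed. Within-family fingerprints are designed to be more similar than
#' between-family ones, standing in for a curated structure set in
#' simulation studies.
#'
#' @param nFamilies number of families.
#' @param members members per family.
#' @param seedSize stems per seed topology.
#' @param perturbFraction fraction of stems removed per member.
#' @param lib a [MotifLibrary-class] covering 5 stems (for the decoy
#'   database).
#' @param targetVertices member size after re-expansion (default
#'   \code{seedSize}).
#' @return List with \code{graphs} (named list of [XIOSGraph-class]),
#'   \code{family} (character vector parallel to \code{graphs}),
#'   \code{seeds} and \code{decoyDB}.
#' @export
synthFamilies <- function(nFamilies = 8L, members = 10L, seedSize = 15L,
                          perturbFraction = 0.2, lib,
                          targetVertices = seedSize) {
    stopifnot(is(lib, "MotifLibrary"))
    seeds <- lapply(seq_len(nFamilies), function(f)
        randomXiosGraph(seedSize, id = paste0("F", f)))
    db <- buildDecoyDB(seeds, lib)
    graphs <- list()
    family <- character()
    for (f in seq_len(nFamilies)) {
        for (m in seq_len(members)) {
            gid <- sprintf("F%d_m%02d", f, m)
            g <- removeVertices(seeds[[f]], perturbFraction)
            if (g@nVertices < targetVertices)
                g <- expandGraph(g, db, targetVertices)
            g@id <- gid
            graphs[[gid]] <- g
            family <- c(family, paste0("F", f))
        }
    }
    list(graphs = graphs, family = family, seeds = seeds, decoyDB = db)
}

#' Decoy control graphs
#'
#' Graphs assembled from the decoy database only: a random 2-stem start is
#' expanded to \code{targetVertices} by decoy splicing. They carry no family
#' signal beyond the background motif distribution, so classification AUC
#' on arbitrary labels is expected near 0.5.
#'
#' @param nGraphs number of graphs.
#' @param db a [DecoyDB-class].
#' @param targetVertices vertex count of each decoy graph.
#' @return Named list of [XIOSGraph-class] objects.
#' @export
decoyGraphs <- function(nGraphs, db, targetVertices = 30L) {
    stopifnot(is(db, "DecoyDB"), nrow(db@entries) > 0L)
    two <- db@entries[db@entries$n_stems == 2L, ]
    if (!nrow(two)) stop("decoy database has no 2-stem motif")
    out <- list()
    for (i in seq_len(nGraphs)) {
        gid <- sprintf("decoy%03d", i)
        pick <- two[sample.int(nrow(two), 1L, prob = two$count), ]
        g <- xiosFromArrangement(
            as.integer(strsplit(pick$arrangement, ",", fixed = TRUE)[[1L]]),
            id = gid)
        g <- expandGraph(g, db, targetVertices)
        g@id <- gid
        out[[gid]] <- g
    }
    out
}
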