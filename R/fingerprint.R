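#' Sample a random connected subgraph
#'
#' Grows a vertex set from a uniformly chosen start vertex by repeatedly
#' adding a uniform choice among the I/O neighbors of the current set,
#' stopping at \code{n} vertices or when no neighbor exists (small
#' components yield the whole reachable component). The induced subgraph
#' keeps all edges among the chosen vertices.
#'
#' @param g a nonempty [XIOSGraph-class].
#' @param n target subgraph size.
#' @return A [XIOSGraph-class] induced on the sampled vertices (original
#'   vertex ids recorded in the \code{sampledVertices} attribute).
#' @export
sampleConnectedSubgraph <- function(g, n) {
    stopifnot(is(g, "XIOSGraph"), n >= 1L)
    if (g@nVertices < 1L) stop("cannot sample from an empty graph")
    rel <- .relMatrix(g)
    adj <- rel <= REL_O
    set <- sample.int(g@nVertices, 1L)
    while (length(set) < n) {
        nbrs <- which(apply(adj[set, , drop = FALSE], 2L, any))
        nbrs <- setdiff(nbrs, set)
        if (!length(nbrs)) break
        set <- c(set, nbrs[sample.int(length(nbrs), 1L)])
    }
    out <- .inducedSubgraph(g, set, id = paste0(g@id, "_sample"))
    attr(out, "sampledVertices") <- set
    out
}

.newFingerprint <- function(graphID, libID, counts, kind, iterations,
                            seed = NA_integer_) {
    if (length(counts)) counts <- counts[order(names(counts))]
    mc <- as.integer(counts)
    names(mc) <- names(counts)
    new("Fingerprint", graphID = graphID, library = libID,
        motifCounts = mc, kind = kind, iterations = as.integer(iterations),
        seed = as.integer(seed))
}

#' Fingerprint by random subgraph sampling
#'
#' Repeatedly samples connected subgraphs of up to \code{subgraphSize}
#' vertices, identifies each by canonical code in the motif library, and
#' counts how often each motif is drawn. Sampling stops when every motif
#' observed so far has been drawn at least \code{minCount} times (the
#' condition is re-checked after every sample, so newly discovered motifs
#' reset readiness), or at \code{maxIter} with a warning. Singleton samples
#' (isolated stems) are discarded; fingerprint motifs therefore have 2 to
#' \code{subgraphSize} stems. A graph with no I/O edge has an empty
#' fingerprint.
#'
#' @param g a [XIOSGraph-class].
#' @param lib a [MotifLibrary-class] with \code{maxStems(lib) >=
#'   subgraphSize}.
#' @param subgraphSize vertices per sample (default 7).
#' @param minCount required samples per observed motif (default 10).
#' @param maxIter sampling cap (default 1e6).
#' @param seed optional integer seed (recorded in the fingerprint).
#' @param batch samples drawn per internal call; affects speed only.
#' @return A [Fingerprint-class] of kind \code{"simple"}.
#' @export
simpleFingerprint <- function(g, lib, subgraphSize = 7L, minCount = 10L,
                              maxIter = 1e6, seed = NULL, batch = 256L) {
    stopifnot(is(g, "XIOSGraph"), is(lib, "MotifLibrary"))
    if (g@nVertices < 1L) stop("cannot fingerprint an empty graph")
    if (maxStems(lib) < subgraphSize)
        stop("library only covers ", maxStems(lib), " stems; need ",
             subgraphSize)
    if (!is.null(seed)) set.seed(seed)
    libID <- paste0("xios", maxStems(lib))
    rel <- .relMatrix(g)
    if (!any(rel <= REL_O))
        return(.newFingerprint(g@id, libID, integer(), "simple", 0L,
                               seed %||% NA_integer_))
    counts <- integer()
    iter <- 0L
    done <- FALSE
    while (!done && iter < maxIter) {
        m <- min(batch, maxIter - iter)
        codes <- .sample_codes(rel, as.integer(subgraphSize), as.integer(m))
        for (code in codes) {
            iter <- iter + 1L
            if (code == "0") next   # singleton sample: below the 2-stem floor
            cur <- counts[code]
            if (is.na(cur)) {
                if (!hasMotif(lib, code))
                    stop("sampled motif not in library (canonicalization ",
                         "inconsistency): ", code)
                counts[code] <- 1L
            } else {
                counts[code] <- cur + 1L
            }
            if (length(counts) && min(counts) >= minCount) {
                done <- TRUE
                break
            }
        }
    }
    if (!done && iter >= maxIter)
        warning("sampling stopped at maxIter = ", maxIter,
                " before all motifs reached minCount")
    .newFingerprint(g@id, libID, counts, "simple", iter,
                    seed %||% NA_integer_)
}

#' Fingerprint by exhaustive subgraph enumeration
#'
#' Enumerates every connected vertex subset of exactly
#' \code{min(subgraphSize, component size)} vertices per I/O component
#' (ESU algorithm), canonicalizes each induced subgraph, and counts the
#' number of distinct subsets mapping to each motif. Singleton components
#' are skipped. This is the deterministic oracle that sampling is validated
#' against.
#'
#' @inheritParams simpleFingerprint
#' @param maxVertices refuse larger graphs unless \code{force} (the subset
#'   count grows combinatorially).
#' @param force bypass the size guard.
#' @return A [Fingerprint-class] of kind \code{"simple"}; \code{iterations}
#'   is the number of subsets enumerated.
#' @export
exhaustiveFingerprint <- function(g, lib, subgraphSize = 7L,
                                  maxVertices = 40L, force = FALSE) {
    stopifnot(is(g, "XIOSGraph"), is(lib, "MotifLibrary"))
    if (g@nVertices < 1L) stop("cannot fingerprint an empty graph")
    if (g@nVertices > maxVertices && !force)
        stop("graph has ", g@nVertices, " vertices; exhaustive enumeration ",
             "is combinatorial — pass force = TRUE to override")
    if (maxStems(lib) < subgraphSize)
        stop("library only covers ", maxStems(lib), " stems; need ",
             subgraphSize)
    rel <- .relMatrix(g)
    counts <- integer()
    total <- 0L
    for (comp in ioComponents(g)) {
        if (length(comp) < 2L) next
        k <- min(as.integer(subgraphSize), length(comp))
        codes <- .esu_codes(rel[comp, comp, drop = FALSE], k)
        total <- total + length(codes)
        tab <- table(codes)
        for (code in names(tab)) {
            if (!hasMotif(lib, code))
                stop("enumerated motif not in library (canonicalization ",
                     "inconsistency): ", code)
            cur <- counts[code]
            counts[code] <- if (is.na(cur)) as.integer(tab[[code]])
                            else cur + as.integer(tab[[code]])
        }
    }
    .newFingerprint(g@id, paste0("xios", maxStems(lib)), counts, "simple",
                    total)
}

#' Extend a fingerprint with motif ancestors
#'
#' Adds every ancestor (parent, grandparent, ..., down to 2 stems) of every
#' fingerprint motif; added motifs get count 0. Idempotent.
#'
#' @param fp a [Fingerprint-class].
#' @param lib the [MotifLibrary-class] the fingerprint was computed with.
#' @return A [Fingerprint-class] of kind \code{"extended"}.
#' @export
extendFingerprint <- function(fp, lib) {
    stopifnot(is(fp, "Fingerprint"), is(lib, "MotifLibrary"))
    ids <- motifIDs(fp)
    anc <- unique(unlist(lapply(ids, motifAncestors, lib = lib)))
    addl <- setdiff(anc, ids)
    counts <- c(fp@motifCounts,
                stats::setNames(integer(length(addl)), addl))
    .newFingerprint(fp@graphID, fp@library, counts, "extended",
                    fp@iterations, fp@seed)
}
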