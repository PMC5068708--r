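#' Base-pair set of an RNA secondary structure
#'
#' Holds the sequence length and the set of base pairs (i, j), 1-based with
#' i < j, of one structure. Each position may occur in at most one pair.
#'
#' @slot length sequence length in nucleotides.
#' @slot pairs two-column integer matrix of pairs, one row per pair, i < j.
#' @exportClass BasePairSet
setClass("BasePairSet",
         representation(length = "integer", pairs = "matrix"))

setValidity("BasePairSet", function(object) {
    p <- object@pairs
    if (!is.numeric(p) || ncol(p) != 2L)
        return("pairs must be a two-column integer matrix")
    if (nrow(p)) {
        if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
        if (any(p < 1L) || any(p > object@length))
            return("pair positions outside 1..length")
        if (anyDuplicated(as.vector(p)))
            return("a position occurs in more than one pair")
    }
    TRUE
})

#' XIOS graph of an RNA topology
#'
#' Vertices are stems numbered 1..N. Edges carry one of three labels:
#' \code{"I"} (the \code{from} stem includes, i.e. nests, the \code{to} stem;
#' directed), \code{"O"} (overlapping = pseudoknotted; undirected) and
#' \code{"X"} (mutually exclusive; undirected). Serial stems have no edge.
#' The stem arrangement (the interleaving order of the 2N half-stems) and the
#' stem coordinates are retained when known.
#'
#' @slot id graph identifier.
#' @slot nVertices number of stems.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{type}.
#' @slot arrangement integer vector of 2N stem labels (may be empty when the
#'   graph was not built from an arrangement and has X edges).
#' @slot stems data.frame of stem coordinates (possibly 0 rows) with columns
#'   \code{id}, \code{l1}, \code{l2}, \code{r1}, \code{r2}.
#' @exportClass XIOSGraph
setClass("XIOSGraph",
         representation(id = "character", nVertices = "integer",
                        edges = "data.frame", arrangement = "integer",
                        stems = "data.frame"))

setValidity("XIOSGraph", function(object) {
    n <- object@nVertices
    e <- object@edges
    if (length(n) != 1L || is.na(n) || n < 0L) return("invalid vertex count")
    if (!all(c("from", "to", "type") %in% names(e)))
        return("edges needs columns from, to, type")
    if (nrow(e)) {
        if (!all(e$type %in% c("I", "O", "X")))
            return("edge types must be I, O or X")
        if (any(e$from == e$to)) return("self-edges are not allowed")
        if (any(e$from < 1L | e$from > n | e$to < 1L | e$to > n))
            return("edge endpoint outside 1..nVertices")
        key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
        if (anyDuplicated(key)) return("more than one edge for a vertex pair")
    }
    if (length(object@arrangement)) {
        ok <- tryCatch({ .checkArrangement(object@arrangement); TRUE },
                       error = function(e) FALSE)
        if (!ok || length(object@arrangement) != 2L * n)
            return("arrangement inconsistent with vertex count")
    }
    TRUE
})

#' Library of unique IO-connected stem topologies
#'
#' All isomorphism classes (motifs) of IO-connected topologies with
#' 1..\code{maxStems} stems, indexed by canonical code. Parent and ancestor
#' relations are computed lazily and memoized.
#'
#' @slot motifs data.frame with columns \code{motif_id} (canonical code),
#'   \code{n_stems} and \code{arrangement} (comma-joined representative).
#' @slot maxStems largest stem count enumerated.
#' @slot index environment mapping motif_id to row number.
#' @slot parents environment caching parent motif ids per motif.
#' @slot ancestors environment caching ancestor closures per motif.
#' @exportClass MotifLibrary
setClass("MotifLibrary",
         representation(motifs = "data.frame", maxStems = "integer",
                        index = "environment", parents = "environment",
                        ancestors = "environment"))

#' Fingerprint of a XIOS graph
#'
#' The set of library motifs found in a graph, with the number of times each
#' was sampled (exhaustive fingerprints count distinct vertex subsets;
#' motifs added by ancestor extension carry count 0).
#'
#' @slot graphID identifier of the fingerprinted graph.
#' @slot library identifier of the motif library used.
#' @slot motifCounts named integer vector, names are motif ids.
#' @slot kind \code{"simple"} or \code{"extended"}.
#' @slot iterations samples drawn (sampling) or subsets enumerated
#'   (exhaustive).
#' @slot seed RNG seed used, or NA.
#' @exportClass Fingerprint
setClass("Fingerprint",
         representation(graphID = "character", library = "character",
                        motifCounts = "integer", kind = "character",
                        iterations = "integer", seed = "integer"))

setValidity("Fingerprint", function(object) {
    if (!object@kind %in% c("simple", "extended"))
        return("kind must be 'simple' or 'extended'")
    mc <- object@motifCounts
    if (length(mc) && (is.null(names(mc)) || anyDuplicated(names(mc))))
        return("motifCounts must have unique names")
    TRUE
})

#' Decoy motif database
#'
#' Occurrence counts of all connected induced subgraphs of 2..5 stems found
#' in a set of source graphs; used to expand graphs to uniform size for the
#' size-artifact control. Sampling draws motifs with probability proportional
#' to count.
#'
#' @slot entries data.frame with columns \code{motif_id}, \code{n_stems},
#'   \code{count}, \code{arrangement} (comma-joined representative).
#' @exportClass DecoyDB
setClass("DecoyDB", representation(entries = "data.frame"))

setValidity("DecoyDB", function(object) {
    e <- object@entries
    if (!all(c("motif_id", "n_stems", "count", "arrangement") %in% names(e)))
        return("entries needs motif_id, n_stems, count, arrangement")
    if (nrow(e) && (any(e$count < 1L) ||
                    any(e$n_stems < 2L) || any(e$n_stems > 5L)))
        return("entries must have counts >= 1 and 2..5 stems")
    TRUE
})
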