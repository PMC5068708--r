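#' Relationship between two stems
#'
#' Classifies an ordered stem pair into one of the four XIOS relationships.
#' With a starting before b (a$l1 < b$l1): \code{S} (serial) when b starts
#' after a ends; \code{I} (a includes b) when b lies entirely within a's
#' loop; \code{O} (overlapping/pseudoknot) when b's left half is inside a's
#' loop but its right half reaches beyond a; \code{X} otherwise (shared bases
#' or interleaved half-stems). Use [stemRelation()] when the stems are not
#' pre-ordered.
#'
#' @param a,b stems: lists or one-row data.frames with fields \code{l1},
#'   \code{l2}, \code{r1}, \code{r2}; \code{a$l1 < b$l1} is required.
#' @return One of \code{"S"}, \code{"I"}, \code{"O"}, \code{"X"}; for
#'   \code{"I"} the first argument is the including stem.
#' @examples
#' a <- list(l1 = 1, l2 = 2, r1 = 5, r2 = 6)
#' b <- list(l1 = 3, l2 = 4, r1 = 8, r2 = 9)
#' classifyEdge(a, b)  # "O": a simple pseudoknot
#' @export
classifyEdge <- function(a, b) {
    if (a$l1 == b$l1 && a$l2 == b$l2 && a$r1 == b$r1 && a$r2 == b$r2)
        stop("cannot classify identical stems")
    if (!(a$l1 < b$l1))
        stop("classifyEdge requires a$l1 < b$l1; use stemRelation() instead")
    if (b$l1 > a$r2) return("S")
    if (b$l1 > a$l2 && b$r2 < a$r1) return("I")
    if (b$l1 > a$l2 && b$l2 < a$r1 && b$r1 > a$r2) return("O")
    "X"
}

#' @rdname classifyEdge
#' @return \code{stemRelation}: a list with \code{type} and, for I edges,
#'   \code{container} (1 if \code{a} includes \code{b}, 2 otherwise).
#' @export
stemRelation <- function(a, b) {
    if (a$l1 == b$l1)
        return(list(type = "X", container = NA_integer_))
    swapped <- a$l1 > b$l1
    type <- if (swapped) classifyEdge(b, a) else classifyEdge(a, b)
    container <- if (type == "I") { if (swapped) 2L else 1L } else NA_integer_
    list(type = type, container = container)
}

#' Build a XIOS graph from stems
#'
#' One vertex per stem; every pair classified I, O or X gets an edge (I
#' directed container to contained); serial pairs have no edge.
#'
#' @param stems data.frame as returned by [pairsToStems()].
#' @param id graph identifier.
#' @return A [XIOSGraph-class].
#' @export
xiosFromStems <- function(stems, id = "xios") {
    n <- nrow(stems)
    from <- integer(); to <- integer(); type <- character()
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                r <- stemRelation(stems[i, ], stems[j, ])
                if (r$type == "S") next
                if (r$type == "I" && identical(r$container, 2L)) {
                    from <- c(from, j); to <- c(to, i)
                } else {
                    from <- c(from, i); to <- c(to, j)
                }
                type <- c(type, r$type)
            }
        }
    }
    st <- stems
    st$id <- seq_len(n)
    rownames(st) <- NULL
    arr <- integer()
    if (n && !any(type == "X")) {
        # half-stem interleaving: order of left starts and right starts
        ev <- order(c(st$l1, st$r1))
        arr <- rep(st$id, 2L)[ev]
        arr <- .relabelArrangement(arr)
    }
    new("XIOSGraph", id = id, nVertices = as.integer(n),
        edges = data.frame(from = from, to = to, type = type),
        arrangement = arr, stems = st)
}

.checkArrangement <- function(arr) {
    arr <- as.integer(arr)
    if (!length(arr) || length(arr) %% 2L != 0L)
        stop("arrangement must have even length")
    n <- length(arr) %/% 2L
    tab <- tabulate(arr, nbins = max(arr))
    if (length(tab) != n || !all(tab == 2L))
        stop("arrangement must contain each of 1..N exactly twice")
    first <- match(seq_len(n), arr)
    if (is.unsorted(first, strictly = TRUE))
        stop("first occurrences must appear in ascending label order")
    arr
}

# renumber labels so that first occurrences ascend 1..N
.relabelArrangement <- function(arr) {
    lab <- unique(arr)
    match(arr, lab)
}

#' Build a XIOS graph from a stem arrangement
#'
#' An arrangement is an ordered list of 2N labels, each stem appearing twice
#' (its two half-stems), with first occurrences in ascending label order; it
#' fully encodes an N-stem topology. For labels j, k with first(j) <
#' first(k): j includes k (edge I) when k closes before j; they overlap
#' (edge O) when j closes between k's two halves; they are serial (no edge)
#' when j closes before k opens.
#'
#' @param arr integer vector of 2N labels.
#' @param id graph identifier.
#' @return A [XIOSGraph-class] (only I and O edges can occur).
#' @examples
#' g <- xiosFromArrangement(c(1, 2, 3, 2, 3, 1))
#' edgeTable(g)  # I(1->2), I(1->3), O(2,3)
#' @export
xiosFromArrangement <- function(arr, id = "xios") {
    arr <- .checkArrangement(arr)
    n <- length(arr) %/% 2L
    rel <- .arrangement_rel(arr)
    .graphFromRel(rel, id = id, arrangement = arr)
}

# build an XIOSGraph from a relation matrix (internal)
.graphFromRel <- function(rel, id = "xios", arrangement = integer(),
                          stems = NULL) {
    n <- nrow(rel)
    from <- integer(); to <- integer(); type <- character()
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                r <- rel[i, j]
                if (r == REL_NONE) next
                if (r == REL_I_IN) {
                    from <- c(from, j); to <- c(to, i); type <- c(type, "I")
                } else {
                    from <- c(from, i); to <- c(to, j)
                    type <- c(type, c("I", "", "O", "X")[r + 1L])
                }
            }
        }
    }
    if (is.null(stems))
        stems <- data.frame(id = integer(), l1 = integer(), l2 = integer(),
                            r1 = integer(), r2 = integer())
    new("XIOSGraph", id = id, nVertices = as.integer(n),
        edges = data.frame(from = from, to = to, type = type),
        arrangement = as.integer(arrangement), stems = stems)
}

# relation matrix of a graph (internal); codes as in src/canonical.cpp
.relMatrix <- function(g) {
    n <- g@nVertices
    rel <- matrix(REL_NONE, n, n)
    e <- g@edges
    if (nrow(e)) {
        for (k in seq_len(nrow(e))) {
            u <- e$from[k]; v <- e$to[k]
            if (e$type[k] == "I") {
                rel[u, v] <- REL_I_OUT
                rel[v, u] <- REL_I_IN
            } else if (e$type[k] == "O") {
                rel[u, v] <- rel[v, u] <- REL_O
            } else {
                rel[u, v] <- rel[v, u] <- REL_X
            }
        }
    }
    diag(rel) <- REL_NONE
    rel
}

#' Mirror image of an arrangement
#'
#' Reverses the half-stem order and renumbers labels so first occurrences
#' ascend. The mirrored arrangement encodes an isomorphic XIOS graph (the
#' structure read 3' to 5').
#'
#' @param arr integer arrangement vector.
#' @return The mirrored arrangement.
#' @examples
#' mirrorArrangement(c(1, 2, 1, 3, 3, 2))  # (1, 2, 2, 3, 1, 3)
#' @export
mirrorArrangement <- function(arr) {
    arr <- .checkArrangement(arr)
    .relabelArrangement(rev(arr))
}

#' Connected components under I and O edges
#'
#' I/O reachability partitions the stems; X edges do not connect (graphs in
#' scope have none anyway) and the I direction is ignored.
#'
#' @param g a [XIOSGraph-class].
#' @return List of integer vertex vectors, one per component.
#' @export
ioComponents <- function(g) {
    stopifnot(is(g, "XIOSGraph"))
    n <- g@nVertices
    if (!n) return(list())
    rel <- .relMatrix(g)
    adj <- rel <= REL_O   # I (either direction) or O
    comp <- integer(n)
    nc <- 0L
    for (s in seq_len(n)) {
        if (comp[s]) next
        nc <- nc + 1L
        queue <- s
        comp[s] <- nc
        while (length(queue)) {
            v <- queue[1L]
            queue <- queue[-1L]
            nb <- which(adj[v, ] & comp == 0L)
            comp[nb] <- nc
            queue <- c(queue, nb)
        }
    }
    split(seq_len(n), comp)
}

# TRUE if the whole graph is one I/O component (internal)
.ioConnected <- function(g) length(ioComponents(g)) <= 1L

# induced subgraph on a vertex subset. When the host carries an arrangement,
# vertices are renumbered by first occurrence so the induced arrangement is
# again first-occurrence canonical; otherwise subset order is kept.
.inducedSubgraph <- function(g, vertices, id = g@id) {
    vertices <- as.integer(vertices)
    arr <- integer()
    if (length(g@arrangement)) {
        keepPos <- g@arrangement %in% vertices
        kept <- g@arrangement[keepPos]
        vertices <- unique(kept)            # first-occurrence order
        arr <- match(kept, vertices)
    }
    rel <- .relMatrix(g)[vertices, vertices, drop = FALSE]
    stems <- data.frame(id = integer(), l1 = integer(), l2 = integer(),
                        r1 = integer(), r2 = integer())
    if (nrow(g@stems)) {
        stems <- g@stems[match(vertices, g@stems$id), ]
        stems$id <- seq_along(vertices)
        rownames(stems) <- NULL
    }
    .graphFromRel(rel, id = id, arrangement = arr, stems = stems)
}
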