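#' Canonical code of a XIOS graph
#'
#' Computes a canonical labeling such that two graphs have equal codes if and
#' only if they are isomorphic, respecting edge labels and the direction of
#' I (containment) edges. The code is the lexicographically minimal
#' adjacency encoding over all vertex orderings (found by branch-and-bound),
#' rendered as edge triples \code{"u.v.L|"} with vertices renumbered
#' 1..N in canonical order and labels \code{i} (u includes v), \code{j}
#' (v includes u), \code{o} (pseudoknot), \code{x} (exclusive). A single
#' vertex has the defined code \code{"0"}. The code string indexes the motif
#' library and appears as \code{motif_id} in fingerprints.
#'
#' @param g a [XIOSGraph-class]; must be connected under I, O and X edges
#'   (canonicalize per component otherwise).
#' @return Canonical code string.
#' @examples
#' canonicalCode(xiosFromArrangement(c(1, 2, 1, 3, 3, 2))) ==
#'     canonicalCode(xiosFromArrangement(c(1, 2, 2, 3, 1, 3)))
#' @export
canonicalCode <- function(g) {
    stopifnot(is(g, "XIOSGraph"))
    n <- g@nVertices
    if (n < 1L) stop("canonicalCode needs at least one vertex")
    rel <- .relMatrix(g)
    if (!.relConnected(rel))
        stop("graph is not connected; canonicalize per component ",
             "(see ioComponents)")
    .min_code_rel(rel)
}

# connectivity over any edge type (internal)
.relConnected <- function(rel) {
    n <- nrow(rel)
    if (n <= 1L) return(TRUE)
    adj <- rel != REL_NONE
    seen <- logical(n)
    seen[1L] <- TRUE
    queue <- 1L
    while (length(queue)) {
        v <- queue[1L]
        queue <- queue[-1L]
        nb <- which(adj[v, ] & !seen)
        seen[nb] <- TRUE
        queue <- c(queue, nb)
    }
    all(seen)
}

#' Parse a canonical code string into edge tuples
#'
#' @param code canonical code string as returned by [canonicalCode()].
#' @return data.frame with columns \code{u}, \code{v}, \code{label}; zero
#'   rows for the single-vertex code \code{"0"}.
#' @export
parseCanonicalCode <- function(code) {
    if (identical(code, "0"))
        return(data.frame(u = integer(), v = integer(), label = character()))
    parts <- strsplit(strsplit(code, "|", fixed = TRUE)[[1L]], ".",
                      fixed = TRUE)
    data.frame(u = vapply(parts, function(p) as.integer(p[1L]), 0L),
               v = vapply(parts, function(p) as.integer(p[2L]), 0L),
               label = vapply(parts, function(p) p[3L], ""))
}

#' Brute-force graph isomorphism oracle
#'
#' Exhaustive search over all vertex bijections for a label- and
#' I-direction-preserving mapping. Exponential; intended as an independent
#' verification oracle for [canonicalCode()] on small graphs.
#'
#' @param g1,g2 [XIOSGraph-class] objects with at most 8 vertices each.
#' @return TRUE if the graphs are isomorphic.
#' @export
isIsomorphicOracle <- function(g1, g2) {
    stopifnot(is(g1, "XIOSGraph"), is(g2, "XIOSGraph"))
    n <- g1@nVertices
    if (n > 8L || g2@nVertices > 8L)
        stop("isIsomorphicOracle supports at most 8 vertices")
    if (n != g2@nVertices) return(FALSE)
    if (n == 0L) return(TRUE)
    r1 <- .relMatrix(g1)
    r2 <- .relMatrix(g2)
    perms <- .allPermutations(n)
    for (k in seq_len(nrow(perms))) {
        p <- perms[k, ]
        if (all(r1 == r2[p, p, drop = FALSE])) return(TRUE)
    }
    FALSE
}

.allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPermutations(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (pos in seq_len(n)) {
        block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                       sub[, seq(pos, n - 1L)[seq_len(n - pos)],
                           drop = FALSE])
        out[r + seq_len(nrow(sub)), ] <- block
        r <- r + nrow(sub)
    }
    out
}
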