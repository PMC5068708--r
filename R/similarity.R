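#' Fingerprint set-similarity functions
#'
#' Compares the motif sets X and Y of two fingerprints (presence/absence
#' only; sample counts are ignored) with one of five functions:
#' \describe{
#'   \item{intersection}{|X n Y|}
#'   \item{cosine}{|X n Y| / sqrt(|X| |Y|)}
#'   \item{dice}{2 |X n Y| / (|X| + |Y|)}
#'   \item{hamming}{|X n Y| + |complement of (X u Y)| over a universe of
#'     \code{universe} motifs — the number of motifs on which the two
#'     fingerprints agree}
#'   \item{jaccard}{|X n Y| / |X u Y|}
#' }
#' Two empty fingerprints are defined as identical (normalized similarity
#' 1); one empty fingerprint gives 0 for jaccard/cosine/dice. The Hamming
#' universe defaults to 55,728, the number of motifs with 2 to 7 stems; the
#' universe is constant within a comparison batch, so rankings do not depend
#' on the choice.
#'
#' @param x,y [Fingerprint-class] objects of the same kind.
#' @param method similarity function.
#' @param universe Hamming universe size U (>= |X u Y|).
#' @return One-row data.frame: \code{method}, \code{value}, \code{size_x},
#'   \code{size_y}, \code{intersection}, \code{universe} (NA unless
#'   hamming).
#' @examples
#' # X = {a, b}, Y = {b, c}: jaccard 1/3, dice 1/2, cosine 1/2
#' @export
fingerprintSimilarity <- function(x, y,
                                  method = c("jaccard", "intersection",
                                             "cosine", "dice", "hamming"),
                                  universe = XIOS_UNIVERSE_2_7) {
    method <- match.arg(method)
    stopifnot(is(x, "Fingerprint"), is(y, "Fingerprint"))
    if (x@kind != y@kind)
        stop("cannot compare a ", x@kind, " with a ", y@kind,
             " fingerprint")
    X <- motifIDs(x)
    Y <- motifIDs(y)
    .setSimilarity(X, Y, method, universe)
}

.setSimilarity <- function(X, Y, method, universe) {
    ni <- length(intersect(X, Y))
    nu <- length(union(X, Y))
    nx <- length(X)
    ny <- length(Y)
    value <- switch(method,
        intersection = ni,
        cosine = if (nx == 0L && ny == 0L) 1
                 else if (nx == 0L || ny == 0L) 0
                 else ni / sqrt(nx * ny),
        dice = if (nx == 0L && ny == 0L) 1 else 2 * ni / (nx + ny),
        jaccard = if (nu == 0L) 1 else ni / nu,
        hamming = {
            if (universe < nu)
                stop("hamming universe (", universe,
                     ") smaller than |X u Y| = ", nu)
            universe - nu + ni
        })
    data.frame(method = method, value = as.numeric(value), size_x = nx,
               size_y = ny, intersection = ni,
               universe = if (method == "hamming") universe else NA_integer_)
}

#' Pairwise similarity matrix
#'
#' @param fps list of [Fingerprint-class] objects (same kind); names (or
#'   graph ids) become dimnames.
#' @inheritParams fingerprintSimilarity
#' @return Symmetric numeric matrix with self-similarity on the diagonal.
#' @export
similarityMatrix <- function(fps, method = c("jaccard", "intersection",
                                             "cosine", "dice", "hamming"),
                             universe = XIOS_UNIVERSE_2_7) {
    method <- match.arg(method)
    n <- length(fps)
    ids <- names(fps)
    if (is.null(ids)) ids <- vapply(fps, graphID, "")
    sets <- lapply(fps, motifIDs)
    kinds <- unique(vapply(fps, fingerprintKind, ""))
    if (length(kinds) > 1L)
        stop("fingerprints must all be the same kind")
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
        for (j in i:n) {
            v <- .setSimilarity(sets[[i]], sets[[j]], method,
                                universe)$value
            m[i, j] <- m[j, i] <- v
        }
    }
    m
}
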