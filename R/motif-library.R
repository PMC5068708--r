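#' Enumerate all first-occurrence-canonical stem arrangements
#'
#' Generates every ordered list of 2n labels in which each label 1..n occurs
#' twice and first occurrences ascend — equivalently every perfect matching
#' of 2n positions — exactly once. There are (2n-1)!! such arrangements.
#'
#' @param n number of stems.
#' @param cap largest permitted n (combinatorial guard, default 7).
#' @return integer matrix with one arrangement per row.
#' @examples
#' enumerateArrangements(2)  # (1,1,2,2), (1,2,1,2), (1,2,2,1)
#' @export
enumerateArrangements <- function(n, cap = 7L) {
    if (n < 1L || n > cap)
        stop("n must be in 1..", cap)
    n <- as.integer(n)
    total <- prod(seq(1L, 2L * n - 1L, by = 2L))
    out <- matrix(0L, total, 2L * n)
    seqv <- integer(2L * n)
    row <- 0L
    rec <- function(label, free) {
        p <- free[1L]
        rest <- free[-1L]
        for (qi in seq_along(rest)) {
            seqv[c(p, rest[qi])] <<- label
            if (length(rest) == 1L) {
                row <<- row + 1L
                out[row, ] <<- seqv
            } else {
                rec(label + 1L, rest[-qi])
            }
        }
    }
    rec(1L, seq_len(2L * n))
    out
}

#' Build the library of unique IO-connected topologies
#'
#' Enumerates all arrangements for 1..\code{maxStems} stems, derives I/O
#' edges, discards topologies that are not IO-connected, and deduplicates by
#' canonical code. Each motif keeps the first arrangement that produced it as
#' its representative. Parent/ancestor relations are computed lazily by
#' [motifParents()] and [motifAncestors()].
#'
#' @param maxStems largest stem count to enumerate (1..7).
#' @return A [MotifLibrary-class].
#' @examples
#' lib <- buildMotifLibrary(4)
#' table(motifTable(lib)$n_stems)  # 1, 2, 8, 46
#' @export
buildMotifLibrary <- function(maxStems = 7L) {
    if (maxStems < 1L || maxStems > 7L) stop("maxStems must be in 1..7")
    maxStems <- as.integer(maxStems)
    tabs <- vector("list", maxStems)
    for (n in seq_len(maxStems)) {
        arrs <- enumerateArrangements(n)
        codes <- .arrangement_codes(arrs)
        keep <- which(!is.na(codes) & !duplicated(codes))
        tabs[[n]] <- data.frame(
            motif_id = codes[keep],
            n_stems = n,
            arrangement = apply(arrs[keep, , drop = FALSE], 1L, paste,
                                collapse = ","))
    }
    motifs <- do.call(rbind, tabs)
    rownames(motifs) <- NULL
    index <- new.env(hash = TRUE, parent = emptyenv())
    for (k in seq_len(nrow(motifs))) assign(motifs$motif_id[k], k, index)
    new("MotifLibrary", motifs = motifs, maxStems = maxStems, index = index,
        parents = new.env(hash = TRUE, parent = emptyenv()),
        ancestors = new.env(hash = TRUE, parent = emptyenv()))
}

# library row number of a motif, or error (internal)
.motifRow <- function(lib, motifID) {
    row <- mget(motifID, envir = lib@index, ifnotfound = list(NULL))[[1L]]
    if (is.null(row)) stop("motif '", motifID, "' is not in the library")
    row
}

#' @rdname buildMotifLibrary
#' @param lib a [MotifLibrary-class].
#' @param motifID canonical code of a library motif.
#' @return \code{hasMotif}: TRUE if the code is a library motif.
#' @export
hasMotif <- function(lib, motifID) {
    !is.null(mget(motifID, envir = lib@index,
                  ifnotfound = list(NULL))[[1L]])
}

#' @rdname buildMotifLibrary
#' @return \code{motifArrangement}: the representative arrangement (integer
#'   vector) of a motif.
#' @export
motifArrangement <- function(lib, motifID) {
    row <- .motifRow(lib, motifID)
    as.integer(strsplit(lib@motifs$arrangement[row], ",", fixed = TRUE)[[1L]])
}

#' Parent motifs
#'
#' The parents of an n-stem motif are the distinct (n-1)-stem motifs obtained
#' by deleting one stem such that the remainder stays IO-connected; every
#' connected graph has at least one non-cut vertex, so every motif with 2 or
#' more stems has at least one parent. Results are memoized in the library.
#'
#' @param lib a [MotifLibrary-class].
#' @param motifID canonical code of a library motif.
#' @return Character vector of parent motif ids (empty for the 1-stem motif).
#' @export
motifParents <- function(lib, motifID) {
    cached <- mget(motifID, envir = lib@parents,
                   ifnotfound = list(NULL))[[1L]]
    if (!is.null(cached)) return(cached)
    row <- .motifRow(lib, motifID)
    if (lib@motifs$n_stems[row] < 2L) {
        assign(motifID, character(), lib@parents)
        return(character())
    }
    rel <- .arrangement_rel(motifArrangement(lib, motifID))
    codes <- .parent_codes_rel(rel)
    for (code in codes) .motifRow(lib, code)  # must all be library motifs
    assign(motifID, codes, lib@parents)
    codes
}

#' Ancestor motifs
#'
#' Transitive closure of [motifParents()], floored at 2 stems: the 1-stem
#' motif is an ancestor of everything and carries no discriminative signal,
#' so it is excluded (as it is from fingerprints and the Hamming universe).
#'
#' @inheritParams motifParents
#' @return Character vector of ancestor motif ids (2 stems and larger).
#' @export
motifAncestors <- function(lib, motifID) {
    cached <- mget(motifID, envir = lib@ancestors,
                   ifnotfound = list(NULL))[[1L]]
    if (!is.null(cached)) return(cached)
    parents <- motifParents(lib, motifID)
    parents <- parents[vapply(parents, function(p)
        lib@motifs$n_stems[.motifRow(lib, p)] >= 2L, TRUE)]
    anc <- parents
    for (p in parents) anc <- union(anc, motifAncestors(lib, p))
    assign(motifID, anc, lib@ancestors)
    anc
}

#' Save and load a motif library as TSV
#'
#' Columns: motif_id, n_stems, arrangement (comma-joined), parent_ids
#' (semicolon-joined; empty when not yet computed). A header comment line
#' records the stem cap and format version. Round-trips the library
#' including any memoized parent sets.
#'
#' @param lib a [MotifLibrary-class].
#' @param path file path.
#' @export
saveMotifLibrary <- function(lib, path) {
    ids <- lib@motifs$motif_id
    parents <- vapply(ids, function(id) {
        p <- mget(id, envir = lib@parents, ifnotfound = list(NULL))[[1L]]
        if (is.null(p)) "" else paste(p, collapse = ";")
    }, "")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# xiosfp motif library\tmax_stems=", lib@maxStems,
                      "\tversion=1"), con)
    writeLines("motif_id\tn_stems\tarrangement\tparent_ids", con)
    writeLines(paste(ids, lib@motifs$n_stems, lib@motifs$arrangement,
                     parents, sep = "\t"), con)
    invisible(path)
}

#' @rdname saveMotifLibrary
#' @return \code{loadMotifLibrary}: the restored [MotifLibrary-class].
#' @export
loadMotifLibrary <- function(path) {
    lines <- readLines(path)
    hdr <- lines[1L]
    if (!startsWith(hdr, "# xiosfp motif library"))
        stop("not a xiosfp motif library file")
    maxStems <- as.integer(sub(".*max_stems=([0-9]+).*", "\\1", hdr))
    tab <- read.delim(text = lines[-1L], colClasses =
                      c("character", "integer", "character", "character"))
    motifs <- tab[, c("motif_id", "n_stems", "arrangement")]
    index <- new.env(hash = TRUE, parent = emptyenv())
    for (k in seq_len(nrow(motifs))) assign(motifs$motif_id[k], k, index)
    parents <- new.env(hash = TRUE, parent = emptyenv())
    pid <- tab$parent_ids
    pid[is.na(pid)] <- ""
    for (k in seq_len(nrow(tab))) {
        if (nzchar(pid[k]))
            assign(motifs$motif_id[k],
                   strsplit(pid[k], ";", fixed = TRUE)[[1L]], parents)
        else if (motifs$n_stems[k] == 1L)
            assign(motifs$motif_id[k], character(), parents)
    }
    new("MotifLibrary", motifs = motifs, maxStems = maxStems, index = index,
        parents = parents,
        ancestors = new.env(hash = TRUE, parent = emptyenv()))
}
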