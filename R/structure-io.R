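#' Parse an RNA secondary structure into a base-pair set
#'
#' Reads one structure in CT (Zuker/mfold 6-column), BPSEQ (3-column) or
#' extended dot-bracket format and returns the set of base pairs. Extended
#' dot-bracket may use the nested bracket alphabets \code{() [] {} <>} and
#' letter pairs \code{Aa, Bb, ...} for pseudoknot layers; each bracket class
#' is matched independently. Sequence letters in CT/BPSEQ records are parsed
#' but ignored (only the topology is retained).
#'
#' @param text character: the structure, either as a single string or a
#'   vector of lines. For dot-bracket, a FASTA-style header line (\code{>})
#'   and a preceding sequence line (letters \code{ACGTUN} only) are skipped.
#' @param format one of \code{"dotbracket"}, \code{"ct"}, \code{"bpseq"}.
#' @return A [BasePairSet-class] object.
#' @examples
#' bp <- parseStructure("((..[[..))..]]", "dotbracket")
#' bp@pairs
#' @export
parseStructure <- function(text, format = c("dotbracket", "ct", "bpseq")) {
    format <- match.arg(format)
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
    switch(format,
           dotbracket = .parseDotBracket(lines),
           ct = .parseCT(lines),
           bpseq = .parseBPSEQ(lines))
}

# opening/closing characters per pseudoknot layer, in assignment order
.BRACKET_OPEN <- c("(", "[", "{", "<", LETTERS)
.BRACKET_CLOSE <- c(")", "]", "}", ">", letters)

.parseDotBracket <- function(lines) {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
    if (!length(lines)) stop("dot-bracket input is empty")
    struct <- lines[1L]
    if (length(lines) >= 2L && grepl("^[ACGTUNacgtun]+$", lines[1L]))
        struct <- lines[2L]
    chars <- strsplit(struct, "")[[1L]]
    n <- length(chars)
    stacks <- vector("list", length(.BRACKET_OPEN))
    np <- 0L
    out <- matrix(0L, n %/% 2L, 2L)
    for (p in seq_len(n)) {
        ch <- chars[p]
        if (ch %in% c(".", ",", ":", "-", "_", "~")) next
        k <- match(ch, .BRACKET_OPEN)
        if (!is.na(k)) {
            stacks[[k]] <- c(stacks[[k]], p)
            next
        }
        k <- match(ch, .BRACKET_CLOSE)
        if (is.na(k))
            stop("unknown character '", ch, "' at position ", p,
                 " in dot-bracket string")
        st <- stacks[[k]]
        if (!length(st))
            stop("unbalanced bracket '", ch, "' at position ", p)
        i <- st[length(st)]
        stacks[[k]] <- st[-length(st)]
        np <- np + 1L
        out[np, ] <- c(i, p)
    }
    open <- vapply(stacks, length, 0L)
    if (any(open > 0L))
        stop("unbalanced brackets: ", sum(open), " unclosed")
    .basePairSet(n, out[seq_len(np), , drop = FALSE])
}

.numField <- function(x, line, what) {
    v <- suppressWarnings(as.integer(x))
    if (any(is.na(v)))
        stop("non-numeric ", what, " on line ", line)
    v
}

.parseCT <- function(lines) {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 1L) stop("CT input is empty")
    hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    n <- .numField(hdr[1L], 1L, "length field in CT header")
    body <- lines[-1L]
    if (length(body) != n)
        stop("CT header declares ", n, " positions but ", length(body),
             " records follow")
    pairs <- matrix(0L, n, 2L)
    np <- 0L
    seen <- integer(n)
    for (k in seq_along(body)) {
        f <- strsplit(trimws(body[k]), "[[:space:]]+")[[1L]]
        if (length(f) < 6L)
            stop("CT record with fewer than 6 fields on line ", k + 1L)
        i <- .numField(f[1L], k + 1L, "position field")
        j <- .numField(f[5L], k + 1L, "pairing field")
        if (i != k) stop("CT positions out of order on line ", k + 1L)
        if (j == 0L) next
        if (j < 1L || j > n)
            stop("pairing partner outside sequence on line ", k + 1L)
        if (seen[i] && seen[i] != j)
            stop("position ", i, " claimed by two pairs (line ", k + 1L, ")")
        if (seen[j] && seen[j] != i)
            stop("position ", j, " claimed by two pairs (line ", k + 1L, ")")
        seen[i] <- j
        seen[j] <- i
        if (i < j) {
            np <- np + 1L
            pairs[np, ] <- c(i, j)
        }
    }
    .basePairSet(n, pairs[seq_len(np), , drop = FALSE])
}

.parseBPSEQ <- function(lines) {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("BPSEQ input is empty")
    n <- length(lines)
    pairs <- matrix(0L, n, 2L)
    np <- 0L
    seen <- integer(n)
    for (k in seq_along(lines)) {
        f <- strsplit(lines[k], "[[:space:]]+")[[1L]]
        if (length(f) < 3L)
            stop("BPSEQ record with fewer than 3 fields on line ", k)
        i <- .numField(f[1L], k, "position field")
        j <- .numField(f[3L], k, "pairing field")
        if (i != k) stop("BPSEQ positions out of order on line ", k)
        if (j == 0L) next
        if (j < 1L || j > n)
            stop("pairing partner outside sequence on line ", k)
        if (seen[i] && seen[i] != j)
            stop("position ", i, " claimed by two pairs (line ", k, ")")
        if (seen[j] && seen[j] != i)
            stop("position ", j, " claimed by two pairs (line ", k, ")")
        seen[i] <- j
        seen[j] <- i
        if (i < j) {
            np <- np + 1L
            pairs[np, ] <- c(i, j)
        }
    }
    .basePairSet(n, pairs[seq_len(np), , drop = FALSE])
}

.basePairSet <- function(length, pairs) {
    pairs <- matrix(as.integer(pairs), ncol = 2L,
                    dimnames = list(NULL, c("i", "j")))
    if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    new("BasePairSet", length = as.integer(length), pairs = pairs)
}

#' Serialize a base-pair set
#'
#' Inverse of [parseStructure()]: writes a [BasePairSet-class] in any of the
#' three supported formats. Bases are emitted as \code{N} (the topology does
#' not retain sequence). Dot-bracket output assigns crossing pairs greedily
#' to the first pseudoknot layer that keeps every layer internally nested.
#'
#' @param bp a [BasePairSet-class].
#' @param format output format.
#' @return character vector of lines (dot-bracket: a single string).
#' @export
writeStructure <- function(bp, format = c("dotbracket", "ct", "bpseq")) {
    format <- match.arg(format)
    stopifnot(is(bp, "BasePairSet"))
    n <- bp@length
    p <- bp@pairs
    if (format == "bpseq") {
        j <- integer(n)
        j[p[, 1L]] <- p[, 2L]
        j[p[, 2L]] <- p[, 1L]
        return(paste(seq_len(n), "N", j))
    }
    if (format == "ct") {
        j <- integer(n)
        j[p[, 1L]] <- p[, 2L]
        j[p[, 2L]] <- p[, 1L]
        i <- seq_len(n)
        return(c(paste(n, "xiosfp"),
                 paste(i, "N", i - 1L, ifelse(i == n, 0L, i + 1L), j, i)))
    }
    chars <- rep(".", n)
    layerPairs <- list()
    if (nrow(p)) {
        ord <- order(p[, 1L])
        for (r in ord) {
            i <- p[r, 1L]; j <- p[r, 2L]
            placed <- FALSE
            for (k in seq_len(length(layerPairs) + 1L)) {
                lp <- if (k <= length(layerPairs)) layerPairs[[k]]
                      else matrix(0L, 0L, 2L)
                crossing <- nrow(lp) &&
                    any((lp[, 1L] < i & i < lp[, 2L] & lp[, 2L] < j) |
                        (i < lp[, 1L] & lp[, 1L] < j & j < lp[, 2L]))
                if (!crossing) {
                    if (k > length(.BRACKET_OPEN))
                        stop("too many pseudoknot layers to serialize")
                    layerPairs[[k]] <- rbind(lp, c(i, j))
                    chars[i] <- .BRACKET_OPEN[k]
                    chars[j] <- .BRACKET_CLOSE[k]
                    placed <- TRUE
                    break
                }
            }
            stopifnot(placed)
        }
    }
    paste(chars, collapse = "")
}

#' Collapse base pairs into stems
#'
#' Groups base pairs into maximal helical runs. Pairs sorted by their left
#' position merge into the same stem while consecutive pairs (i, j), (i', j')
#' satisfy 1 <= i' - i <= gapLimit + 1 and 1 <= j - j' <= gapLimit + 1, i.e.
#' small bulges and internal loops up to \code{gapLimit} unpaired positions
#' are tolerated. Each run yields one stem with left half l1..l2 and right
#' half r1..r2; stems are numbered 1..N by l1.
#'
#' @param bp a [BasePairSet-class].
#' @param gapLimit maximum tolerated gap (default 3).
#' @return data.frame with columns \code{id}, \code{l1}, \code{l2},
#'   \code{r1}, \code{r2}.
#' @examples
#' bp <- parseStructure("((..))", "dotbracket")
#' pairsToStems(bp, gapLimit = 0)
#' @export
pairsToStems <- function(bp, gapLimit = 3L) {
    stopifnot(is(bp, "BasePairSet"), gapLimit >= 0L)
    p <- bp@pairs
    if (!nrow(p))
        return(data.frame(id = integer(), l1 = integer(), l2 = integer(),
                          r1 = integer(), r2 = integer()))
    p <- p[order(p[, 1L]), , drop = FALSE]
    di <- diff(p[, 1L])
    dj <- -diff(p[, 2L])
    newRun <- c(TRUE, di > gapLimit + 1L | dj > gapLimit + 1L | dj < 1L)
    run <- cumsum(newRun)
    stems <- data.frame(
        id = seq_len(max(run)),
        l1 = as.integer(tapply(p[, 1L], run, min)),
        l2 = as.integer(tapply(p[, 1L], run, max)),
        r1 = as.integer(tapply(p[, 2L], run, min)),
        r2 = as.integer(tapply(p[, 2L], run, max)))
    stems <- stems[order(stems$l1), ]
    stems$id <- seq_len(nrow(stems))
    rownames(stems) <- NULL
    stems
}

#' Read and write XIOS graphs as JSON
#'
#' The JSON dialect is \code{{"id": str, "vertices": [{"id": int,
#' "left": [l1,l2], "right": [r1,r2]}], "edges": [[u, v, "I"|"O"|"X"]]}};
#' \code{"I"} is directional (u includes v) and stem coordinates are optional
#' (abstract graphs carry none). \code{readXIOS} accepts a JSON string or a
#' file path; \code{writeXIOS} returns the JSON string and optionally writes
#' it to \code{file}.
#'
#' @param text JSON string or path to a JSON file.
#' @return \code{readXIOS}: a [XIOSGraph-class]. \code{writeXIOS}: the JSON
#'   string, invisibly when written to a file.
#' @examples
#' g <- xiosFromArrangement(c(1, 2, 1, 2), id = "pk")
#' identical(writeXIOS(readXIOS(writeXIOS(g))), writeXIOS(g))
#' @export
readXIOS <- function(text) {
    if (length(text) == 1L && !grepl("{", text, fixed = TRUE) &&
        file.exists(text))
        text <- paste(readLines(text, warn = FALSE), collapse = "\n")
    obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    if (is.null(obj$vertices)) stop("XIOS JSON lacks 'vertices'")
    ids <- vapply(obj$vertices, function(v) as.integer(v$id), 0L)
    if (anyDuplicated(ids)) stop("duplicate vertex ids in XIOS JSON")
    n <- length(ids)
    remap <- seq_len(n)
    names(remap) <- as.character(sort(ids))
    hasCoords <- vapply(obj$vertices,
                        function(v) !is.null(v$left) && !is.null(v$right),
                        TRUE)
    stems <- data.frame(id = integer(), l1 = integer(), l2 = integer(),
                        r1 = integer(), r2 = integer())
    if (n && all(hasCoords)) {
        stems <- do.call(rbind, lapply(obj$vertices, function(v)
            data.frame(id = remap[[as.character(v$id)]],
                       l1 = v$left[[1L]], l2 = v$left[[2L]],
                       r1 = v$right[[1L]], r2 = v$right[[2L]])))
        stems <- stems[order(stems$id), ]
        rownames(stems) <- NULL
    }
    edges <- data.frame(from = integer(), to = integer(),
                        type = character())
    if (length(obj$edges)) {
        edges <- do.call(rbind, lapply(obj$edges, function(e) {
            if (length(e) != 3L) stop("edge entries must be [u, v, type]")
            type <- as.character(e[[3L]])
            if (!type %in% c("I", "O", "X"))
                stop("unknown edge label '", type, "'")
            u <- as.character(e[[1L]]); v <- as.character(e[[2L]])
            if (!u %in% names(remap) || !v %in% names(remap))
                stop("edge references missing vertex: [", u, ", ", v, "]")
            data.frame(from = remap[[u]], to = remap[[v]], type = type)
        }))
    }
    arr <- if (!is.null(obj$arrangement))
        as.integer(unlist(obj$arrangement)) else integer()
    new("XIOSGraph", id = as.character(obj$id %||% "xios"),
        nVertices = n, edges = edges, arrangement = arr, stems = stems)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readXIOS
#' @param g a [XIOSGraph-class].
#' @param file optional path to write to.
#' @export
writeXIOS <- function(g, file = NULL) {
    stopifnot(is(g, "XIOSGraph"))
    verts <- lapply(seq_len(g@nVertices), function(i) {
        v <- list(id = i)
        if (nrow(g@stems)) {
            s <- g@stems[g@stems$id == i, ]
            v$left <- c(s$l1, s$l2)
            v$right <- c(s$r1, s$r2)
        }
        v
    })
    edges <- lapply(seq_len(nrow(g@edges)), function(k)
        list(g@edges$from[k], g@edges$to[k], g@edges$type[k]))
    obj <- list(id = g@id, vertices = verts, edges = edges)
    if (length(g@arrangement)) obj$arrangement <- g@arrangement
    txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

#' Read and write fingerprints as JSON
#'
#' Dialect: \code{{"graph_id": str, "library": str, "kind": str,
#' "iterations": int, "motifs": {motif_id: count}}}.
#'
#' @param text JSON string or file path.
#' @return \code{readFingerprint}: a [Fingerprint-class].
#' @export
readFingerprint <- function(text) {
    if (length(text) == 1L && !grepl("{", text, fixed = TRUE) &&
        file.exists(text))
        text <- paste(readLines(text, warn = FALSE), collapse = "\n")
    obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    counts <- vapply(obj$motifs, function(x) as.integer(x), 0L)
    new("Fingerprint", graphID = as.character(obj$graph_id),
        library = as.character(obj$library %||% ""),
        motifCounts = counts,
        kind = as.character(obj$kind %||% "simple"),
        iterations = as.integer(obj$iterations %||% 0L),
        seed = as.integer(obj$seed %||% NA_integer_))
}

#' @rdname readFingerprint
#' @param fp a [Fingerprint-class].
#' @param file optional path to write to.
#' @export
writeFingerprint <- function(fp, file = NULL) {
    stopifnot(is(fp, "Fingerprint"))
    obj <- list(graph_id = fp@graphID, library = fp@library, kind = fp@kind,
                iterations = fp@iterations,
                motifs = as.list(fp@motifCounts))
    if (!is.na(fp@seed)) obj$seed <- fp@seed
    txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}
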