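#' @name xiosfp-accessors
#' @title Accessors for xiosfp classes
#' @description Slot accessors for [XIOSGraph-class], [MotifLibrary-class],
#'   [Fingerprint-class] and [DecoyDB-class] objects.
#' @param x an object.
#' @return The corresponding slot value.
NULL

#' @rdname xiosfp-accessors
#' @export
setGeneric("graphID", function(x) standardGeneric("graphID"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("vertexCount", function(x) standardGeneric("vertexCount"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("arrangement", function(x) standardGeneric("arrangement"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("stemTable", function(x) standardGeneric("stemTable"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("motifTable", function(x) standardGeneric("motifTable"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("maxStems", function(x) standardGeneric("maxStems"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("motifIDs", function(x) standardGeneric("motifIDs"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("fingerprintKind", function(x) standardGeneric("fingerprintKind"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("iterationCount", function(x) standardGeneric("iterationCount"))

#' @rdname xiosfp-accessors
#' @export
setGeneric("decoyEntries", function(x) standardGeneric("decoyEntries"))

setMethod("graphID", "XIOSGraph", function(x) x@id)
setMethod("vertexCount", "XIOSGraph", function(x) x@nVertices)
setMethod("edgeTable", "XIOSGraph", function(x) x@edges)
setMethod("arrangement", "XIOSGraph", function(x) x@arrangement)
setMethod("stemTable", "XIOSGraph", function(x) x@stems)

setMethod("motifTable", "MotifLibrary", function(x) x@motifs)
setMethod("maxStems", "MotifLibrary", function(x) x@maxStems)

setMethod("graphID", "Fingerprint", function(x) x@graphID)
setMethod("motifIDs", "Fingerprint", function(x) names(x@motifCounts))
setMethod("motifCounts", "Fingerprint", function(x) x@motifCounts)
setMethod("fingerprintKind", "Fingerprint", function(x) x@kind)
setMethod("iterationCount", "Fingerprint", function(x) x@iterations)

setMethod("decoyEntries", "DecoyDB", function(x) x@entries)

setMethod("show", "XIOSGraph", function(object) {
    e <- object@edges
    cat("XIOSGraph '", object@id, "': ", object@nVertices, " stems, ",
        nrow(e), " edges (I=", sum(e$type == "I"),
        " O=", sum(e$type == "O"), " X=", sum(e$type == "X"), ")\n", sep = "")
    if (length(object@arrangement))
        cat("  arrangement: (", paste(object@arrangement, collapse = ","),
            ")\n", sep = "")
})

setMethod("show", "MotifLibrary", function(object) {
    tab <- table(factor(object@motifs$n_stems, levels = 1:object@maxStems))
    cat("MotifLibrary: IO-connected topologies up to ", object@maxStems,
        " stems\n  motifs per stem count: ",
        paste(names(tab), unname(tab), sep = ":", collapse = " "),
        "\n  total: ", nrow(object@motifs), "\n", sep = "")
})

setMethod("show", "Fingerprint", function(object) {
    cat("Fingerprint of '", object@graphID, "' (", object@kind, "): ",
        length(object@motifCounts), " motifs, ",
        object@iterations, " iterations\n", sep = "")
})

setMethod("show", "DecoyDB", function(object) {
    e <- object@entries
    cat("DecoyDB: ", nrow(e), " motifs (2-5 stems), total count ",
        sum(e$count), "\n", sep = "")
})
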