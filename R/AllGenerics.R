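#' Accessors for simulated panels, matrices and fits
#'
#' Small accessor generics used across the package instead of direct slot
#' access: \code{proteomes}, \code{genomes}, \code{geneTable},
#' \code{groundTruth}, \code{simConfig} for [StrainSimulation-class];
#' \code{famCounts} for [PresenceAbsenceMatrix-class]; \code{aniValues} for
#' [AniMatrix-class]; \code{groups} for [SpeciesGrouping-class];
#' \code{openness} for [HeapsFit-class].
#'
#' @param x an object of the documented class.
#' @return the slot content; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteomes", function(x) standardGeneric("proteomes"))
#' @rdname accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @rdname accessors
#' @export
setGeneric("famCounts", function(x) standardGeneric("famCounts"))
#' @rdname accessors
#' @export
setGeneric("aniValues", function(x) standardGeneric("aniValues"))
#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname accessors
#' @export
setGeneric("openness", function(x) standardGeneric("openness"))

#' @rdname accessors
setMethod("proteomes", "StrainSimulation", function(x) x@proteomes)
#' @rdname accessors
setMethod("genomes", "StrainSimulation", function(x) x@genomes)
#' @rdname accessors
setMethod("geneTable", "StrainSimulation", function(x) x@geneTable)
#' @rdname accessors
setMethod("groundTruth", "StrainSimulation", function(x) x@truth)
#' @rdname accessors
setMethod("simConfig", "StrainSimulation", function(x) x@config)
#' @rdname accessors
setMethod("famCounts", "PresenceAbsenceMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("aniValues", "AniMatrix", function(x) x@values)
#' @rdname accessors
setMethod("groups", "SpeciesGrouping", function(x) x@groups)
#' @rdname accessors
setMethod("openness", "HeapsFit", function(x) x@openness)

#' @describeIn accessors coerce a presence-absence matrix to a base matrix.
#' @export
setMethod("as.matrix", "PresenceAbsenceMatrix", function(x, ...) x@counts)

#' @describeIn accessors dimensions (families, strains).
#' @export
setMethod("dim", "PresenceAbsenceMatrix", function(x) dim(x@counts))

#' @describeIn accessors fitted Heaps coefficients as a named vector.
#' @param object a fit object.
#' @param ... unused.
#' @export
setMethod("coef", "HeapsFit",
          function(object, ...) c(A = object@A, B = object@B, C = object@C))

#' @describeIn accessors fitted exponential coefficients as a named vector.
#' @export
setMethod("coef", "CoreFit",
          function(object, ...) c(A = object@A, B = object@B, C = object@C))

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nStrains, "strains,",
        object@nCore, "core families\n")
    cat("  dispensable rate", object@dispensableRate,
        "/branch; unique", object@uniquePerStrain, "/tip\n")
    cat("  divergence", object@perBranchDivergence, "/site/branch; GC",
        object@backgroundGC, "\n")
    if (!is.null(object@hgtCluster))
        cat("  planted HGT cluster:", object@hgtCluster$n_genes,
            "genes, GC shift", sprintf("%+.3f", object@hgtCluster$gc_shift),
            "from", object@hgtCluster$donor_label, "\n")
    cat("  seed", object@seed, "\n")
})

setMethod("show", "StrainSimulation", function(object) {
    cat("StrainSimulation:", length(object@proteomes), "strains,",
        nrow(object@geneTable), "genes,",
        nrow(object@truth@familyTable), "true families")
    if (length(object@truth@hgtGeneIds))
        cat(" +", length(object@truth@hgtGeneIds), "planted HGT genes")
    cat("\n")
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
    cat("PresenceAbsenceMatrix:", nrow(object@counts), "families x",
        ncol(object@counts), "strains\n")
})

setMethod("show", "PanPartition", function(object) {
    cat("PanPartition: pan", object@nPan, "= core", object@nCore,
        "+ dispensable", object@nDispensable,
        "+ specific", object@nSpecific, "\n")
})

setMethod("show", "HeapsFit", function(object) {
    cat(sprintf("HeapsFit: y = %.2f * x^%.4f + %.2f  (rss %.3g) -> %s\n",
                object@A, object@B, object@C, object@rss, object@openness))
})

setMethod("show", "CoreFit", function(object) {
    cat(sprintf("CoreFit: y = %.2f * exp(%.4f x) + %.2f  (rss %.3g)\n",
                object@A, object@B, object@C, object@rss))
})

setMethod("show", "AniMatrix", function(object) {
    cat("AniMatrix over", nrow(object@values), "strains\n")
    print(round(object@values, 2))
})

setMethod("show", "SpeciesGrouping", function(object) {
    cat("SpeciesGrouping at ANI >", object@threshold, ":",
        length(object@groups), "group(s)\n")
    for (i in seq_along(object@groups))
        cat("  group", i, ":", paste(object@groups[[i]], collapse = ", "), "\n")
})

setMethod("show", "PanCurves", function(object) {
    cat("PanCurves over", nrow(object@pan), "genome depths,",
        object@nOrderings,
        if (object@exhaustive) "orderings (exhaustive)\n" else "orderings\n")
})
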