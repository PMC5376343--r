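#' Accessors for SigNetPath classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("sourceNode", function(x) standardGeneric("sourceNode"))
#' @rdname accessors
#' @export
setGeneric("targetMembers", function(x) standardGeneric("targetMembers"))
#' @rdname accessors
#' @export
setGeneric("peptideRecords", function(x) standardGeneric("peptideRecords"))
#' @rdname accessors
#' @export
setGeneric("distanceTable", function(x) standardGeneric("distanceTable"))
#' @rdname accessors
#' @export
setGeneric("walkScores", function(x) standardGeneric("walkScores"))
#' @rdname accessors
#' @export
setGeneric("pathwayMembers", function(x) standardGeneric("pathwayMembers"))

#' @rdname accessors
#' @export
setMethod("nodeTable", "AnnotatedNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edgeTable", "AnnotatedNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("sourceNode", "AnnotatedNetwork",
    function(x) if (length(x@sourceId)) x@sourceId else NA_character_)
#' @rdname accessors
#' @export
setMethod("nodeTable", "PathSubnetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edgeTable", "PathSubnetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("sourceNode", "PathSubnetwork", function(x) x@sourceId)
#' @rdname accessors
#' @export
setMethod("targetMembers", "TargetSet", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("peptideRecords", "TargetSet", function(x) x@peptideRecords)
#' @rdname accessors
#' @export
setMethod("distanceTable", "DistanceAssignment", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("walkScores", "WalkScores",
    function(x) data.frame(id = names(x@pi), pi = unname(x@pi),
                           pi0 = unname(x@pi0),
                           ratio = unname(x@pi / x@pi0)))
#' @rdname accessors
#' @export
setMethod("pathwayMembers", "Pathway", function(x) x@members)

setMethod("show", "IdMap", function(object) {
    cat("IdMap with", length(unique(object@forward)), "canonical ids,",
        length(object@forward), "foreign keys,",
        sum(lengths(object@groups) > 1L), "multi-member groups\n")
})

setMethod("show", "TargetSet", function(object) {
    m <- object@members
    cat("TargetSet:", length(unique(m$id)), "proteins,", nrow(m),
        "member records\n")
    if (nrow(m)) {
        tb <- table(m$tag)
        cat("  tags:", paste(sprintf("%s=%d", names(tb), tb),
                             collapse = ", "), "\n")
    }
    if (nrow(object@peptideRecords))
        cat("  peptide records:", nrow(object@peptideRecords), "\n")
})

setMethod("show", "Pathway", function(object) {
    cat(sprintf("Pathway %s [%s]: %d members, %d interactions, %d groups\n",
                object@id, object@sourceDb, length(object@members),
                nrow(object@interactions), length(object@groups)))
})

setMethod("show", "AnnotatedNetwork", function(object) {
    cat(sprintf("AnnotatedNetwork: %d nodes (%d groups), %d edges\n",
                nrow(object@nodes), sum(object@nodes$isGroup),
                nrow(object@edges)))
    if (length(object@sourceId))
        cat("  source:", object@sourceId, "\n")
})

setMethod("show", "DistanceAssignment", function(object) {
    tb <- object@table
    cat("DistanceAssignment over", nrow(tb), "edges;",
        if (all(is.na(tb$refined))) "base distances only"
        else "refined distances available", "\n")
    if (nrow(tb)) {
        lv <- table(tb$base)
        cat("  base levels:", paste(sprintf("d=%s:%d", names(lv), lv),
                                    collapse = " "), "\n")
    }
})

setMethod("show", "PathSubnetwork", function(object) {
    cat(sprintf(
        "PathSubnetwork (epsilon=%g): %d nodes, %d edges; source %s -> %d targets\n",
        object@epsilon, nrow(object@nodes), nrow(object@edges),
        object@sourceId, length(object@targets)))
})

setMethod("show", "WalkModel", function(object) {
    cat(sprintf("WalkModel: %d states, p0=%g\n",
                nrow(object@P), object@p0))
})

setMethod("show", "WalkScores", function(object) {
    cat("WalkScores over", length(object@pi), "nodes\n")
})
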