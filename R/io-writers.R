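## GraphML / SIF / JSON export with node and edge attribute columns, and the
## matching GraphML reader for round-tripping (attributes that are id lists
## are serialized "|"-joined).

.joinList <- function(lst) vapply(lst, paste, character(1), collapse = "|")
.splitList <- function(v) lapply(strsplit(v, "|", fixed = TRUE),
                                 function(x) x[nzchar(x)])

#' Write / read an annotated network as GraphML
#'
#' All node and edge annotations travel as GraphML attributes (list-valued
#' ones joined with \code{"|"}), so \code{readGraphML(writeGraphML(net))}
#' reproduces the network, and the files open directly in Cytoscape 3.x.
#'
#' @param x an [AnnotatedNetwork-class] or [PathSubnetwork-class].
#' @param path file path.
#' @return \code{writeGraphML}: the path, invisibly. \code{readGraphML}: an
#'   [AnnotatedNetwork-class].
#' @export
setGeneric("writeGraphML", function(x, path) standardGeneric("writeGraphML"))

#' @rdname writeGraphML
#' @export
setMethod("writeGraphML", "AnnotatedNetwork", function(x, path) {
    nd <- x@nodes; ed <- x@edges
    vattr <- data.frame(
        name = nd$id, isGroup = nd$isGroup,
        isPtyrModifier = nd$isPtyrModifier, unknownId = nd$unknownId,
        pathways = .joinList(nd$pathways),
        categories = .joinList(nd$categories),
        evidence = .joinList(nd$evidence),
        groupMembers = .joinList(nd$groupMembers))
    eattr <- cbind(ed[c("source", "target")],
                   data.frame(types = .joinList(ed$types),
                              sign = ed$sign,
                              pathways = .joinList(ed$pathways)))
    g <- igraph::graph_from_data_frame(eattr, directed = TRUE,
                                       vertices = vattr)
    if (length(x@sourceId) == 1L)
        g <- igraph::set_graph_attr(g, "sourceId", x@sourceId)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
})

#' @rdname writeGraphML
#' @export
setMethod("writeGraphML", "PathSubnetwork", function(x, path) {
    g <- igraph::graph_from_data_frame(
        x@edges, directed = TRUE,
        vertices = data.frame(name = x@nodes$id,
                              overflow = x@nodes$overflow))
    g <- igraph::set_graph_attr(g, "sourceId", x@sourceId)
    g <- igraph::set_graph_attr(g, "epsilon", x@epsilon)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
})

#' @rdname writeGraphML
#' @export
readGraphML <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    vd <- igraph::as_data_frame(g, what = "vertices")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- data.frame(
        id = vd$name, isGroup = as.logical(vd$isGroup),
        isPtyrModifier = as.logical(vd$isPtyrModifier),
        unknownId = as.logical(vd$unknownId),
        pathways = I(.splitList(vd$pathways)),
        categories = I(.splitList(vd$categories)),
        evidence = I(.splitList(vd$evidence)),
        groupMembers = I(.splitList(vd$groupMembers)))
    edges <- if (nrow(ed)) data.frame(
        source = ed$from, target = ed$to, sign = ed$sign,
        types = I(.splitList(ed$types)),
        pathways = I(.splitList(ed$pathways)))
    else .newEdges()
    src <- igraph::graph_attr(g, "sourceId")
    .newNetwork(nodes, edges,
                if (is.null(src)) character() else src)
}

#' Write a network or subnetwork in SIF format
#'
#' One line per edge: source, relation (interaction types joined with
#' \code{";"}, or \code{"edge"} for subnetworks), target.
#'
#' @param x an [AnnotatedNetwork-class] or [PathSubnetwork-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeSif <- function(x, path) {
    ed <- edgeTable(x)
    rel <- if ("types" %in% names(ed))
        vapply(ed$types, paste, character(1), collapse = ";")
    else rep("edge", nrow(ed))
    writeLines(paste(ed$source, rel, ed$target, sep = "\t"), path)
    invisible(path)
}

#' Export a subnetwork as JSON
#'
#' Node/edge lists with overflow annotations, for lightweight web viewers.
#'
#' @param subnetwork a [PathSubnetwork-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeSubnetworkJson <- function(subnetwork, path) {
    jsonlite::write_json(
        list(source = subnetwork@sourceId,
             targets = subnetwork@targets,
             epsilon = subnetwork@epsilon,
             nodes = subnetwork@nodes, edges = subnetwork@edges),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Write a target-set table
#'
#' @param targetSet a [TargetSet-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeTargetTable <- function(targetSet, path) {
    write.table(targetMembers(targetSet), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
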