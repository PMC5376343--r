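## Shortest and near-shortest source-to-target subnetworks with per-element
## overflow annotation.

.FP_TOL <- 1e-9

.weightedGraph <- function(net, weights) {
    ed <- net@edges
    stopifnot(length(weights) == nrow(ed))
    g <- igraph::graph_from_data_frame(
        cbind(ed[c("source", "target")], weight = weights),
        directed = TRUE, vertices = data.frame(name = net@nodes$id))
    g
}

#' Single-source shortest distances (Dijkstra)
#'
#' Exact shortest distances over positive edge distances; unreachable nodes
#' are infinite. With \code{reverse = TRUE} distances TO the origin are
#' computed.
#'
#' @param net an exploded [AnnotatedNetwork-class].
#' @param distances a [DistanceAssignment-class], or a numeric vector of
#'   per-edge weights in edge-table order.
#' @param origin origin node id (error if absent).
#' @param reverse compute distances to the origin instead of from it.
#' @param use distance column when \code{distances} is an assignment.
#' @return named numeric vector of distances over all nodes.
#' @export
dijkstraDistances <- function(net, distances, origin, reverse = FALSE,
                              use = "base") {
    if (!origin %in% net@nodes$id) stop("origin node absent: ", origin)
    w <- if (is.numeric(distances)) distances
         else unname(.edgeWeightVector(distances, use)[
             paste(net@edges$source, net@edges$target, sep = "\r")])
    if (any(w <= 0)) stop("all distances must be > 0")
    g <- .weightedGraph(net, w)
    d <- igraph::distances(g, v = origin, mode = if (reverse) "in"
                           else "out", weights = igraph::E(g)$weight,
                           algorithm = "dijkstra")
    setNames(as.numeric(d[1, ]), colnames(d))
}

#' Extract the near-shortest source-to-target subnetwork
#'
#' An edge (u, v) is retained iff for some target t the best acceptable
#' route through it satisfies
#' \code{dfwd(u) + d(u,v) + dbwd_t(v) <= (1 + epsilon) * dfwd(t)}, where
#' \code{dfwd} are shortest distances from the source and \code{dbwd_t} to
#' the target; a node is retained iff incident to a retained edge. Each
#' element is annotated with its overflow: the extra distance, beyond the
#' per-target shortest distance, of the best acceptable route using it
#' (minimum over served targets; 0 for shortest-path elements). The
#' composite subnetwork may contain walks longer than acceptable, but every
#' retained element lies on at least one acceptable route.
#'
#' @param net an exploded [AnnotatedNetwork-class].
#' @param distances a [DistanceAssignment-class] or numeric per-edge weight
#'   vector in edge-table order.
#' @param source origin node id.
#' @param targets character vector of target ids.
#' @param epsilon allowed overflow fraction (>= 0); 0 gives the strict
#'   shortest-path subnetwork.
#' @param use distance column when \code{distances} is an assignment
#'   (\code{"base"} or \code{"refined"}).
#' @param absoluteSlack if not \code{NULL}, use this absolute extra distance
#'   instead of the relative fraction.
#' @return a [PathSubnetwork-class]; empty (with a warning) when no target
#'   is reachable.
#' @export
nearShortestSubnetwork <- function(net, distances, source, targets,
                                   epsilon = 0.2, use = "base",
                                   absoluteSlack = NULL) {
    stopifnot(epsilon >= 0)
    w <- if (is.numeric(distances)) distances
         else unname(.edgeWeightVector(distances, use)[
             paste(net@edges$source, net@edges$target, sep = "\r")])
    dfwd <- dijkstraDistances(net, w, source, reverse = FALSE)
    targets <- unique(targets)
    reach <- targets[is.finite(dfwd[targets])]
    if (!length(reach)) {
        warning("no requested target is reachable from the source")
        return(new("PathSubnetwork",
                   nodes = data.frame(id = character(),
                                      overflow = numeric()),
                   edges = data.frame(source = character(),
                                      target = character(),
                                      overflow = numeric()),
                   perTarget = data.frame(target = character(),
                                          source = character(),
                                          to = character(),
                                          overflow = numeric()),
                   sourceId = source, targets = targets,
                   epsilon = epsilon,
                   shortestDist = setNames(numeric(), character())))
    }
    # restrict backward searches to the source-reachable component
    comp <- names(dfwd)[is.finite(dfwd)]
    keepE <- net@edges$source %in% comp & net@edges$target %in% comp
    sub <- .newNetwork(net@nodes[net@nodes$id %in% comp, , drop = FALSE],
                       net@edges[keepE, , drop = FALSE], character())
    wSub <- w[keepE]
    ed <- sub@edges
    shortest <- dfwd[reach]
    perTarget <- list()
    edgeOver <- rep(Inf, nrow(ed))
    du <- dfwd[ed$source]
    for (t in reach) {
        dbwd <- dijkstraDistances(sub, wSub, t, reverse = TRUE)
        slackBudget <- if (is.null(absoluteSlack))
            epsilon * dfwd[[t]] else absoluteSlack
        over <- du + wSub + dbwd[ed$target] - dfwd[[t]]
        over[abs(over) <= .FP_TOL * max(1, dfwd[[t]])] <- 0
        ok <- is.finite(over) & over <= slackBudget +
            .FP_TOL * max(1, dfwd[[t]])
        if (any(ok)) {
            perTarget[[t]] <- data.frame(
                target = t, source = ed$source[ok], to = ed$target[ok],
                overflow = pmax(over[ok], 0))
            edgeOver[ok] <- pmin(edgeOver[ok], pmax(over[ok], 0))
        }
    }
    keep <- is.finite(edgeOver)
    edges <- data.frame(source = ed$source[keep], target = ed$target[keep],
                        overflow = edgeOver[keep])
    ids <- unique(c(edges$source, edges$target))
    nodeOver <- vapply(ids, function(i)
        min(edges$overflow[edges$source == i | edges$target == i]),
        numeric(1))
    if (!nrow(edges) && source %in% reach) {
        # degenerate: the source is its own target
        ids <- source; nodeOver <- setNames(0, source)
    }
    new("PathSubnetwork",
        nodes = data.frame(id = ids, overflow = unname(nodeOver)),
        edges = edges,
        perTarget = if (length(perTarget))
            do.call(rbind, c(perTarget, make.row.names = FALSE))
        else data.frame(target = character(), source = character(),
                        to = character(), overflow = numeric()),
        sourceId = source, targets = targets, epsilon = epsilon,
        shortestDist = shortest)
}

#' Strict shortest-path subnetwork
#'
#' The union over targets of all edges lying on some shortest source-to-
#' target path (all tied alternatives retained); equals
#' [nearShortestSubnetwork()] with \code{epsilon = 0}.
#'
#' @inheritParams nearShortestSubnetwork
#' @export
shortestSubnetwork <- function(net, distances, source, targets,
                               use = "base") {
    nearShortestSubnetwork(net, distances, source, targets, epsilon = 0,
                           use = use)
}

#' Unweighted (hop-count) subnetwork
#'
#' [nearShortestSubnetwork()] with unit distances on every edge.
#'
#' @inheritParams nearShortestSubnetwork
#' @export
unweightedSubnetwork <- function(net, source, targets, epsilon = 0) {
    nearShortestSubnetwork(net, rep(1, nrow(net@edges)), source, targets,
                           epsilon = epsilon)
}

#' Per-target path report
#'
#' Long-form table of retained edges with their per-target overflow (the
#' subnetwork's own annotations keep the global minimum).
#'
#' @param subnetwork a [PathSubnetwork-class].
#' @return data.frame with columns \code{target}, \code{source}, \code{to},
#'   \code{overflow}.
#' @export
pathReport <- function(subnetwork) subnetwork@perTarget

#' Write a per-target path report
#'
#' @param subnetwork a [PathSubnetwork-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePathReport <- function(subnetwork, path) {
    write.table(pathReport(subnetwork), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
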