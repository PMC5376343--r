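## Merging selected pathways into one annotated directed network: provenance
## tracking, type/sign reconciliation, GO category and modifier annotation,
## dataset evidence, and group-node explosion.

.newNodes <- function(ids = character()) {
    n <- length(ids)
    data.frame(id = ids, isGroup = logical(n), isPtyrModifier = logical(n),
               unknownId = logical(n),
               pathways = I(rep(list(character()), n)),
               categories = I(rep(list(character()), n)),
               evidence = I(rep(list(character()), n)),
               groupMembers = I(rep(list(character()), n)))
}

.newEdges <- function() {
    data.frame(source = character(), target = character(),
               sign = character(),
               types = I(list()), pathways = I(list()))
}

.newNetwork <- function(nodes = .newNodes(), edges = .newEdges(),
                        sourceId = character()) {
    rownames(nodes) <- NULL; rownames(edges) <- NULL
    new("AnnotatedNetwork", nodes = nodes, edges = edges,
        sourceId = sourceId)
}

#' Combine interaction signs across pathways
#'
#' The commutative, associative join of the sign lattice: all-positive gives
#' positive, all-negative negative, positive and negative together give
#' unclear, unknown is neutral unless it is all there is.
#'
#' @param signs character vector from \{positive, negative, unknown,
#'   unclear\} (nonempty).
#' @return a single combined sign.
#' @examples
#' combineSigns(c("positive", "positive"))  # "positive"
#' combineSigns(c("positive", "negative"))  # "unclear"
#' combineSigns(c("unknown", "negative"))   # "negative"
#' @export
combineSigns <- function(signs) {
    stopifnot(length(signs) > 0)
    hasP <- any(signs == "positive"); hasN <- any(signs == "negative")
    if (any(signs == "unclear") || (hasP && hasN)) "unclear"
    else if (hasP) "positive"
    else if (hasN) "negative"
    else "unknown"
}

.aggregateEdges <- function(long) {
    # long: source, target, type (chr), sign (chr), pathway (chr) rows
    key <- paste(long$source, long$target, sep = "\r")
    idx <- split(seq_len(nrow(long)), key)
    first <- vapply(idx, `[`, integer(1), 1L)
    data.frame(
        source = long$source[first], target = long$target[first],
        sign = vapply(idx, function(i) combineSigns(long$sign[i]),
                      character(1)),
        types = I(lapply(idx, function(i) sort(unique(long$type[i])))),
        pathways = I(lapply(idx, function(i)
            sort(unique(long$pathway[i])))),
        row.names = NULL)
}

#' Merge pathways into an annotated directed network
#'
#' Produces one node per canonical id and one edge per ordered (source,
#' target) pair; interaction types are unioned, pathway provenance
#' accumulated, and signs combined with [combineSigns()] (positive in one
#' pathway and negative in another becomes unclear). Group constructs are
#' conserved as marked group nodes with bidirectional member-link edges
#' (type \code{"member"}); use [explodeGroups()] before path search.
#' Interactions whose ids cannot be mapped are kept under the raw id and
#' flagged \code{unknownId}.
#'
#' @param pathways list of [Pathway-class] objects.
#' @param idmap optional [IdMap-class]; when supplied, member and endpoint
#'   ids are canonicalized, looked up in the namespace matching each
#'   pathway's source database (see \code{namespaces}).
#' @param namespaces named character: source database to id namespace.
#' @param sourceId optional id of the signal origin to record.
#' @return an [AnnotatedNetwork-class].
#' @export
mergePathways <- function(pathways, idmap = NULL,
                          namespaces = c(KEGG = "KEGG",
                                         PathwayCommons = "HGNC"),
                          sourceId = character()) {
    canon <- function(ids, db) {
        if (!length(ids)) return(ids)
        isGroup <- startsWith(ids, "group:")
        if (is.null(idmap)) {
            attr(ids, "unknown") <- rep(FALSE, length(ids))
            return(ids)
        }
        ns <- if (!is.na(namespaces[db])) namespaces[[db]] else "UNIPROT"
        out <- ids; unk <- rep(FALSE, length(ids))
        if (any(!isGroup)) {
            cc <- canonicalize(ids[!isGroup], idmap, ns)
            # fall back to the UNIPROT namespace for already-canonical ids
            u <- attr(cc, "unknown")
            if (any(u) && ns != "UNIPROT") {
                cc2 <- canonicalize(ids[!isGroup][u], idmap, "UNIPROT")
                cc[u] <- cc2
                u[u] <- attr(cc2, "unknown")
            }
            out[!isGroup] <- cc
            unk[!isGroup] <- u
        }
        attr(out, "unknown") <- unk
        out
    }
    nodeRows <- list(); edgeRows <- list(); memberRows <- list()
    groupsAll <- list(); unknownIds <- character()
    for (pw in pathways) {
        mem <- canon(pw@members, pw@sourceDb)
        unknownIds <- c(unknownIds, mem[attr(mem, "unknown")])
        lookup <- setNames(as.character(mem), pw@members)
        gmap <- lapply(pw@groups, function(g)
            unique(unname(ifelse(g %in% names(lookup), lookup[g], g))))
        for (gid in names(gmap)) groupsAll[[gid]] <- gmap[[gid]]
        nodeRows[[pw@id]] <- unique(c(as.character(mem), names(gmap)))
        it <- pw@interactions
        if (nrow(it)) {
            tr <- function(v) ifelse(v %in% names(lookup), lookup[v], v)
            edgeRows[[length(edgeRows) + 1L]] <- data.frame(
                source = unname(tr(it$source)),
                target = unname(tr(it$target)),
                type = it$type, sign = it$sign, pathway = pw@id)
        }
        if (length(gmap)) {
            gm <- data.frame(
                g = rep(names(gmap), lengths(gmap)),
                m = unlist(gmap, use.names = FALSE))
            memberRows[[length(memberRows) + 1L]] <- data.frame(
                source = c(gm$g, gm$m), target = c(gm$m, gm$g),
                type = "member", sign = "unknown", pathway = pw@id)
        }
    }
    long <- do.call(rbind, c(edgeRows, memberRows))
    allIds <- sort(unique(c(unlist(nodeRows, use.names = FALSE),
                            if (!is.null(long)) c(long$source,
                                                  long$target))))
    nodes <- .newNodes(allIds)
    nodes$unknownId <- nodes$id %in% unknownIds
    nodes$isGroup <- nodes$id %in% names(groupsAll)
    nodes$groupMembers[nodes$isGroup] <- groupsAll[
        nodes$id[nodes$isGroup]]
    prov <- lapply(setNames(nodes$id, nodes$id), function(i) character())
    for (pid in names(nodeRows))
        for (i in nodeRows[[pid]]) prov[[i]] <- c(prov[[i]], pid)
    nodes$pathways <- I(lapply(prov[nodes$id], function(p)
        sort(unique(p))))
    edges <- if (is.null(long)) .newEdges() else .aggregateEdges(long)
    if (any(nodes$unknownId))
        warning(sum(nodes$unknownId),
                " node(s) kept under raw unmappable id")
    net <- .newNetwork(nodes, edges, sourceId)
    validObject(net)
    net
}

#' Shipped GO term groups for process categories and modifiers
#'
#' The default category-to-GO-term mapping used to tag nodes with the
#' processes relevant to the source kinase (cell adhesion and motility, cell
#' growth and death, immunity and inflammation, cell differentiation), plus
#' the phospho-tyrosine-modifier terms (protein tyrosine kinase GO:0004713
#' and phosphatase GO:0004725 activity).
#'
#' @param path optional alternative YAML path.
#' @return list with elements \code{categories} (named list of GO id
#'   vectors) and \code{modifier_terms} (GO id vector).
#' @export
goTermGroups <- function(path = system.file("extdata", "config",
                                            "go-groups.yaml",
                                            package = "SigNetPath")) {
    yaml::read_yaml(path)
}

.annotationsByProtein <- function(gaf, obo, terms, includePartOf = FALSE) {
    closure <- termDescendants(obo, terms, includePartOf)
    unique(gaf$protein_id[gaf$go_id %in% closure])
}

#' Annotate network nodes with process categories
#'
#' A node carries a category iff it is annotated (directly or via an
#' ontology descendant of a group term) to any GO id of that category's term
#' group. Descendant closure follows \code{is_a} edges (optionally
#' \code{part_of}).
#'
#' @param net an [AnnotatedNetwork-class].
#' @param gaf annotation data.frame from [readGaf()] (protein ids already
#'   canonical).
#' @param obo ontology from [readObo()].
#' @param termGroups named list category -> GO id vector; default the
#'   \code{categories} element of [goTermGroups()].
#' @param includePartOf follow \code{part_of} in the closure.
#' @return the network with the \code{categories} node column filled.
#' @export
annotateCategories <- function(net, gaf, obo,
                               termGroups = goTermGroups()$categories,
                               includePartOf = FALSE) {
    hits <- lapply(termGroups, function(terms)
        .annotationsByProtein(gaf, obo, terms, includePartOf))
    nodes <- net@nodes
    nodes$categories <- I(lapply(nodes$id, function(i)
        sort(names(hits)[vapply(hits, function(v) i %in% v, logical(1))])))
    .newNetwork(nodes, net@edges, net@sourceId)
}

#' Flag phospho-tyrosine modifiers
#'
#' Sets \code{isPtyrModifier} for nodes annotated to a modifier GO term (or
#' a descendant), then applies the manual allow/deny overrides standing in
#' for the hand-verified list.
#'
#' @inheritParams annotateCategories
#' @param modifierTerms GO ids marking tyrosine kinase/phosphatase activity.
#' @param manualAllow ids forced to modifier status.
#' @param manualDeny ids denied modifier status despite their GO terms.
#' @return the network with \code{isPtyrModifier} filled.
#' @export
annotateModifiers <- function(net, gaf, obo,
                              modifierTerms = goTermGroups()$modifier_terms,
                              manualAllow = character(),
                              manualDeny = character(),
                              includePartOf = FALSE) {
    hit <- .annotationsByProtein(gaf, obo, modifierTerms, includePartOf)
    nodes <- net@nodes
    nodes$isPtyrModifier <-
        (nodes$id %in% hit | nodes$id %in% manualAllow) &
        !nodes$id %in% manualDeny
    .newNetwork(nodes, net@edges, net@sourceId)
}

#' Attach dataset evidence to network nodes
#'
#' Copies the dataset tags of a curated [TargetSet-class] onto the matching
#' nodes (the \code{evidence} column used by the edge-distance scheme).
#'
#' @param net an [AnnotatedNetwork-class].
#' @param targetSet a [TargetSet-class] with canonical ids.
#' @return the annotated network.
#' @export
annotateEvidence <- function(net, targetSet) {
    tags <- split(targetMembers(targetSet)$tag, targetMembers(targetSet)$id)
    nodes <- net@nodes
    nodes$evidence <- I(lapply(nodes$id, function(i)
        sort(unique(tags[[i]])) %||% character()))
    .newNetwork(nodes, net@edges, net@sourceId)
}

#' Explode group nodes into protein-level edges
#'
#' Every edge incident to a group node is replaced by edges to/from each
#' member, inheriting type, sign and provenance; member-link edges and group
#' nodes are removed. Nested groups are expanded to a fully protein-level
#' fixpoint. Explosion preserves reachability between protein-level nodes.
#'
#' @param net an [AnnotatedNetwork-class] with marked group nodes.
#' @return the exploded network (no group nodes remain).
#' @export
explodeGroups <- function(net) {
    nodes <- net@nodes
    if (!any(nodes$isGroup)) return(net)
    gmap <- setNames(nodes$groupMembers[nodes$isGroup],
                     nodes$id[nodes$isGroup])
    if (any(!lengths(gmap))) stop("empty group node")
    # flatten nested groups down to protein-level member sets
    flatten <- function(gid, seen = character()) {
        if (gid %in% seen)
            stop("cyclic group membership involving ", gid)
        mem <- gmap[[gid]]
        unique(unlist(lapply(mem, function(m)
            if (m %in% names(gmap)) flatten(m, c(seen, gid)) else m)))
    }
    flat <- lapply(setNames(names(gmap), names(gmap)), flatten)
    if (any(!lengths(flat))) stop("empty group node after flattening")
    ed <- net@edges
    keep <- !vapply(ed$types, function(t) identical(t, "member"),
                    logical(1))
    ed <- ed[keep, , drop = FALSE]
    if (nrow(ed)) {
        expand <- function(v) lapply(v, function(x)
            if (x %in% names(flat)) flat[[x]] else x)
        srcL <- expand(ed$source); tgtL <- expand(ed$target)
        rows <- lapply(seq_len(nrow(ed)), function(i) {
            combos <- expand.grid(s = srcL[[i]], t = tgtL[[i]],
                                  stringsAsFactors = FALSE)
            data.frame(source = combos$s, target = combos$t,
                       type = paste(ed$types[[i]], collapse = "\r"),
                       sign = ed$sign[i],
                       pathway = paste(ed$pathways[[i]],
                                       collapse = "\r"))
        })
        agg <- .aggregateEdges(do.call(rbind, rows))
        # unsplit the packed type/pathway strings
        agg$types <- I(lapply(agg$types, function(t)
            sort(unique(unlist(strsplit(t, "\r", fixed = TRUE))))))
        agg$pathways <- I(lapply(agg$pathways, function(p)
            sort(unique(unlist(strsplit(p, "\r", fixed = TRUE))))))
        ed <- agg
    }
    nodes <- nodes[!nodes$isGroup, , drop = FALSE]
    .newNetwork(nodes, ed, net@sourceId)
}

#' Convert an annotated network to an igraph object
#'
#' @param net an [AnnotatedNetwork-class].
#' @return a directed \pkg{igraph} graph whose vertices are node ids.
#' @export
asIgraph <- function(net) {
    igraph::graph_from_data_frame(
        net@edges[c("source", "target")], directed = TRUE,
        vertices = data.frame(name = net@nodes$id))
}

#' Targets reachable from the source by directed paths
#'
#' @param net an exploded [AnnotatedNetwork-class].
#' @param source origin node id (error if absent).
#' @param targets candidate target ids.
#' @return the subset of \code{targets} reachable from \code{source}.
#' @export
reachableTargets <- function(net, source, targets) {
    if (!source %in% net@nodes$id) stop("source node absent: ", source)
    g <- asIgraph(net)
    reach <- igraph::subcomponent(g, source, mode = "out")$name
    intersect(targets, reach)
}

#' Census of interactions between identified targets
#'
#' Counts the network edges joining two dataset targets, split by
#' dataset-of-origin combination: both endpoints specific to the first
#' dataset, both specific to the second, at least one endpoint shared by
#' both datasets, or endpoints specific to different datasets.
#'
#' @param net an exploded [AnnotatedNetwork-class].
#' @param targetsByDataset named list of two id vectors (e.g.
#'   \code{list(MCF7 = ..., MDA231 = ...)}).
#' @return named integer vector \code{both_first}, \code{both_second},
#'   \code{involving_shared}, \code{cross_dataset}, \code{total}.
#' @export
targetInteractionCensus <- function(net, targetsByDataset) {
    stopifnot(length(targetsByDataset) == 2L)
    a <- targetsByDataset[[1]]; b <- targetsByDataset[[2]]
    shared <- intersect(a, b)
    allT <- union(a, b)
    ed <- net@edges
    inA <- ed$source %in% allT & ed$target %in% allT
    ed <- ed[inA, , drop = FALSE]
    cls <- function(s, t) {
        if (s %in% shared || t %in% shared) "involving_shared"
        else if (s %in% a && t %in% a) "both_first"
        else if (s %in% b && t %in% b) "both_second"
        else "cross_dataset"
    }
    lab <- if (nrow(ed)) mapply(cls, ed$source, ed$target) else character()
    out <- c(both_first = 0L, both_second = 0L, involving_shared = 0L,
             cross_dataset = 0L)
    tb <- table(lab)
    out[names(tb)] <- as.integer(tb)
    c(out, total = nrow(ed))
}
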