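## Evidence-based edge distances: the six-level scheme and random-walk
## refinement.

#' Default edge-distance scheme
#'
#' The six distance levels and the evidence-class mapping: "normal" edges
#' have distance 5; edges out of an identified protein are promoted to 3;
#' edges from a phospho-tyrosine modifier into an identified protein to 2,
#' or 1 when the modifier source is itself identified. Edges reaching a
#' differentially phosphorylated target are demoted to 8 when the source is
#' neither a modifier nor identified, and to 6 when the non-modifier source
#' is identified. \code{dp_tags} lists the evidence classes counting as
#' "differentially phosphorylated" (site-level observations).
#'
#' @param path optional alternative YAML path.
#' @return list with elements \code{levels} (named numeric) and
#'   \code{dp_tags} (character).
#' @export
distanceScheme <- function(path = system.file("extdata", "config",
                                              "distance-scheme.yaml",
                                              package = "SigNetPath")) {
    cfg <- yaml::read_yaml(path)
    cfg$levels <- unlist(cfg$levels)
    cfg
}

#' Assign the base distance of one edge from node annotations
#'
#' Rule precedence (exactly one rule fires): the modifier-source promotion
#' branch is evaluated before the demotion branch, because demotion only
#' concerns edges that do not come from a tyrosine kinase or phosphatase.
#' With the default levels the result is in \{1, 2, 3, 5, 6, 8\}.
#'
#' @param sourceEvidence character vector of the source node's dataset tags
#'   (empty if unidentified).
#' @param sourceModifier logical, source is a phospho-tyrosine modifier.
#' @param targetEvidence character vector of the target node's dataset tags.
#' @param scheme scheme configuration, see [distanceScheme()].
#' @return a single positive distance.
#' @examples
#' assignDistance(character(), FALSE, character())          # 5 (normal)
#' assignDistance("complex-level", TRUE, "site-level")      # 1
#' assignDistance(character(), FALSE, "site-level")         # 8
#' @export
assignDistance <- function(sourceEvidence, sourceModifier, targetEvidence,
                           scheme = distanceScheme()) {
    lv <- scheme$levels
    sId <- length(sourceEvidence) > 0L
    tId <- length(targetEvidence) > 0L
    tDp <- any(targetEvidence %in% scheme$dp_tags)
    if (sId && sourceModifier && tId) return(unname(lv["promoted_both"]))
    if (sourceModifier && tId) return(unname(lv["modifier_source"]))
    if (tDp && !sourceModifier && !sId) return(unname(lv["demoted"]))
    if (tDp && !sourceModifier && sId)
        return(unname(lv["demoted_identified_source"]))
    if (sId) return(unname(lv["identified_source"]))
    unname(lv["normal"])
}

#' Assign base distances to every edge of a network
#'
#' Vectorized application of [assignDistance()] using the network's
#' \code{evidence} and \code{isPtyrModifier} node annotations (see
#' [annotateEvidence()] and [annotateModifiers()]).
#'
#' @param net an annotated, exploded [AnnotatedNetwork-class].
#' @param scheme see [distanceScheme()].
#' @return a [DistanceAssignment-class] with \code{refined = NA}.
#' @export
assignDistances <- function(net, scheme = distanceScheme()) {
    nodes <- net@nodes; ed <- net@edges
    ev <- setNames(nodes$evidence, nodes$id)
    mod <- setNames(nodes$isPtyrModifier, nodes$id)
    base <- vapply(seq_len(nrow(ed)), function(i)
        assignDistance(ev[[ed$source[i]]], mod[[ed$source[i]]],
                       ev[[ed$target[i]]], scheme), numeric(1))
    tb <- data.frame(source = ed$source, target = ed$target,
                     base = base, refined = NA_real_)
    new("DistanceAssignment", table = tb, scheme = scheme)
}

#' Refine edge distances with random-walk scores
#'
#' Multiplies each edge's base distance by the inverse of its source node's
#' normalized stationary score: \code{refined(i -> j) = base * pi0[i] /
#' pi[i]}. Edges out of nodes where both scores are zero (outside the walk's
#' reachable component) are maximally demoted but kept finite, using the
#' largest \code{pi0/pi} factor observed among reached nodes, so the graph
#' stays connected for path search. A node with \code{pi0 = 0} but
#' \code{pi > 0} indicates inconsistent runs and is an error.
#'
#' @param assignment a [DistanceAssignment-class] with base distances.
#' @param scores a [WalkScores-class] from [scoreNodes()].
#' @return the assignment with the \code{refined} column filled.
#' @export
refineDistances <- function(assignment, scores) {
    tb <- assignment@table
    pi1 <- scores@pi; pi0 <- scores@pi0
    if (any(pi0 == 0 & pi1 > 0))
        stop("pi0 is zero where pi is positive: inconsistent walk runs")
    reached <- pi1 > 0
    factor <- rep(if (any(reached)) max(pi0[reached] / pi1[reached]) else 1,
                  nrow(tb))
    src <- tb$source
    known <- src %in% names(pi1) & reached[match(src, names(pi1))]
    known[is.na(known)] <- FALSE
    factor[known] <- pi0[src[known]] / pi1[src[known]]
    tb$refined <- tb$base * factor
    new("DistanceAssignment", table = tb, scheme = assignment@scheme)
}

#' Write a distance table
#'
#' @param assignment a [DistanceAssignment-class].
#' @param path output TSV path (columns source, target, base_d, refined_d).
#' @return the path, invisibly.
#' @export
writeDistanceTable <- function(assignment, path) {
    tb <- assignment@table
    names(tb) <- c("source", "target", "base_d", "refined_d")
    write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
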