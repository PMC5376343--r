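#' @import methods
#' @importFrom stats setNames
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Identifier map across Uniprot, KEGG and HGNC namespaces
#'
#' An \code{IdMap} canonicalizes protein identifiers: every foreign key
#' (namespace, raw id) resolves to exactly one canonical Uniprot accession,
#' accessions sharing a KEGG or HGNC identifier are grouped under a single
#' representative (preferring reviewed entries), and isoform suffixes never
#' appear in canonical ids.
#'
#' @slot forward named character vector; names are \code{"<NAMESPACE>|<raw>"}
#'   keys, values are canonical ids.
#' @slot reviewed named logical vector, review status per accession.
#' @slot groups named list mapping each canonical id to its member accessions
#'   (a canonical id is always one of its own members).
#' @export
setClass("IdMap",
    representation(forward = "character", reviewed = "logical",
                   groups = "list"))

setValidity("IdMap", function(object) {
    msg <- character()
    if (anyDuplicated(names(object@forward)))
        msg <- c(msg, "duplicated foreign keys in forward map")
    if (any(grepl("-[0-9]+$", object@forward)))
        msg <- c(msg, "isoform suffix present in a canonical id")
    bad <- !mapply(function(cid, mem) cid %in% mem,
                   names(object@groups), object@groups)
    if (length(bad) && any(bad))
        msg <- c(msg, "a canonical id is not a member of its own group")
    if (length(msg)) msg else TRUE
})

#' Curated set of proteomic targets
#'
#' Holds curated target proteins with their evidence class and direction of
#' change, plus the per-peptide records retained for audit.
#'
#' @slot members data.frame with columns \code{id}, \code{tag} (one of
#'   \code{"complex-level"}, \code{"site-level"}, \code{"direct-substrate"})
#'   and \code{direction} (\code{"up"}, \code{"down"} or \code{"mixed"}).
#'   A protein may appear once per tag.
#' @slot peptideRecords data.frame of the peptide rows backing site-level and
#'   direct-substrate members (may be empty).
#' @export
setClass("TargetSet",
    representation(members = "data.frame", peptideRecords = "data.frame"))

.targetTags <- c("complex-level", "site-level", "direct-substrate")
.directions <- c("up", "down", "mixed")

setValidity("TargetSet", function(object) {
    m <- object@members
    msg <- character()
    need <- c("id", "tag", "direction")
    if (!all(need %in% names(m)))
        return(sprintf("members must have columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(m)) {
        if (!all(m$tag %in% .targetTags))
            msg <- c(msg, "unknown dataset tag")
        if (anyDuplicated(m[c("id", "tag")]))
            msg <- c(msg, "duplicate (id, tag) member rows")
        lvl <- m$tag %in% c("complex-level", "site-level")
        if (any(lvl & (is.na(m$direction) | !m$direction %in% .directions)))
            msg <- c(msg, "direction undefined for a complex/site-level member")
    }
    if (length(msg)) msg else TRUE
})

#' A pathway: a named member set plus raw interaction rows
#'
#' @slot id pathway identifier.
#' @slot sourceDb database of origin (e.g. \code{"KEGG"}).
#' @slot members character vector of protein ids (nonempty).
#' @slot interactions data.frame with columns \code{source}, \code{target},
#'   \code{type}, \code{sign}; may reference group constructs.
#' @slot groups named list mapping group-node ids to member id vectors.
#' @export
setClass("Pathway",
    representation(id = "character", sourceDb = "character",
                   members = "character", interactions = "data.frame",
                   groups = "list"))

setValidity("Pathway", function(object) {
    if (!length(object@members)) return("pathway has no members")
    it <- object@interactions
    if (nrow(it)) {
        known <- c(object@members, names(object@groups))
        if (!all(c(it$source, it$target) %in% known))
            return("interaction references an id outside members/groups")
    }
    TRUE
})

#' Annotated directed interaction network
#'
#' The merged, annotated network: one node per canonical protein (or group
#' construct), one directed edge per ordered pair, with pathway provenance,
#' reconciled interaction types and signs, GO-derived process categories,
#' phospho-tyrosine-modifier flags and dataset evidence.
#'
#' @slot nodes data.frame with columns \code{id}, \code{isGroup},
#'   \code{isPtyrModifier}, \code{unknownId} and list-columns
#'   \code{pathways}, \code{categories}, \code{evidence}, \code{groupMembers}.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} and list-columns \code{types}, \code{pathways}.
#' @slot sourceId id of the signal origin (possibly not yet set: length 0).
#' @export
setClass("AnnotatedNetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   sourceId = "character"))

setValidity("AnnotatedNetwork", function(object) {
    nd <- object@nodes; ed <- object@edges
    msg <- character()
    if (anyDuplicated(nd$id)) msg <- c(msg, "duplicated node ids")
    if (nrow(ed)) {
        if (!all(c(ed$source, ed$target) %in% nd$id))
            msg <- c(msg, "edge references a missing node")
        if (anyDuplicated(ed[c("source", "target")]))
            msg <- c(msg, "duplicate edge for an ordered (source, target) pair")
        if (any(!lengths(ed$pathways)))
            msg <- c(msg, "edge with empty pathway provenance")
    }
    grp <- nd$isGroup
    if (any(grp) && any(!lengths(nd$groupMembers[grp])))
        msg <- c(msg, "group node without members")
    if (length(object@sourceId) == 1L && !object@sourceId %in% nd$id)
        msg <- c(msg, "sourceId not present among nodes")
    if (length(msg)) msg else TRUE
})

#' Per-edge distance assignment
#'
#' Base distances follow the six-level evidence scheme; refined distances are
#' defined after a random-walk pass (\code{NA} until then).
#'
#' @slot table data.frame with columns \code{source}, \code{target},
#'   \code{base}, \code{refined}.
#' @slot scheme list of the six rule levels and the evidence-class mapping.
#' @export
setClass("DistanceAssignment",
    representation(table = "data.frame", scheme = "list"))

setValidity("DistanceAssignment", function(object) {
    tb <- object@table
    if (nrow(tb)) {
        if (any(tb$base <= 0)) return("non-positive base distance")
        if (any(!is.na(tb$refined) & tb$refined <= 0))
            return("non-positive refined distance")
    }
    TRUE
})

#' Extracted near-shortest-path subnetwork
#'
#' Nodes and edges retained on at least one acceptable source-to-target path,
#' each annotated with its overflow (extra distance of the best acceptable
#' path using it, relative to the per-target shortest distance; 0 for
#' shortest-path elements).
#'
#' @slot nodes data.frame with columns \code{id}, \code{overflow}.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{overflow}.
#' @slot perTarget data.frame of per-target edge overflows (\code{target},
#'   \code{source}, \code{to}, \code{overflow}).
#' @slot sourceId origin protein id.
#' @slot targets requested target ids.
#' @slot epsilon allowed overflow fraction (>= 0).
#' @slot shortestDist named numeric, per-target shortest distance.
#' @export
setClass("PathSubnetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   perTarget = "data.frame", sourceId = "character",
                   targets = "character", epsilon = "numeric",
                   shortestDist = "numeric"))

setValidity("PathSubnetwork", function(object) {
    msg <- character()
    if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
    if (nrow(object@nodes) && any(object@nodes$overflow < 0))
        msg <- c(msg, "negative node overflow")
    if (nrow(object@edges) && any(object@edges$overflow < 0))
        msg <- c(msg, "negative edge overflow")
    if (length(msg)) msg else TRUE
})

#' Random-walk transition model
#'
#' Row-stochastic transition structure over the source-reachable component,
#' with a uniform per-step return probability to the origin folded in as an
#' explicit return edge (terminal nodes return with probability 1).
#'
#' @slot P sparse row-stochastic matrix (\code{dgCMatrix}).
#' @slot p0 return probability to the origin node.
#' @slot nodeOrder character vector mapping row/column index to node id.
#' @export
setClass("WalkModel",
    representation(P = "dgCMatrix", p0 = "numeric", nodeOrder = "character"))

setValidity("WalkModel", function(object) {
    msg <- character()
    if (length(object@p0) != 1L || object@p0 <= 0 || object@p0 >= 1)
        msg <- c(msg, "p0 must lie strictly in (0, 1)")
    rs <- Matrix::rowSums(object@P)
    if (any(abs(rs - 1) > 1e-10))
        msg <- c(msg, "a transition row does not sum to 1 within 1e-10")
    if (any(object@P@x < 0)) msg <- c(msg, "negative transition probability")
    if (nrow(object@P) != length(object@nodeOrder))
        msg <- c(msg, "nodeOrder length mismatch")
    if (length(msg)) msg else TRUE
})

#' Stationary node scores of the weighted and topology-only walks
#'
#' @slot pi named numeric, stationary probability per node (weighted run).
#' @slot pi0 named numeric, stationary probability per node (equal-weight
#'   run), on the same node order.
#' @export
setClass("WalkScores", representation(pi = "numeric", pi0 = "numeric"))

setValidity("WalkScores", function(object) {
    msg <- character()
    if (!identical(names(object@pi), names(object@pi0)))
        msg <- c(msg, "pi and pi0 are not on the same node order")
    for (v in list(object@pi, object@pi0)) {
        if (length(v)) {
            if (any(v < 0)) msg <- c(msg, "negative stationary probability")
            if (abs(sum(v) - 1) > 1e-8)
                msg <- c(msg, "stationary vector does not sum to 1")
        }
    }
    if (length(msg)) msg else TRUE
})
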