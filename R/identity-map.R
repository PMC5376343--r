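## Identifier canonicalization across Uniprot / KEGG / HGNC namespaces.

# Uniprot-shaped accession, optionally with an isoform suffix
.ACCESSION_RE <- "^[A-Z][A-Z0-9]{5,9}(-[0-9]+)?$"

#' Strip an isoform suffix from Uniprot-shaped accessions
#'
#' Removes a trailing \code{-<digits>} isoform postfix, but only when the
#' prefix looks like a Uniprot accession; other identifiers pass unchanged.
#'
#' @param ids character vector of raw identifiers.
#' @return character vector of the same length.
#' @export
stripIsoform <- function(ids) {
    hit <- grepl(.ACCESSION_RE, ids) & grepl("-[0-9]+$", ids)
    ids[hit] <- sub("-[0-9]+$", "", ids[hit])
    ids
}

#' Build an identifier map from Uniprot id-mapping and HGNC tables
#'
#' Accessions sharing a KEGG or HGNC identifier are grouped; groups connected
#' through any shared foreign id are union-merged across namespaces. Each
#' group elects one representative canonical id, preferring reviewed entries
#' (so unreviewed accessions map to an associated reviewed entry when one
#' exists), with ties broken by lexicographic order.
#'
#' @param uniprotRows data.frame with columns \code{uniprot_id},
#'   \code{namespace}, \code{foreign_id} and logical \code{reviewed}
#'   (review status per accession; contradictory flags for one accession are
#'   a hard error).
#' @param hgncRows optional data.frame with columns \code{uniprot_id} and
#'   \code{symbol}; rows are folded in under the \code{"HGNC"} namespace.
#' @return an [IdMap-class] object.
#' @examples
#' rows <- data.frame(uniprot_id = c("U1", "U2"),
#'                    namespace = "KEGG", foreign_id = "k1",
#'                    reviewed = c(FALSE, TRUE))
#' im <- buildIdMap(rows)
#' canonicalize(c("U1", "U2"), im)  # both map to the reviewed U2
#' @export
buildIdMap <- function(uniprotRows, hgncRows = NULL) {
    need <- c("uniprot_id", "namespace", "foreign_id", "reviewed")
    if (!all(need %in% names(uniprotRows)))
        stop("uniprotRows must have columns ",
             paste(need, collapse = ", "))
    rows <- uniprotRows[need]
    if (!is.null(hgncRows) && nrow(hgncRows)) {
        rev <- setNames(uniprotRows$reviewed, uniprotRows$uniprot_id)
        rows <- rbind(rows, data.frame(
            uniprot_id = hgncRows$uniprot_id, namespace = "HGNC",
            foreign_id = hgncRows$symbol,
            reviewed = ifelse(is.na(rev[hgncRows$uniprot_id]), FALSE,
                              rev[hgncRows$uniprot_id])))
    }
    rows$uniprot_id <- stripIsoform(rows$uniprot_id)
    rows <- unique(rows)

    rev <- tapply(rows$reviewed, rows$uniprot_id, function(v) unique(v))
    bad <- names(rev)[lengths(rev) > 1L]
    if (length(bad))
        stop("contradictory review status for accession(s): ",
             paste(bad, collapse = ", "))
    reviewed <- vapply(rev, `[`, logical(1), 1L)

    ids <- sort(unique(rows$uniprot_id))
    parent <- setNames(seq_along(ids), ids)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    key <- paste(rows$namespace, rows$foreign_id, sep = "|")
    for (mem in split(match(rows$uniprot_id, ids), key)) {
        mem <- unique(mem)
        if (length(mem) > 1L) {
            r <- findRoot(mem[1L])
            for (j in mem[-1L]) parent[findRoot(j)] <- r
        }
    }
    root <- vapply(seq_along(ids), findRoot, integer(1))
    groups <- split(ids, root)
    canonOf <- setNames(rep(NA_character_, length(ids)), ids)
    groupsOut <- list()
    for (mem in groups) {
        cand <- mem[reviewed[mem]]
        rep_ <- if (length(cand)) min(cand) else min(mem)
        canonOf[mem] <- rep_
        groupsOut[[rep_]] <- mem
    }
    forward <- c(
        setNames(unname(canonOf[rows$uniprot_id]), key),
        setNames(unname(canonOf), paste0("UNIPROT|", ids)))
    forward <- forward[!duplicated(names(forward))]
    new("IdMap", forward = forward, reviewed = reviewed, groups = groupsOut)
}

#' Canonicalize protein identifiers
#'
#' Strips isoform suffixes, then resolves each id through the map. Unknown
#' ids are returned stripped but flagged (never dropped), so downstream
#' coverage can be reported. Canonicalization is idempotent.
#'
#' @param ids character vector of raw ids.
#' @param idmap an [IdMap-class].
#' @param namespace namespace to look the ids up in (default
#'   \code{"UNIPROT"}; use \code{"KEGG"} or \code{"HGNC"} for foreign ids).
#' @return character vector of canonical ids with a logical attribute
#'   \code{"unknown"} marking ids absent from the map.
#' @export
canonicalize <- function(ids, idmap, namespace = "UNIPROT") {
    stripped <- stripIsoform(as.character(ids))
    hit <- idmap@forward[paste(namespace, stripped, sep = "|")]
    unknown <- is.na(hit)
    out <- ifelse(unknown, stripped, unname(hit))
    attr(out, "unknown") <- unname(unknown)
    out
}

#' Canonical group membership
#'
#' @param idmap an [IdMap-class].
#' @return named list: canonical id to member accessions.
#' @export
canonicalGroups <- function(idmap) idmap@groups
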