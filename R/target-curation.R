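## Curation of target sets from proteomic tables: SILAC-ratio filtering,
## condition-exclusive phosphopeptides, peptide-to-protein mapping, direct
## substrates, and provenance-preserving merging.

.newTargetSet <- function(members = NULL, peptides = NULL) {
    if (is.null(members))
        members <- data.frame(id = character(), tag = character(),
                              direction = character())
    if (is.null(peptides)) peptides <- data.frame()
    rownames(members) <- NULL
    new("TargetSet", members = members, peptideRecords = peptides)
}

#' Select targets from a SILAC protein-ratio table
#'
#' Retains proteins whose SILAC ratio reflects at least the given relative
#' variation: \code{|ratio - 1| >= threshold} (the bound itself is included).
#' Direction is \code{"up"} for ratio > 1 and \code{"down"} for ratio < 1;
#' members are tagged \code{"complex-level"}.
#'
#' @param proteinRatios data.frame with columns \code{id} and
#'   \code{silac_ratio} (strictly positive; non-positive rows are rejected
#'   with a warning).
#' @param threshold relative variation in (0, 1); default 0.1 (a 10\% change).
#' @return a [TargetSet-class].
#' @examples
#' tab <- data.frame(id = c("A", "B", "C"),
#'                   silac_ratio = c(1.25, 1.02, 0.80))
#' targetMembers(selectRatioTargets(tab))
#' @export
selectRatioTargets <- function(proteinRatios, threshold = 0.1) {
    stopifnot(threshold > 0, threshold < 1)
    tab <- proteinRatios
    bad <- !is.finite(tab$silac_ratio) | tab$silac_ratio <= 0
    if (any(bad)) {
        warning(sum(bad), " row(s) with non-positive ratio rejected")
        tab <- tab[!bad, , drop = FALSE]
    }
    keep <- abs(tab$silac_ratio - 1) >= threshold - 1e-12
    tab <- tab[keep, , drop = FALSE]
    .newTargetSet(if (nrow(tab)) data.frame(
        id = tab$id, tag = "complex-level",
        direction = ifelse(tab$silac_ratio > 1, "up", "down")))
}

.peptideKey <- function(sequence, phosphosite)
    paste(toupper(sequence), phosphosite, sep = "@")

.PHOSPHOSITE_RE <- "^[STY][0-9]+(;[STY][0-9]+)*$"

#' Partition phosphopeptides by condition exclusivity
#'
#' Peptides whose (sequence, phosphosite) key is observed in both conditions
#' are excluded as not differential; the key ignores methionine oxidation, so
#' pairs differing only by oxidation state collapse and are excluded too.
#' Remaining peptides are deduplicated and partitioned by condition.
#'
#' @param peptides data.frame with columns \code{sequence},
#'   \code{phosphosite} (e.g. \code{"Y424"}; malformed rows are rejected with
#'   a warning), \code{oxidation_state} and \code{condition} (\code{"pos"} or
#'   \code{"neg"}).
#' @return list with data.frames \code{pos}, \code{neg} (condition-exclusive
#'   peptides) and \code{excluded_shared} (one row per shared key).
#' @export
selectExclusivePeptides <- function(peptides) {
    stopifnot(all(peptides$condition %in% c("pos", "neg")))
    ok <- grepl(.PHOSPHOSITE_RE, peptides$phosphosite)
    if (any(!ok)) {
        warning(sum(!ok), " row(s) with malformed phosphosite rejected")
        peptides <- peptides[ok, , drop = FALSE]
    }
    key <- .peptideKey(peptides$sequence, peptides$phosphosite)
    inPos <- unique(key[peptides$condition == "pos"])
    inNeg <- unique(key[peptides$condition == "neg"])
    shared <- intersect(inPos, inNeg)
    dedup <- peptides[!duplicated(paste(key, peptides$condition)), ,
                      drop = FALSE]
    dkey <- .peptideKey(dedup$sequence, dedup$phosphosite)
    list(
        pos = dedup[dedup$condition == "pos" & !dkey %in% shared, ,
                    drop = FALSE],
        neg = dedup[dedup$condition == "neg" & !dkey %in% shared, ,
                    drop = FALSE],
        excluded_shared = dedup[!duplicated(dkey) & dkey %in% shared, ,
                                drop = FALSE])
}

#' Map condition-exclusive peptides to proteins
#'
#' Ambiguous peptides (matching several proteins through sequence redundancy)
#' contribute all their proteins. A protein with exclusive peptides in both
#' conditions gets direction \code{"mixed"}; members are tagged
#' \code{"site-level"}.
#'
#' @param exclusivePeptides data.frame of condition-exclusive peptides with
#'   columns \code{sequence}, \code{phosphosite}, \code{condition} (typically
#'   \code{rbind} of the \code{pos}/\code{neg} parts of
#'   [selectExclusivePeptides()]).
#' @param proteinIndex data.frame with columns \code{sequence} and
#'   \code{protein_id} mapping peptide sequences to protein ids; peptides
#'   absent from the index are orphans (warning, not fatal).
#' @return a [TargetSet-class] whose \code{peptideRecords} retain the mapped
#'   peptide rows.
#' @export
mapPeptidesToProteins <- function(exclusivePeptides, proteinIndex) {
    pep <- exclusivePeptides
    if (!nrow(pep)) return(.newTargetSet())
    idx <- split(proteinIndex$protein_id, toupper(proteinIndex$sequence))
    prots <- idx[toupper(pep$sequence)]
    orphan <- !lengths(prots)
    if (any(orphan))
        warning(sum(orphan), " orphan peptide(s) matched no protein")
    rec <- data.frame(
        protein_id = unlist(prots, use.names = FALSE),
        sequence = rep(pep$sequence, lengths(prots)),
        phosphosite = rep(pep$phosphosite, lengths(prots)),
        condition = rep(pep$condition, lengths(prots)))
    if (!nrow(rec)) return(.newTargetSet())
    dir <- tapply(rec$condition, rec$protein_id, function(cc)
        if (all(cc == "pos")) "up" else if (all(cc == "neg")) "down"
        else "mixed")
    .newTargetSet(
        data.frame(id = names(dir), tag = "site-level",
                   direction = unname(dir)),
        rec)
}

#' Select direct substrates of the source kinase
#'
#' A protein from the in-vitro kinase dataset is a direct substrate iff at
#' least one of its in-vitro phosphopeptides is also found in the cellular
#' condition-exclusive positive set, after applying configured per-protein or
#' per-peptide exclusions and forced inclusions (see [curationDefaults()] for
#' the shipped reference configuration). Sequence comparison ignores
#' case-based modification marks.
#'
#' @param invitroPeptides data.frame with columns \code{protein_id} and
#'   \code{sequence} (peptides phosphorylated in vitro).
#' @param cellularPosPeptides character vector of peptide sequences exclusive
#'   to the positive cellular condition.
#' @param curation list with elements \code{exclude_proteins} (ids),
#'   \code{exclude_peptides} (data.frame \code{protein_id}, \code{sequence})
#'   and \code{include_proteins} (ids); exclusions naming absent ids warn.
#' @return a [TargetSet-class] tagged \code{"direct-substrate"} (direction
#'   \code{"up"}).
#' @export
selectDirectSubstrates <- function(invitroPeptides, cellularPosPeptides,
                                   curation = list()) {
    exP <- curation$exclude_proteins %||% character()
    exPep <- curation$exclude_peptides %||%
        data.frame(protein_id = character(), sequence = character())
    incl <- curation$include_proteins %||% character()
    miss <- setdiff(exP, invitroPeptides$protein_id)
    if (length(miss))
        warning("exclusion of absent protein(s): ",
                paste(miss, collapse = ", "))
    pep <- invitroPeptides[!invitroPeptides$protein_id %in% exP, ,
                           drop = FALSE]
    if (nrow(exPep)) {
        drop <- paste(pep$protein_id, toupper(pep$sequence)) %in%
            paste(exPep$protein_id, toupper(exPep$sequence))
        pep <- pep[!drop, , drop = FALSE]
    }
    hit <- toupper(pep$sequence) %in% toupper(cellularPosPeptides)
    ids <- sort(unique(c(pep$protein_id[hit], incl)))
    .newTargetSet(
        if (length(ids)) data.frame(id = ids, tag = "direct-substrate",
                                    direction = "up"),
        pep[hit, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge curated target sets
#'
#' Union of members with dataset tags accumulated; the same (id, tag) from
#' several sets keeps one row (conflicting directions become
#' \code{"mixed"}). The merge is commutative and associative on member sets.
#'
#' @param sets list of [TargetSet-class] objects (ids already canonical).
#' @return a merged [TargetSet-class].
#' @seealso [targetOverlap()] for the per-tag-combination overlap report.
#' @export
mergeTargetSets <- function(sets) {
    m <- do.call(rbind, lapply(sets, targetMembers))
    precs <- Filter(function(d) nrow(d) > 0, lapply(sets, peptideRecords))
    allCols <- unique(unlist(lapply(precs, names)))
    p <- do.call(rbind, lapply(precs, function(d) {
        d[setdiff(allCols, names(d))] <- NA
        d[allCols]
    }))
    if (is.null(m) || !nrow(m)) return(.newTargetSet(peptides = p))
    key <- paste(m$id, m$tag)
    dir <- tapply(m$direction, key, function(d) {
        d <- unique(d[!is.na(d)])
        if (!length(d)) NA_character_
        else if (length(d) == 1L) d else "mixed"
    })
    first <- m[!duplicated(key), , drop = FALSE]
    first$direction <- unname(dir[paste(first$id, first$tag)])
    first <- first[order(first$id, first$tag), , drop = FALSE]
    .newTargetSet(first, p)
}

#' Overlap report for target sets
#'
#' Counts proteins per combination of dataset tags (and, for a list of named
#' sets, per combination of set membership).
#'
#' @param sets named list of [TargetSet-class] objects.
#' @return data.frame with columns \code{combination} and \code{n}.
#' @export
targetOverlap <- function(sets) {
    idsBy <- lapply(sets, function(s) unique(targetMembers(s)$id))
    all <- sort(unique(unlist(idsBy)))
    comb <- vapply(all, function(id) paste(
        names(sets)[vapply(idsBy, function(v) id %in% v, logical(1))],
        collapse = "+"), character(1))
    tb <- table(comb)
    data.frame(combination = names(tb), n = as.integer(tb),
               row.names = NULL)
}

#' Shipped reference curation configuration
#'
#' The hand-curated exclusion/inclusion lists used when selecting direct
#' substrates of Syk from the in-vitro kinase dataset, shipped as a YAML
#' config so the mechanism stays general: proteins whose in-vitro
#' phosphopeptides were not retrieved exclusively in Syk-expressing cells
#' (FHL2, PTPN11, PTPN1, cortactin, vimentin, PTPN12), one excluded MAP1B
#' peptide, and the forced cofilin-1/2 inclusions.
#'
#' @param path optional path to an alternative YAML file.
#' @return list with \code{exclude_proteins}, \code{exclude_peptides},
#'   \code{include_proteins}.
#' @export
curationDefaults <- function(path = system.file("extdata", "config",
                                                "curation.yaml",
                                                package = "SigNetPath")) {
    cfg <- yaml::read_yaml(path)
    cfg$exclude_peptides <- if (length(cfg$exclude_peptides))
        do.call(rbind, lapply(cfg$exclude_peptides, as.data.frame))
    else data.frame(protein_id = character(), sequence = character())
    cfg
}
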