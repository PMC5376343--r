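## Readers for the standard input formats: GMT gene sets, KEGG KGML,
## Pathway Commons extended SIF, OBO ontologies, GAF annotations, Uniprot
## id-mapping and HGNC tables, and the proteomic target tables.

#' @importFrom utils read.delim
NULL

#' Read a GMT gene-set file
#'
#' Uses \pkg{fgsea}'s reader when available, otherwise a minimal fallback.
#'
#' @param path GMT file path.
#' @param sourceDb database label stored on the returned pathways.
#' @return list of [Pathway-class] objects (membership only, no
#'   interactions).
#' @export
readGmt <- function(path, sourceDb = "GMT") {
    sets <- if (requireNamespace("fgsea", quietly = TRUE))
        fgsea::gmtPathways(path)
    else {
        lines <- strsplit(readLines(path), "\t", fixed = TRUE)
        setNames(lapply(lines, function(x) x[-(1:2)]),
                 vapply(lines, `[`, character(1), 1L))
    }
    lapply(names(sets), function(nm)
        new("Pathway", id = nm, sourceDb = sourceDb,
            members = unique(sets[[nm]]),
            interactions = .emptyInteractions(), groups = list()))
}

.emptyInteractions <- function()
    data.frame(source = character(), target = character(),
               type = character(), sign = character())

#' Shipped relation-type mapping tables
#'
#' Maps KGML relation subtypes and extended-SIF relation names to the three
#' interaction type labels (phosphorylation, modification, regulation; plus
#' \code{other}) and a sign. Editable: supply an alternative YAML.
#'
#' @param path optional alternative YAML path.
#' @return list with elements \code{kgml} and \code{sif}; each a named list
#'   of \code{list(type=, sign=)}.
#' @export
relationTypeMap <- function(path = system.file("extdata", "config",
                                               "relation-map.yaml",
                                               package = "SigNetPath")) {
    yaml::read_yaml(path)
}

#' Read a KEGG KGML pathway file
#'
#' Gene entries become members (raw KEGG ids, to be canonicalized against an
#' [IdMap-class] with namespace \code{"KEGG"}); multi-gene entries and
#' explicit group entries become group constructs; relations become typed,
#' signed interactions via [relationTypeMap()].
#'
#' @param path KGML (XML) file path.
#' @param typeMap relation mapping, see [relationTypeMap()].
#' @return a [Pathway-class] object.
#' @export
readKgml <- function(path, typeMap = relationTypeMap()) {
    doc <- xml2::read_xml(path)
    pid <- xml2::xml_attr(doc, "name")
    entries <- xml2::xml_find_all(doc, ".//entry")
    eid <- xml2::xml_attr(entries, "id")
    etype <- xml2::xml_attr(entries, "type")
    ename <- xml2::xml_attr(entries, "name")
    entryIds <- list()   # KGML entry id -> node id used in interactions
    groups <- list()
    members <- character()
    for (i in seq_along(entries)) {
        if (etype[i] == "gene") {
            genes <- strsplit(ename[i], " ", fixed = TRUE)[[1]]
            genes <- genes[nzchar(genes)]
            members <- c(members, genes)
            if (length(genes) == 1L) {
                entryIds[[eid[i]]] <- genes
            } else {
                gid <- sprintf("group:%s:%s", pid, eid[i])
                groups[[gid]] <- genes
                entryIds[[eid[i]]] <- gid
            }
        }
    }
    for (i in which(etype == "group")) {
        comp <- xml2::xml_attr(
            xml2::xml_find_all(entries[[i]], ".//component"), "id")
        mem <- unlist(entryIds[comp], use.names = FALSE)
        if (length(mem)) {
            gid <- sprintf("group:%s:%s", pid, eid[i])
            groups[[gid]] <- mem
            entryIds[[eid[i]]] <- gid
        }
    }
    rels <- xml2::xml_find_all(doc, ".//relation")
    rows <- lapply(rels, function(r) {
        a <- entryIds[[xml2::xml_attr(r, "entry1")]]
        b <- entryIds[[xml2::xml_attr(r, "entry2")]]
        if (is.null(a) || is.null(b)) return(NULL)
        subs <- xml2::xml_attr(xml2::xml_find_all(r, ".//subtype"), "name")
        if (!length(subs)) subs <- NA_character_
        do.call(rbind, lapply(subs, function(s) {
            mp <- typeMap$kgml[[s]] %||% list(type = "other",
                                              sign = "unknown")
            data.frame(source = a, target = b, type = mp$type,
                       sign = mp$sign)
        }))
    })
    it <- do.call(rbind, rows)
    new("Pathway", id = pid, sourceDb = "KEGG",
        members = unique(members),
        interactions = if (is.null(it)) .emptyInteractions() else it,
        groups = groups)
}

#' Read a Pathway Commons extended-SIF file
#'
#' Expects tab-separated columns \code{PARTICIPANT_A},
#' \code{INTERACTION_TYPE}, \code{PARTICIPANT_B} and optionally
#' \code{PATHWAY_NAMES} (semicolon-separated); with the pathway column, one
#' [Pathway-class] per named pathway is returned, otherwise a single pathway
#' under \code{defaultId}.
#'
#' @param path file path (header optional for the 3-column form).
#' @param defaultId pathway id used when no pathway column is present.
#' @param sourceDb database label.
#' @param typeMap relation mapping, see [relationTypeMap()].
#' @return list of [Pathway-class] objects.
#' @export
readExtendedSif <- function(path, defaultId = basename(path),
                            sourceDb = "PathwayCommons",
                            typeMap = relationTypeMap()) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("PARTICIPANT", first, fixed = TRUE)
    tab <- read.delim(path, header = hasHeader,
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (!hasHeader)
        names(tab)[1:3] <- c("PARTICIPANT_A", "INTERACTION_TYPE",
                             "PARTICIPANT_B")
    mp <- lapply(tab$INTERACTION_TYPE, function(s)
        typeMap$sif[[s]] %||% list(type = "other", sign = "unknown"))
    rows <- data.frame(source = tab$PARTICIPANT_A,
                       target = tab$PARTICIPANT_B,
                       type = vapply(mp, `[[`, character(1), "type"),
                       sign = vapply(mp, `[[`, character(1), "sign"))
    pwNames <- if ("PATHWAY_NAMES" %in% names(tab))
        strsplit(tab$PATHWAY_NAMES, ";", fixed = TRUE)
    else rep(list(defaultId), nrow(tab))
    long <- rows[rep(seq_len(nrow(rows)), lengths(pwNames)), , drop = FALSE]
    long$pathway <- unlist(pwNames)
    lapply(split(long, long$pathway), function(d)
        new("Pathway", id = d$pathway[1L], sourceDb = sourceDb,
            members = unique(c(d$source, d$target)),
            interactions = d[c("source", "target", "type", "sign")],
            groups = list()))
}

#' Read a (go-basic style) OBO ontology
#'
#' Minimal reader covering what annotation closure needs: term ids,
#' \code{is_a} parents and optionally \code{part_of} relationships.
#' Obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @return list with \code{terms} (character), \code{is_a} and
#'   \code{part_of} (named lists: term to parent ids).
#' @export
readObo <- function(path) {
    lines <- readLines(path)
    termStarts <- which(lines == "[Term]")
    blockEnd <- c(which(grepl("^\\[", lines))[-1] - 1L, length(lines))
    terms <- character(); isa <- list(); partof <- list()
    for (s in termStarts) {
        e <- blockEnd[match(TRUE, blockEnd >= s)]
        blk <- lines[s:e]
        if (any(grepl("^is_obsolete: true", blk))) next
        id <- sub("^id: *", "", grep("^id: ", blk, value = TRUE)[1])
        terms <- c(terms, id)
        pa <- sub(" !.*$", "", sub("^is_a: *", "",
                                   grep("^is_a: ", blk, value = TRUE)))
        po <- grep("^relationship: part_of ", blk, value = TRUE)
        po <- sub(" !.*$", "", sub("^relationship: part_of *", "", po))
        if (length(pa)) isa[[id]] <- pa
        if (length(po)) partof[[id]] <- po
    }
    list(terms = unique(terms), is_a = isa, part_of = partof)
}

#' Descendant closure of ontology terms
#'
#' All terms whose \code{is_a} (and optionally \code{part_of}) ancestry
#' reaches one of the given terms, including the terms themselves. Terms
#' absent from the ontology trigger a warning.
#'
#' @param obo ontology from [readObo()].
#' @param termIds character vector of ancestor term ids.
#' @param includePartOf also follow \code{part_of} edges (default FALSE).
#' @return character vector of term ids.
#' @export
termDescendants <- function(obo, termIds, includePartOf = FALSE) {
    miss <- setdiff(termIds, obo$terms)
    if (length(miss))
        warning("term(s) absent from ontology: ",
                paste(miss, collapse = ", "))
    up <- obo$is_a
    if (includePartOf)
        for (id in names(obo$part_of))
            up[[id]] <- unique(c(up[[id]], obo$part_of[[id]]))
    children <- list()
    for (id in names(up))
        for (p in up[[id]]) children[[p]] <- c(children[[p]], id)
    seen <- unique(termIds)
    queue <- seen
    while (length(queue)) {
        nxt <- unique(unlist(children[queue], use.names = FALSE))
        nxt <- setdiff(nxt, seen)
        seen <- c(seen, nxt)
        queue <- nxt
    }
    seen
}

#' Read a GAF annotation file
#'
#' @param path GAF 2.x file path (\code{!} comment lines skipped).
#' @param evidenceExclude evidence codes to drop (default none; e.g.
#'   \code{"IEA"}).
#' @return data.frame with columns \code{protein_id}, \code{go_id},
#'   \code{evidence}.
#' @export
readGaf <- function(path, evidenceExclude = character()) {
    tab <- read.delim(path, header = FALSE, comment.char = "!",
                      stringsAsFactors = FALSE)
    out <- data.frame(protein_id = tab[[2]], go_id = tab[[5]],
                      evidence = if (ncol(tab) >= 7) tab[[7]]
                                 else NA_character_)
    if (length(evidenceExclude))
        out <- out[!out$evidence %in% evidenceExclude, , drop = FALSE]
    unique(out)
}

#' Read a Uniprot id-mapping table
#'
#' Three-column TSV (accession, namespace, foreign id); an optional fourth
#' \code{reviewed} column (yes/no or logical) gives review status, default
#' unreviewed.
#'
#' @param path TSV file path (no header).
#' @return data.frame with columns \code{uniprot_id}, \code{namespace},
#'   \code{foreign_id}, \code{reviewed}.
#' @export
readUniprotMapping <- function(path) {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(uniprot_id = tab[[1]], namespace = tab[[2]],
               foreign_id = as.character(tab[[3]]),
               reviewed = if (ncol(tab) >= 4)
                   tab[[4]] %in% c(TRUE, "yes", "reviewed", "TRUE")
               else FALSE)
}

#' Read an HGNC symbol table
#'
#' @param path TSV with a header containing at least \code{symbol} and
#'   \code{uniprot_id} columns.
#' @return data.frame with columns \code{uniprot_id}, \code{symbol}.
#' @export
readHgncTable <- function(path) {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("symbol", "uniprot_id") %in% names(tab)))
    tab[c("uniprot_id", "symbol")]
}

#' Read the proteomic target tables
#'
#' \code{readRatioTable}: per-protein SILAC ratios (columns \code{id},
#' \code{silac_ratio}). \code{readPeptideTable}: per-peptide phosphosite
#' observations (columns \code{sequence}, \code{phosphosite},
#' \code{oxidation_state}, \code{condition}). \code{readPeptideIndex}:
#' peptide-to-protein mapping (columns \code{sequence}, \code{protein_id}).
#' All are header-carrying TSV (convert spreadsheet supplements to TSV once;
#' the package itself has no spreadsheet dependency).
#'
#' @param path TSV file path.
#' @return data.frame with the documented columns.
#' @export
readRatioTable <- function(path) {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "silac_ratio") %in% names(tab)))
    tab
}

#' @rdname readRatioTable
#' @export
readPeptideTable <- function(path) {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("sequence", "phosphosite", "condition") %in% names(tab)))
    if (!"oxidation_state" %in% names(tab)) tab$oxidation_state <- "none"
    tab
}

#' @rdname readRatioTable
#' @export
readPeptideIndex <- function(path) {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("sequence", "protein_id") %in% names(tab)))
    tab
}
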