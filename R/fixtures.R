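## Synthetic fixture bundles with planted ground truth: pathway collections
## (KGML + extended SIF + GMT), GO stub ontology and annotations, id-mapping
## tables and proteomic target tables, all in the standard text formats the
## real readers consume. The generator certifies its own ground truth: noise
## edges never create a route from the source to a planted target shorter
## than the planted path.

#' @importFrom stats runif
NULL

#' Specification of a synthetic fixture
#'
#' @param nProteins number of proteins in the universe.
#' @param nPathways number of pathways (the first \code{nPlanted} carry the
#'   planted paths).
#' @param pathwaySizeRange integer range of pathway sizes.
#' @param nPlanted number of planted source -> kinase -> target paths.
#' @param chainLength intermediates per planted path (>= 1; the first chain
#'   node is the kinase).
#' @param noiseEdges total number of random intra-pathway edges.
#' @param targetFraction fraction of proteins carrying dataset evidence.
#' @param sharedPeptides phosphopeptides planted in both conditions (thus
#'   excluded by curation), in addition to \code{oxidationPairs} pairs
#'   differing only by methionine oxidation.
#' @param oxidationPairs shared pairs differing only by oxidation state.
#' @param seed RNG seed; a fixed seed yields byte-identical outputs.
#' @return a \code{fixtureSpec} list.
#' @export
fixtureSpec <- function(nProteins = 60, nPathways = 6,
                        pathwaySizeRange = c(8, 15), nPlanted = 1,
                        chainLength = 1, noiseEdges = 80,
                        targetFraction = 0.15, sharedPeptides = 5,
                        oxidationPairs = 2, seed = 1) {
    stopifnot(nProteins >= nPlanted * (chainLength + 1) + 2,
              chainLength >= 1, nPathways >= nPlanted,
              pathwaySizeRange[1] >= chainLength + 2)
    structure(list(nProteins = nProteins, nPathways = nPathways,
                   pathwaySizeRange = pathwaySizeRange,
                   nPlanted = nPlanted, chainLength = chainLength,
                   noiseEdges = noiseEdges,
                   targetFraction = targetFraction,
                   sharedPeptides = sharedPeptides,
                   oxidationPairs = oxidationPairs, seed = seed),
              class = "fixtureSpec")
}

.fxIds <- function(n) sprintf("P%05d", seq_len(n))

.randSeq <- function(n, len = 10L) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVW", "")[[1]]
    vapply(seq_len(n), function(i)
        paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}

# Internal: lay out roles, pathways and edges; certify planted shortest.
.fxDesign <- function(spec) {
    set.seed(spec$seed)
    ids <- .fxIds(spec$nProteins)
    source <- ids[1L]
    cursor <- 2L
    planted <- list()
    for (k in seq_len(spec$nPlanted)) {
        chain <- ids[cursor:(cursor + spec$chainLength - 1L)]
        target <- ids[cursor + spec$chainLength]
        cursor <- cursor + spec$chainLength + 1L
        planted[[k]] <- list(kinase = chain[1L], chain = chain,
                             target = target,
                             nodes = c(source, chain, target))
    }
    modifiers <- c(source, vapply(planted, `[[`, character(1), "kinase"))
    plantedNodes <- unique(unlist(lapply(planted, `[[`, "nodes")))
    # dataset evidence: site-level = chains + targets + random extras;
    # complex-level = source + random extras
    nSite <- max(length(plantedNodes) - 1L,
                 round(spec$targetFraction * spec$nProteins))
    pool <- setdiff(ids, plantedNodes)
    siteTargets <- unique(c(setdiff(plantedNodes, source),
                            sample(pool, max(0L, nSite -
                                             (length(plantedNodes) - 1L)))))
    pool2 <- setdiff(pool, siteTargets)
    complexTargets <- unique(c(source,
                               sample(pool2, min(length(pool2), 5L))))
    # pathway membership: pathway k <= nPlanted hosts planted path k
    sizes <- sample(spec$pathwaySizeRange[1]:spec$pathwaySizeRange[2],
                    spec$nPathways, replace = TRUE)
    members <- vector("list", spec$nPathways)
    for (k in seq_len(spec$nPathways)) {
        if (k <= spec$nPlanted) {
            need <- planted[[k]]$nodes
            extraTargets <- sample(setdiff(siteTargets, need),
                                   min(4L, length(setdiff(siteTargets,
                                                          need))))
            fill <- sample(setdiff(ids, c(need, extraTargets)),
                           max(0L, sizes[k] - length(need) -
                               length(extraTargets)))
            members[[k]] <- unique(c(need, extraTargets, fill))
        } else {
            # noise pathways are drawn mostly from non-target proteins
            nonT <- setdiff(ids, c(siteTargets, complexTargets))
            members[[k]] <- unique(sample(nonT, min(sizes[k],
                                                    length(nonT))))
        }
    }
    plantedEdges <- do.call(rbind, lapply(planted, function(p) {
        v <- p$nodes
        data.frame(source = v[-length(v)], target = v[-1])
    }))
    plantedDist <- vapply(planted, function(p) length(p$nodes) - 1,
                          numeric(1))  # all planted edges have d = 1
    names(plantedDist) <- vapply(planted, `[[`, character(1), "target")

    evid <- setNames(rep(list(character()), length(ids)), ids)
    for (i in siteTargets) evid[[i]] <- c(evid[[i]], "site-level")
    for (i in complexTargets) evid[[i]] <- c(evid[[i]], "complex-level")
    isMod <- setNames(ids %in% modifiers, ids)
    scheme <- distanceScheme()
    edgeDist <- function(s, t) {
        mapply(function(a, b) assignDistance(evid[[a]], isMod[[a]],
                                             evid[[b]], scheme), s, t)
    }
    drawNoise <- function(k) {
        mem <- members[[k]]
        # modifier sources are reserved for curated (planted) edges
        src <- sample(setdiff(mem, modifiers), 1L)
        tgt <- sample(setdiff(mem, src), 1L)
        c(src, tgt)
    }
    perPw <- table(sample(seq_len(spec$nPathways), spec$noiseEdges,
                          replace = TRUE,
                          prob = lengths(members)))
    noise <- do.call(rbind, lapply(names(perPw), function(k) {
        k <- as.integer(k)
        t(replicate(perPw[[as.character(k)]], drawNoise(k))) |>
            (\(m) data.frame(source = m[, 1], target = m[, 2],
                             pathway = k))()
    }))
    pkey <- paste(plantedEdges$source, plantedEdges$target)
    noise <- noise[!paste(noise$source, noise$target) %in% pkey, ,
                   drop = FALSE]
    # certification: no route to a planted target may beat the planted path
    for (iter in seq_len(200L)) {
        allE <- rbind(plantedEdges,
                      noise[c("source", "target")])
        allE <- allE[!duplicated(paste(allE$source, allE$target)), ,
                     drop = FALSE]
        w <- edgeDist(allE$source, allE$target)
        g <- igraph::graph_from_data_frame(
            cbind(allE, weight = w), directed = TRUE,
            vertices = data.frame(name = ids))
        d <- igraph::distances(g, v = source, mode = "out",
                               weights = igraph::E(g)$weight)[1, ]
        offend <- names(plantedDist)[d[names(plantedDist)] <
                                     plantedDist - 1e-9]
        if (!length(offend)) break
        # resample noise edges entering offended targets or their chains
        hot <- unique(unlist(lapply(planted, function(p)
            if (p$target %in% offend) p$nodes)))
        bad <- which(noise$target %in% hot)
        for (b in bad) {
            nd <- drawNoise(noise$pathway[b])
            noise$source[b] <- nd[1]; noise$target[b] <- nd[2]
        }
        if (iter == 200L)
            stop("could not certify planted paths as shortest")
    }
    list(ids = ids, source = source, planted = planted,
         modifiers = modifiers, siteTargets = siteTargets,
         complexTargets = complexTargets, members = members,
         plantedEdges = plantedEdges, plantedDist = plantedDist,
         noise = noise, evid = evid)
}

# Internal: KGML text for the planted pathway (exercises the KGML reader,
# group constructs and KEGG-namespace canonicalization end to end).
.fxKgml <- function(pid, mem, edges, ids, groupMembers) {
    kegg <- setNames(sprintf("hsa:%d", match(mem, ids)), mem)
    ent <- sprintf(
        '  <entry id="%d" name="%s" type="gene"/>',
        seq_along(mem), kegg)
    gid <- length(mem) + 1L
    grp <- c(sprintf('  <entry id="%d" type="group">', gid),
             sprintf('    <component id="%d"/>',
                     match(groupMembers, mem)),
             "  </entry>")
    eIdx <- setNames(seq_along(mem), mem)
    rel <- vapply(seq_len(nrow(edges)), function(i) {
        sub <- if (edges$phospho[i])
            paste0('<subtype name="phosphorylation" value="+p"/>',
                   '<subtype name="activation" value="--&gt;"/>')
        else '<subtype name="binding/association" value="---"/>'
        sprintf('  <relation entry1="%d" entry2="%d" type="PPrel">%s</relation>',
                eIdx[[edges$source[i]]], eIdx[[edges$target[i]]], sub)
    }, character(1))
    # one relation from the first group member's upstream node to the group
    relG <- sprintf(
        '  <relation entry1="%d" entry2="%d" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
        eIdx[[groupMembers[1]]], gid)
    c(sprintf('<pathway name="path:%s" org="hsa" number="1" title="%s">',
              pid, pid),
      ent, grp, rel, relG, "</pathway>")
}

#' Generate a synthetic fixture bundle on disk
#'
#' Writes pathway files (the planted pathways as KGML with a group
#' construct, the rest as extended SIF), a GMT membership file, a GAF
#' annotation table (the source and every planted kinase carry GO:0004713;
#' planted targets carry a child term of the adhesion group), an OBO stub
#' ontology, a Uniprot id-mapping TSV (with grouped unreviewed accessions)
#' and the proteomic target tables of
#' [generateTwoDatasetTables()]. Outputs are byte-identical for a fixed
#' seed.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{files} (paths) and
#'   \code{groundTruth} (source, planted edges and per-target planted
#'   distance, target ids, modifiers, pathway membership).
#' @export
generateFixture <- function(spec, dir) {
    dsn <- .fxDesign(spec)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ids <- dsn$ids
    pids <- sprintf("syn%05d", seq_len(spec$nPathways))
    files <- list()

    # --- pathway files ----------------------------------------------------
    edgesOf <- function(k) {
        pl <- if (k <= spec$nPlanted) {
            pe <- dsn$planted[[k]]
            v <- pe$nodes
            data.frame(source = v[-length(v)], target = v[-1],
                       phospho = TRUE)
        } else NULL
        nz <- dsn$noise[dsn$noise$pathway == k, c("source", "target")]
        if (nrow(nz)) nz$phospho <- FALSE
        unique(rbind(pl, if (nrow(nz)) nz))
    }
    sifRows <- list()
    for (k in seq_len(spec$nPathways)) {
        ed <- edgesOf(k)
        if (k <= spec$nPlanted) {
            mem <- dsn$members[[k]]
            grpMem <- setdiff(mem, c(dsn$planted[[k]]$nodes))[1:2]
            kg <- .fxKgml(pids[k], mem, ed, ids, grpMem)
            f <- file.path(dir, paste0(pids[k], ".xml"))
            writeLines(kg, f)
            files$kgml <- c(files$kgml, f)
        } else if (!is.null(ed) && nrow(ed)) {
            sifRows[[k]] <- data.frame(
                PARTICIPANT_A = ed$source,
                INTERACTION_TYPE = ifelse(ed$phospho,
                                          "controls-phosphorylation-of",
                                          "interacts-with"),
                PARTICIPANT_B = ed$target, PATHWAY_NAMES = pids[k])
        }
    }
    sif <- do.call(rbind, sifRows)
    files$sif <- file.path(dir, "interactions.sif")
    write.table(sif, files$sif, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files$gmt <- file.path(dir, "pathways.gmt")
    writeLines(vapply(seq_len(spec$nPathways), function(k)
        paste(c(pids[k], "synthetic", dsn$members[[k]]), collapse = "\t"),
        character(1)), files$gmt)

    # --- ontology stub and annotations ------------------------------------
    grp <- goTermGroups()
    allTerms <- unique(c(unlist(grp$categories), grp$modifier_terms))
    obo <- c("format-version: 1.2",
             unlist(lapply(allTerms, function(t)
                 c("", "[Term]", paste0("id: ", t),
                   paste0("name: stub ", t)))),
             "", "[Term]", "id: GO:9000001", "name: synthetic child",
             "is_a: GO:0007155 ! cell adhesion",
             "", "[Term]", "id: GO:9000002",
             "name: synthetic kinase child",
             "is_a: GO:0004713 ! protein tyrosine kinase activity")
    files$obo <- file.path(dir, "ontology.obo")
    writeLines(obo, files$obo)
    gafRow <- function(id, go) sprintf(
        "UniProtKB\t%s\t%s\t\t%s\t PMID:0\tIDA\t\tF\t\t\tprotein\ttaxon:9606\t20150101\tSYN\t\t",
        id, id, go)
    gaf <- c("!gaf-version: 2.1",
             gafRow(dsn$source, "GO:0004713"),
             vapply(dsn$planted, function(p) gafRow(p$kinase,
                                                    "GO:9000002"),
                    character(1)),
             vapply(dsn$planted, function(p) gafRow(p$target,
                                                    "GO:9000001"),
                    character(1)),
             gafRow(dsn$source, "GO:0007155"),
             vapply(sample(ids, 6L), function(i)
                 gafRow(i, "GO:0008283"), character(1)))
    files$gaf <- file.path(dir, "annotations.gaf")
    writeLines(gaf, files$gaf)

    # --- id mapping --------------------------------------------------------
    idm <- data.frame(uniprot_id = ids, namespace = "KEGG",
                      foreign_id = sprintf("hsa:%d", seq_along(ids)),
                      reviewed = "yes")
    # a couple of unreviewed accessions grouped with reviewed ones
    extra <- data.frame(uniprot_id = c("X99901", "X99902"),
                        namespace = "KEGG",
                        foreign_id = sprintf("hsa:%d", 1:2),
                        reviewed = "no")
    files$idmapping <- file.path(dir, "idmapping.tsv")
    write.table(rbind(idm, extra), files$idmapping, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)

    # --- proteomic tables ---------------------------------------------------
    tabs <- generateTwoDatasetTables(spec, dsn)
    files$ratio <- file.path(dir, "ratio_targets.tsv")
    write.table(tabs$ratio, files$ratio, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files$peptides <- file.path(dir, "peptides.tsv")
    write.table(tabs$peptides, files$peptides, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files$peptideIndex <- file.path(dir, "peptide_index.tsv")
    write.table(tabs$index, files$peptideIndex, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files$invitro <- file.path(dir, "invitro_peptides.tsv")
    write.table(tabs$invitro, files$invitro, sep = "\t", quote = FALSE,
                row.names = FALSE)

    groundTruth <- list(
        source = dsn$source, plantedEdges = dsn$plantedEdges,
        plantedDist = dsn$plantedDist,
        plantedTargets = vapply(dsn$planted, `[[`, character(1),
                                "target"),
        modifiers = dsn$modifiers, siteTargets = dsn$siteTargets,
        complexTargets = dsn$complexTargets,
        plantedPathways = pids[seq_len(spec$nPlanted)],
        pathwayMembers = setNames(dsn$members, pids),
        tables = tabs$truth)
    invisible(list(files = files, groundTruth = groundTruth))
}

#' Generate the two proteomic dataset tables with known filter outputs
#'
#' The SILAC ratio table has controlled fractions above and below the 10\%
#' band (complex-level targets drawn outside it, all other proteins well
#' inside), and the peptide table has controlled counts of
#' condition-exclusive and shared peptides, including pairs differing only
#' by methionine oxidation, so curation outputs are known by construction.
#'
#' @param spec a [fixtureSpec()].
#' @param design internal design (computed from \code{spec} when NULL).
#' @return list with data.frames \code{ratio}, \code{peptides},
#'   \code{index}, \code{invitro} and a \code{truth} list of expected
#'   curation counts.
#' @export
generateTwoDatasetTables <- function(spec, design = NULL) {
    dsn <- design %||% .fxDesign(spec)
    ids <- dsn$ids
    up <- dsn$complexTargets[seq_len(ceiling(length(dsn$complexTargets) /
                                             2))]
    down <- setdiff(dsn$complexTargets, up)
    others <- setdiff(ids, dsn$complexTargets)
    ratio <- rbind(
        data.frame(id = up, silac_ratio = round(runif(length(up), 1.15,
                                                      1.6), 3)),
        data.frame(id = down, silac_ratio = round(runif(length(down),
                                                        0.6, 0.85), 3)),
        data.frame(id = others, silac_ratio = round(runif(length(others),
                                                          0.96, 1.04),
                                                    3)))
    ratio <- ratio[order(ratio$id), ]

    # exclusive positive peptides for every site-level target
    st <- sort(dsn$siteTargets)
    seqs <- .randSeq(length(st) + spec$sharedPeptides +
                     spec$oxidationPairs + 2L)
    posPep <- data.frame(sequence = seqs[seq_along(st)],
                         phosphosite = sprintf("Y%d", 100 + seq_along(st)),
                         oxidation_state = "none", condition = "pos")
    index <- data.frame(sequence = posPep$sequence, protein_id = st)
    # one ambiguous peptide: maps to two proteins (both included)
    ambig <- seqs[length(st) + spec$sharedPeptides +
                  spec$oxidationPairs + 1L]
    posPep <- rbind(posPep, data.frame(sequence = ambig,
                                       phosphosite = "Y500",
                                       oxidation_state = "none",
                                       condition = "pos"))
    index <- rbind(index, data.frame(sequence = ambig,
                                     protein_id = st[1:2]))
    # a negative-exclusive peptide for the first target -> direction mixed
    negSeq <- seqs[length(st) + spec$sharedPeptides +
                   spec$oxidationPairs + 2L]
    negPep <- data.frame(sequence = negSeq, phosphosite = "Y600",
                         oxidation_state = "none", condition = "neg")
    index <- rbind(index, data.frame(sequence = negSeq,
                                     protein_id = st[1]))
    # shared peptides (both conditions) incl. oxidation-only pairs
    nShared <- spec$sharedPeptides + spec$oxidationPairs
    shSeq <- seqs[length(st) + seq_len(nShared)]
    ox <- c(rep(FALSE, spec$sharedPeptides), rep(TRUE,
                                                 spec$oxidationPairs))
    shared <- do.call(rbind, lapply(seq_len(nShared), function(i) {
        data.frame(sequence = shSeq[i],
                   phosphosite = sprintf("Y%d", 700 + i),
                   oxidation_state = c("none",
                                       if (ox[i]) "ox" else "none"),
                   condition = c("pos", "neg"))
    }))
    sharedHost <- setdiff(dsn$ids, c(st, dsn$complexTargets))
    index <- rbind(index, data.frame(sequence = shSeq,
                                     protein_id = sharedHost[
                                         seq_len(nShared)]))
    peptides <- rbind(posPep, negPep, shared)
    # in-vitro kinase peptides: the planted targets' positive peptides
    plT <- vapply(dsn$planted, `[[`, character(1), "target")
    invitro <- data.frame(protein_id = plT,
                          sequence = posPep$sequence[match(plT, st)])
    list(ratio = ratio, peptides = peptides, index = index,
         invitro = invitro,
         truth = list(
             nRatioTargets = length(dsn$complexTargets),
             nUp = length(up), nDown = length(down),
             nSharedExcluded = nShared,
             nOxidationPairs = spec$oxidationPairs,
             nPosExclusive = nrow(posPep), nNegExclusive = 1L,
             siteTargets = st, mixedProtein = st[1],
             directSubstrates = sort(plT)))
}
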