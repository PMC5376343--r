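## Orchestration of the four-step workflow: target curation, network
## building (enrichment -> selection -> rescue -> merge -> annotate ->
## explode), and subnetwork extraction with optional random-walk refinement.
## These functions are the programmatic surface behind the shipped CLI
## script (inst/scripts/signetpath.R).

#' Assemble a run configuration
#'
#' All tunable parameters of the workflow with their shipped defaults:
#' enrichment cutoff \code{alpha = 0.1}, overflow fraction
#' \code{epsilon = 0.2}, return probability \code{p0 = 0.15}, the six-level
#' distance scheme, the GO term groups, and the curation lists. Numeric
#' parameters are range-checked; referenced input files must exist.
#'
#' @param inputDir directory holding the input bundle (the layout written
#'   by [generateFixture()]: KGML files, \code{interactions.sif},
#'   \code{annotations.gaf}, \code{ontology.obo}, \code{idmapping.tsv},
#'   \code{ratio_targets.tsv}, \code{peptides.tsv},
#'   \code{peptide_index.tsv}, \code{invitro_peptides.tsv}).
#' @param outputDir directory for outputs (created on demand).
#' @param path optional YAML file whose entries override the defaults.
#' @param ... named overrides applied last (e.g. \code{alpha = 0.05}).
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(inputDir, outputDir = file.path(inputDir, "out"),
                      path = NULL, ...) {
    cfg <- list(inputDir = inputDir, outputDir = outputDir,
                alpha = 0.1, epsilon = 0.2, p0 = 0.15, tol = 1e-10,
                maxIter = 100000L, threshold = 0.1,
                rescuePolicy = "best-p", alternative = "two.sided",
                targetCategory = NULL, seed = 1L,
                scheme = distanceScheme(), goGroups = goTermGroups(),
                curation = curationDefaults())
    if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
    over <- list(...)
    if (length(over)) cfg <- utils::modifyList(cfg, over)
    if (!dir.exists(cfg$inputDir)) stop("input directory not found: ",
                                        cfg$inputDir)
    stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$epsilon >= 0,
              cfg$p0 > 0, cfg$p0 < 1, cfg$threshold > 0,
              cfg$threshold < 1)
    class(cfg) <- "runConfig"
    cfg
}

.inFile <- function(cfg, name, required = TRUE) {
    f <- file.path(cfg$inputDir, name)
    if (required && !file.exists(f)) stop("missing input file: ", f)
    f
}

.loadIdMap <- function(cfg) {
    buildIdMap(readUniprotMapping(.inFile(cfg, "idmapping.tsv")))
}

.loadPathways <- function(cfg) {
    kgml <- list.files(cfg$inputDir, pattern = "\\.xml$",
                       full.names = TRUE)
    pws <- lapply(sort(kgml), readKgml)
    sif <- file.path(cfg$inputDir, "interactions.sif")
    if (file.exists(sif)) pws <- c(pws, readExtendedSif(sif))
    if (!length(pws)) stop("no pathway files found in ", cfg$inputDir)
    pws
}

#' Curate the target sets from the proteomic tables
#'
#' Reads the SILAC ratio table, the phosphopeptide table and the peptide
#' index, applies the curation filters ([selectRatioTargets()],
#' [selectExclusivePeptides()], [mapPeptidesToProteins()],
#' [selectDirectSubstrates()]), canonicalizes ids, merges the sets and
#' writes per-dataset and merged TSVs plus the overlap report.
#'
#' @param cfg a [runConfig()].
#' @return list with the merged [TargetSet-class] (\code{merged}),
#'   per-dataset sets (\code{ratio}, \code{site}, \code{direct}) and the
#'   overlap data.frame.
#' @export
cmdTargets <- function(cfg) {
    idmap <- .loadIdMap(cfg)
    ratioTab <- readRatioTable(.inFile(cfg, "ratio_targets.tsv"))
    ratioTab$id <- canonicalize(ratioTab$id, idmap)
    ratio <- selectRatioTargets(ratioTab, cfg$threshold)
    pep <- readPeptideTable(.inFile(cfg, "peptides.tsv"))
    excl <- selectExclusivePeptides(pep)
    idx <- readPeptideIndex(.inFile(cfg, "peptide_index.tsv"))
    idx$protein_id <- canonicalize(idx$protein_id, idmap)
    site <- mapPeptidesToProteins(rbind(excl$pos, excl$neg), idx)
    direct <- NULL
    ivf <- .inFile(cfg, "invitro_peptides.tsv", required = FALSE)
    if (file.exists(ivf)) {
        iv <- readPeptideIndex(ivf)
        iv$protein_id <- canonicalize(iv$protein_id, idmap)
        direct <- selectDirectSubstrates(iv, excl$pos$sequence,
                                         cfg$curation)
    }
    sets <- Filter(Negate(is.null),
                   list(ratio = ratio, site = site, direct = direct))
    merged <- mergeTargetSets(sets)
    overlap <- targetOverlap(sets)
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(sets))
        writeTargetTable(sets[[nm]],
                         file.path(cfg$outputDir,
                                   paste0("targets_", nm, ".tsv")))
    writeTargetTable(merged, file.path(cfg$outputDir,
                                       "targets_merged.tsv"))
    write.table(overlap, file.path(cfg$outputDir, "target_overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    c(list(merged = merged, overlap = overlap), sets)
}

#' Build the annotated network from enriched pathways
#'
#' Runs enrichment of the curated targets over the pathway collection,
#' selects over-represented pathways below \code{alpha}, rescues pathways
#' covering otherwise-uncovered targets, merges the selection into one
#' annotated network, annotates GO categories, modifier flags and dataset
#' evidence, explodes group nodes, and writes GraphML/SIF plus the
#' enrichment report.
#'
#' @param cfg a [runConfig()].
#' @param targets result of [cmdTargets()] (recomputed when NULL).
#' @param sourceId origin protein id (error if no targets are given and the
#'   target list is empty).
#' @return list with the exploded [AnnotatedNetwork-class] (\code{network}),
#'   the pre-explosion network, the enrichment table, selected and rescued
#'   pathway ids, and the target coverage counts.
#' @export
cmdBuild <- function(cfg, sourceId, targets = NULL) {
    if (is.null(targets)) targets <- cmdTargets(cfg)
    tids <- unique(targetMembers(targets$merged)$id)
    if (!length(tids)) stop("no targets: the curated target list is empty")
    idmap <- .loadIdMap(cfg)
    pws <- .loadPathways(cfg)
    canonMembers <- lapply(pws, function(pw) {
        mem <- nodeTable(mergePathways(list(pw), idmap))
        mem$id[!mem$isGroup]
    })
    cpws <- lapply(seq_along(pws), function(i)
        new("Pathway", id = pws[[i]]@id, sourceDb = pws[[i]]@sourceDb,
            members = canonMembers[[i]],
            interactions = .emptyInteractions(), groups = list()))
    enr <- enrichPathways(tids, cpws, alternative = cfg$alternative)
    selected <- selectPathways(enr, cfg$alpha)
    rescued <- rescuePathways(cpws, selected, tids, enr,
                              cfg$rescuePolicy)
    chosen <- union(selected, rescued)
    net <- mergePathways(pws[vapply(pws, slot, character(1), "id") %in%
                             chosen],
                         idmap, sourceId = sourceId)
    gaf <- readGaf(.inFile(cfg, "annotations.gaf"))
    gaf$protein_id <- canonicalize(gaf$protein_id, idmap)
    obo <- readObo(.inFile(cfg, "ontology.obo"))
    net <- annotateCategories(net, gaf, obo, cfg$goGroups$categories)
    net <- annotateModifiers(net, gaf, obo, cfg$goGroups$modifier_terms)
    net <- annotateEvidence(net, targets$merged)
    preExplosion <- net
    net <- explodeGroups(net)
    covered <- intersect(tids, net@nodes$id)
    reachable <- reachableTargets(net, sourceId, covered)
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeEnrichmentReport(enr, file.path(cfg$outputDir,
                                         "enrichment.tsv"))
    writeGraphML(net, file.path(cfg$outputDir, "network.graphml"))
    writeSif(net, file.path(cfg$outputDir, "network.sif"))
    message(sprintf(
        "network: %d nodes, %d edges from %d pathways; %d/%d targets covered, %d reachable",
        nrow(net@nodes), nrow(net@edges), length(chosen),
        length(covered), length(tids), length(reachable)))
    list(network = net, preExplosion = preExplosion, enrichment = enr,
         selected = selected, rescued = rescued, covered = covered,
         reachable = reachable, targets = targets)
}

#' Extract a near-shortest subnetwork from a built network
#'
#' Assigns the evidence-based distances, optionally refines them with the
#' random walk, and extracts the near-shortest subnetwork from the source
#' to the requested targets (all reachable covered targets by default, or
#' those of a GO category when \code{cfg$targetCategory} is set). Writes
#' GraphML with overflow attributes and the per-target path report.
#'
#' @param cfg a [runConfig()].
#' @param build result of [cmdBuild()].
#' @param mode \code{"unit"} (hop count), \code{"scheme"} (base distances)
#'   or \code{"refined"} (random-walk refined distances).
#' @param targets target ids; defaults as described above.
#' @return list with the [PathSubnetwork-class] (\code{subnetwork}), the
#'   [DistanceAssignment-class] and, for refined mode, the
#'   [WalkScores-class].
#' @export
cmdExtract <- function(cfg, build, mode = c("scheme", "unit", "refined"),
                       targets = NULL) {
    mode <- match.arg(mode)
    net <- build$network
    if (is.null(targets)) {
        targets <- build$reachable
        if (!is.null(cfg$targetCategory)) {
            nd <- nodeTable(net)
            inCat <- nd$id[vapply(nd$categories, function(cc)
                cfg$targetCategory %in% cc, logical(1))]
            targets <- intersect(targets, inCat)
        }
    }
    dist <- assignDistances(net, cfg$scheme)
    scores <- NULL
    sub <- switch(mode,
        unit = unweightedSubnetwork(net, sourceNode(net), targets,
                                    cfg$epsilon),
        scheme = nearShortestSubnetwork(net, dist, sourceNode(net),
                                        targets, cfg$epsilon),
        refined = {
            scores <- scoreNodes(net, dist, sourceNode(net), cfg$p0,
                                 cfg$tol, cfg$maxIter)
            dist <- refineDistances(dist, scores)
            nearShortestSubnetwork(net, dist, sourceNode(net), targets,
                                   cfg$epsilon, use = "refined")
        })
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeGraphML(sub, file.path(cfg$outputDir,
                                paste0("subnetwork_", mode, ".graphml")))
    writePathReport(sub, file.path(cfg$outputDir,
                                   paste0("paths_", mode, ".tsv")))
    writeDistanceTable(dist, file.path(cfg$outputDir,
                                       paste0("distances_", mode,
                                              ".tsv")))
    list(subnetwork = sub, distances = dist, scores = scores,
         targets = targets)
}
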