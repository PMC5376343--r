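mkPathway <- function(id, edges, members = NULL, groups = list(),
                      type = "other", sign = "unknown", db = "TEST") {
    it <- if (nrow(edges)) data.frame(source = edges$source,
                                      target = edges$target,
                                      type = if ("type" %in% names(edges))
                                          edges$type else type,
                                      sign = if ("sign" %in% names(edges))
                                          edges$sign else sign)
          else data.frame(source = character(), target = character(),
                          type = character(), sign = character())
    new("Pathway", id = id, sourceDb = db,
        members = unique(c(members, edges$source, edges$target,
                           unlist(groups))),
        interactions = it, groups = groups)
}

test_that("sign combination is a commutative, associative join", {
    expect_equal(combineSigns(c("positive", "positive")), "positive")
    expect_equal(combineSigns(c("positive", "negative")), "unclear")
    expect_equal(combineSigns(c("unknown", "negative")), "negative")
    expect_equal(combineSigns("unknown"), "unknown")
    set.seed(2)
    vals <- c("positive", "negative", "unknown")
    for (i in 1:25) {
        s <- sample(vals, sample(1:5, 1), replace = TRUE)
        expect_equal(combineSigns(s), combineSigns(rev(s)))
        if (length(s) > 1) {
            k <- sample(length(s) - 1, 1)
            expect_equal(
                combineSigns(c(combineSigns(s[1:k]),
                               s[(k + 1):length(s)])),
                combineSigns(s))
        }
    }
})

test_that("pathway merging deduplicates edges and reconciles signs", {
    e1 <- data.frame(source = "A", target = "B", sign = "positive",
                     type = "phosphorylation")
    e2 <- data.frame(source = "A", target = "B", sign = "negative",
                     type = "regulation")
    net <- mergePathways(list(mkPathway("P1", e1), mkPathway("P2", e2)))
    ed <- edgeTable(net)
    expect_equal(nrow(ed), 1L)
    expect_equal(ed$sign, "unclear")
    expect_equal(ed$types[[1]], c("phosphorylation", "regulation"))
    expect_equal(ed$pathways[[1]], c("P1", "P2"))
    # provenance recorded on nodes too
    nd <- nodeTable(net)
    expect_equal(nd$pathways[[which(nd$id == "A")]], c("P1", "P2"))
    # disjoint pathways: node count is the sum, edge count bounded by rows
    d1 <- mkPathway("D1", data.frame(source = "X1", target = "X2"))
    d2 <- mkPathway("D2", data.frame(source = "Y1", target = "Y2"))
    net2 <- mergePathways(list(d1, d2))
    expect_equal(nrow(nodeTable(net2)), 4L)
    expect_lte(nrow(edgeTable(net2)), 2L)
})

test_that("unmappable interaction ids are kept and flagged", {
    im <- buildIdMap(data.frame(uniprot_id = "P00001",
                                namespace = "KEGG", foreign_id = "hsa:1",
                                reviewed = TRUE))
    pw <- mkPathway("P1", data.frame(source = "hsa:1",
                                     target = "hsa:999"), db = "KEGG")
    expect_warning(net <- mergePathways(list(pw), im), "unmappable")
    nd <- nodeTable(net)
    expect_true("P00001" %in% nd$id)
    expect_true(nd$unknownId[nd$id == "hsa:999"])
})

test_that("GO category annotation follows descendant closure", {
    obo <- stubObo(terms = c("GO:0007155", "GO:0008283", "GO:1111111"),
                   is_a = list("GO:1111111" = "GO:0007155"))
    gaf <- data.frame(protein_id = c("A", "B"),
                      go_id = c("GO:0007155", "GO:1111111"),
                      evidence = "IDA")
    net <- makeNet(data.frame(source = c("A", "B"),
                              target = c("B", "C")))
    groups <- list("adhesion-motility" = "GO:0007155",
                   "growth-death" = "GO:0008283")
    ann <- annotateCategories(net, gaf, obo, groups)
    nd <- nodeTable(ann)
    expect_equal(nd$categories[[which(nd$id == "A")]], "adhesion-motility")
    expect_equal(nd$categories[[which(nd$id == "B")]], "adhesion-motility")
    expect_length(nd$categories[[which(nd$id == "C")]], 0L)
    # empty GAF leaves all categories empty
    ann0 <- annotateCategories(net, emptyGaf(), obo, groups)
    expect_true(all(lengths(nodeTable(ann0)$categories) == 0L))
})

test_that("modifier flags respect GO terms and manual overrides", {
    obo <- stubObo(terms = c("GO:0004713", "GO:0004725"))
    gaf <- data.frame(protein_id = c("A", "B"),
                      go_id = "GO:0004713", evidence = "IDA")
    net <- makeNet(data.frame(source = c("A", "B", "C"),
                              target = c("B", "C", "A")))
    ann <- annotateModifiers(net, gaf, obo, manualDeny = "B",
                             manualAllow = "C")
    nd <- nodeTable(ann)
    expect_true(nd$isPtyrModifier[nd$id == "A"])
    expect_false(nd$isPtyrModifier[nd$id == "B"])  # denied despite GO term
    expect_true(nd$isPtyrModifier[nd$id == "C"])   # allowed without terms
})

test_that("group explosion expands edges and removes groups", {
    pw <- mkPathway("P1",
                    data.frame(source = c("X", "G"),
                               target = c("G", "Y")),
                    groups = list(G = c("A", "B")))
    net <- mergePathways(list(pw))
    ex <- explodeGroups(net)
    nd <- nodeTable(ex)
    expect_false(any(nd$isGroup))
    keys <- paste(edgeTable(ex)$source, edgeTable(ex)$target)
    expect_setequal(keys, c("X A", "X B", "A Y", "B Y"))
    # inherited provenance
    expect_true(all(vapply(edgeTable(ex)$pathways, identical, logical(1),
                           "P1")))
    # singleton group
    pw1 <- mkPathway("P2", data.frame(source = "G", target = "Y"),
                     groups = list(G = "A"))
    ex1 <- explodeGroups(mergePathways(list(pw1)))
    expect_setequal(paste(edgeTable(ex1)$source, edgeTable(ex1)$target),
                    "A Y")
    expect_false("G" %in% nodeTable(ex1)$id)
    # nested groups reach a fully protein-level fixpoint
    pw2 <- mkPathway("P3", data.frame(source = "X", target = "G1"),
                     groups = list(G1 = c("A", "G2"),
                                   G2 = c("B", "C")))
    ex2 <- explodeGroups(mergePathways(list(pw2)))
    keys2 <- paste(edgeTable(ex2)$source, edgeTable(ex2)$target)
    expect_true(all(c("X A", "X B", "X C") %in% keys2))
    expect_false(any(nodeTable(ex2)$isGroup))
})

test_that("explosion preserves protein-level reachability", {
    set.seed(9)
    for (i in 1:10) {
        prot <- sprintf("p%d", 1:8)
        edges <- data.frame(
            source = sample(c(prot, "G"), 12, replace = TRUE),
            target = sample(c(prot, "G"), 12, replace = TRUE))
        edges <- edges[edges$source != edges$target, , drop = FALSE]
        edges <- edges[!duplicated(edges), , drop = FALSE]
        mem <- sample(prot, 3)
        pw <- mkPathway("P", edges, members = prot,
                        groups = list(G = mem))
        net <- mergePathways(list(pw))
        ex <- explodeGroups(net)
        # oracle: naive substitution of the group endpoint by its members
        sub <- function(v) lapply(v, function(x) if (x == "G") mem else x)
        s <- sub(edges$source); t <- sub(edges$target)
        oracle <- do.call(rbind, lapply(seq_along(s), function(j)
            expand.grid(source = s[[j]], target = t[[j]],
                        stringsAsFactors = FALSE)))
        g0 <- igraph::graph_from_data_frame(
            unique(oracle), directed = TRUE,
            vertices = data.frame(name = prot))
        reach0 <- igraph::subcomponent(g0, "p1", mode = "out")$name
        gx <- asIgraph(ex)
        reachx <- igraph::subcomponent(gx, "p1", mode = "out")$name
        expect_setequal(reachx, reach0)
    }
})

test_that("reachable targets follow edge direction", {
    net <- makeNet(data.frame(source = c("S", "A", "U"),
                              target = c("A", "T", "S")),
                   source = "S")
    expect_equal(reachableTargets(net, "S", c("T", "U")), "T")
    expect_error(reachableTargets(net, "nope", "T"), "absent")
    # random DAG against a BFS oracle
    set.seed(21)
    for (i in 1:5) {
        edges <- randomDigraph(20, 0.12, seed = 100 + i)
        if (!nrow(edges)) next
        net <- makeNet(edges, source = edges$source[1])
        src <- edges$source[1]
        d <- bfDistances(transform(edges, weight = 1), src)
        oracle <- names(d)[is.finite(unlist(d))]
        got <- reachableTargets(net, src, nodeTable(net)$id)
        expect_setequal(got, intersect(oracle, nodeTable(net)$id))
    }
})

test_that("target interaction census splits by dataset of origin", {
    edges <- data.frame(
        source = c("a1", "a2", "b1", "a1", "sh", "x"),
        target = c("a2", "b1", "b2", "b2", "a1", "y"))
    net <- makeNet(edges)
    counts <- targetInteractionCensus(
        net, list(MCF7 = c("a1", "a2", "sh"),
                  MDA231 = c("b1", "b2", "sh")))
    expect_equal(unname(counts["both_first"]), 1L)     # a1 -> a2
    expect_equal(unname(counts["both_second"]), 1L)    # b1 -> b2
    expect_equal(unname(counts["involving_shared"]), 1L)  # sh -> a1
    expect_equal(unname(counts["cross_dataset"]), 2L)  # a2->b1, a1->b2
    expect_equal(unname(counts["total"]), 5L)
    zero <- targetInteractionCensus(net, list(A = "zz", B = "ww"))
    expect_equal(unname(zero["total"]), 0L)
})
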