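daFor <- function(edges) new("DistanceAssignment",
    table = data.frame(source = edges$source, target = edges$target,
                       base = edges$weight, refined = NA_real_),
    scheme = list())

test_that("dijkstra distances match a Bellman-Ford oracle", {
    edges <- data.frame(source = c("S", "A"), target = c("A", "B"),
                        weight = c(5, 5))
    net <- makeNet(edges, source = "S")
    d <- dijkstraDistances(net, netWeights(net, edges), "S")
    expect_equal(unname(d["S"]), 0)
    expect_equal(unname(d["B"]), 10)
    net2 <- makeNet(edges, source = "S", extraNodes = "far")
    d2 <- dijkstraDistances(net2, netWeights(net2, edges), "S")
    expect_equal(unname(d2["far"]), Inf)
    expect_error(dijkstraDistances(net, netWeights(net, edges), "zz"),
                 "absent")
    # reverse mode plus random graphs
    for (i in 1:8) {
        eg <- randomDigraph(10, 0.3, seed = 500 + i)
        if (!nrow(eg)) next
        net <- makeNet(eg)
        w <- netWeights(net, eg)
        src <- eg$source[1]
        fwd <- dijkstraDistances(net, w, src)
        bf <- bfDistances(eg, src)
        expect_equal(unname(fwd[names(bf)]), unname(unlist(bf)))
        rev <- dijkstraDistances(net, w, src, reverse = TRUE)
        bfR <- bfDistances(eg, src, reverse = TRUE)
        expect_equal(unname(rev[names(bfR)]), unname(unlist(bfR)))
    }
})

test_that("shortest subnetwork keeps ties and drops longer routes", {
    # two equal alternatives are both retained
    eq <- data.frame(source = c("S", "A", "S", "B"),
                     target = c("A", "T", "B", "T"),
                     weight = c(2, 2, 2, 2))
    net <- makeNet(eq, source = "S")
    sub <- shortestSubnetwork(net, netWeights(net, eq), "S", "T")
    expect_equal(nrow(edgeTable(sub)), 4L)
    expect_true(all(edgeTable(sub)$overflow == 0))
    expect_true(all(nodeTable(sub)$overflow == 0))
    # a strictly longer alternative is excluded
    lng <- data.frame(source = c("S", "A", "S", "B"),
                      target = c("A", "T", "B", "T"),
                      weight = c(2, 2, 2, 3))
    net2 <- makeNet(lng, source = "S")
    sub2 <- shortestSubnetwork(net2, netWeights(net2, lng), "S", "T")
    keys <- paste(edgeTable(sub2)$source, edgeTable(sub2)$target)
    expect_setequal(keys, c("S A", "A T"))
    # asymmetric diamond against exhaustive simple-path enumeration
    dia <- data.frame(source = c("S", "S", "A", "B", "A"),
                      target = c("A", "B", "T", "T", "B"),
                      weight = c(1, 4, 6, 2, 1))
    net3 <- makeNet(dia, source = "S")
    sub3 <- shortestSubnetwork(net3, netWeights(net3, dia), "S", "T")
    paths <- simplePaths(dia, "S", "T")
    best <- min(vapply(paths, `[[`, numeric(1), "len"))
    onBest <- unique(unlist(lapply(paths, function(p)
        if (p$len == best) paste(head(p$nodes, -1), p$nodes[-1]))))
    expect_setequal(paste(edgeTable(sub3)$source, edgeTable(sub3)$target),
                    onBest)
})

test_that("near-shortest retention follows the acceptance inequality", {
    # shortest 10; detour of 12 accepted at 20%, 12.5 rejected
    edges <- data.frame(source = c("S", "A", "S", "B"),
                        target = c("A", "T", "B", "T"),
                        weight = c(5, 5, 6, 6))
    net <- makeNet(edges, source = "S")
    sub <- nearShortestSubnetwork(net, netWeights(net, edges), "S", "T",
                                  epsilon = 0.2)
    ed <- edgeTable(sub)
    expect_equal(ed$overflow[ed$source == "S" & ed$target == "B"], 2)
    expect_equal(ed$overflow[ed$source == "S" & ed$target == "A"], 0)
    edges$weight[3] <- 6.5
    net2 <- makeNet(edges, source = "S")
    sub2 <- nearShortestSubnetwork(net2, netWeights(net2, edges), "S",
                                   "T", epsilon = 0.2)
    expect_false("B" %in% nodeTable(sub2)$id)
    # epsilon = 0 degenerates to the shortest subnetwork
    sub0 <- nearShortestSubnetwork(net, netWeights(net, edges), "S", "T",
                                   epsilon = 0)
    subS <- shortestSubnetwork(net, netWeights(net, edges), "S", "T")
    expect_equal(edgeTable(sub0), edgeTable(subS))
})

test_that("the composite subnetwork may contain over-long walks", {
    # (A,B,C) shortest; (A,I,B,C) and (A,B,J,C) acceptable: all their
    # elements are retained even though (A,I,B,J,C) would be too long
    edges <- data.frame(source = c("A", "B", "A", "I", "B", "J"),
                        target = c("B", "C", "I", "B", "J", "C"),
                        weight = c(1, 1, 0.7, 0.8, 0.7, 0.8))
    net <- makeNet(edges, source = "A")
    sub <- nearShortestSubnetwork(net, netWeights(net, edges), "A", "C",
                                  epsilon = 0.5)
    expect_setequal(nodeTable(sub)$id, c("A", "B", "C", "I", "J"))
    expect_equal(nrow(edgeTable(sub)), 6L)
    ed <- edgeTable(sub)
    expect_equal(ed$overflow[ed$source == "A" & ed$target == "I"], 0.5)
    expect_equal(ed$overflow[ed$source == "B" & ed$target == "J"], 0.5)
})

test_that("retention uses walk semantics on cyclic graphs", {
    # the only way through u -> v returns via x, so no simple path uses it,
    # yet an acceptable walk does; the backtracking construction keeps it
    edges <- data.frame(source = c("S", "x", "u", "v", "x"),
                        target = c("x", "u", "v", "x", "t"),
                        weight = c(1, 1, 1, 1, 6))
    net <- makeNet(edges, source = "S")
    sub <- nearShortestSubnetwork(net, netWeights(net, edges), "S", "t",
                                  epsilon = 0.5)   # bound 10.5, walk 10
    ed <- edgeTable(sub)
    expect_true(any(ed$source == "u" & ed$target == "v"))
    expect_equal(ed$overflow[ed$source == "u" & ed$target == "v"], 3)
    expect_length(simplePaths(edges, "S", "t", maxLen = 10.5) |>
                      Filter(f = function(p) "u" %in% p$nodes), 0L)
})

test_that("subnetworks grow monotonically with epsilon", {
    set.seed(31)
    for (i in 1:10) {
        eg <- randomDigraph(9, 0.3, seed = 600 + i)
        if (nrow(eg) < 3) next
        net <- makeNet(eg)
        w <- netWeights(net, eg)
        src <- eg$source[1]
        tgt <- setdiff(unique(eg$target), src)
        tgt <- tgt[seq_len(min(2, length(tgt)))]
        prev <- NULL
        for (eps in c(0, 0.1, 0.3, 0.6)) {
            sub <- suppressWarnings(
                nearShortestSubnetwork(net, w, src, tgt, eps))
            keys <- paste(edgeTable(sub)$source, edgeTable(sub)$target)
            if (!is.null(prev)) expect_true(all(prev %in% keys))
            prev <- keys
        }
    }
})

test_that("unweighted extraction counts hops", {
    edges <- data.frame(source = c("S", "A", "S", "B", "C"),
                        target = c("A", "T", "B", "C", "T"),
                        weight = 1)
    net <- makeNet(edges, source = "S")
    sub0 <- unweightedSubnetwork(net, "S", "T", epsilon = 0)
    expect_setequal(paste(edgeTable(sub0)$source, edgeTable(sub0)$target),
                    c("S A", "A T"))
    sub5 <- unweightedSubnetwork(net, "S", "T", epsilon = 0.5)
    expect_setequal(nodeTable(sub5)$id, c("S", "A", "B", "C", "T"))
    one <- makeNet(data.frame(source = "S", target = "T", weight = 1),
                   source = "S")
    subOne <- unweightedSubnetwork(one, "S", "T")
    expect_equal(nrow(edgeTable(subOne)), 1L)
})

test_that("unreachable targets give an empty subnetwork with a warning", {
    edges <- data.frame(source = "A", target = "S", weight = 1)
    net <- makeNet(edges, source = "S")
    expect_warning(
        sub <- nearShortestSubnetwork(net, netWeights(net, edges), "S",
                                      "A", 0.2),
        "reachable")
    expect_equal(nrow(edgeTable(sub)), 0L)
    expect_equal(nrow(nodeTable(sub)), 0L)
})

test_that("the per-target report records each target's own overflow", {
    edges <- data.frame(source = c("S", "A", "A"),
                        target = c("A", "T1", "T2"),
                        weight = c(1, 1, 2))
    net <- makeNet(edges, source = "S")
    sub <- nearShortestSubnetwork(net, netWeights(net, edges), "S",
                                  c("T1", "T2"), 0.2)
    rep <- pathReport(sub)
    expect_setequal(unique(rep$target), c("T1", "T2"))
    expect_true(all(rep$overflow == 0))
})
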