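# Independent oracles used across the suite: Bellman-Ford shortest
# distances, exhaustive enumeration of acceptable walks / simple paths,
# dense stationary solves, and hypergeometric tail enumeration. These stay
# deliberately naive and separate from the package's own algorithms.

# Bellman-Ford over an edge data.frame (source, target, weight)
bfDistances <- function(edges, origin, reverse = FALSE) {
    if (reverse && nrow(edges))
        edges <- data.frame(source = edges$target, target = edges$source,
                            weight = edges$weight)
    nodes <- unique(c(edges$source, edges$target, origin))
    d <- setNames(rep(Inf, length(nodes)), nodes)
    d[origin] <- 0
    for (pass in seq_len(length(nodes) + 1L)) {
        changed <- FALSE
        for (j in seq_len(nrow(edges))) {
            nd <- d[[edges$source[j]]] + edges$weight[j]
            if (nd < d[[edges$target[j]]] - 1e-12) {
                d[[edges$target[j]]] <- nd
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    d
}

# Exhaustive enumeration of every walk source -> target with total length
# <= bound (weights are positive so the enumeration is finite; pruning by
# remaining distance only discards walks that provably cannot finish within
# the bound). Returns minimal acceptable walk length per edge ("u|v") and
# per node.
walkEnumeration <- function(edges, source, target, bound, tol = 1e-9) {
    toT <- bfDistances(edges, target, reverse = TRUE)
    out <- split(seq_len(nrow(edges)), edges$source)
    bestEdge <- new.env(parent = emptyenv())
    bestNode <- new.env(parent = emptyenv())
    note <- function(env, key, len) {
        cur <- env[[key]]
        if (is.null(cur) || len < cur) env[[key]] <- len
    }
    rec <- function(node, len, pathEdges, pathNodes) {
        if (node == target) {
            for (e in pathEdges) note(bestEdge, e, len)
            for (v in pathNodes) note(bestNode, v, len)
        }
        for (i in out[[node]]) {
            v <- edges$target[i]
            L <- len + edges$weight[i]
            if (!is.null(toT[[v]]) && is.finite(toT[[v]]) &&
                L + toT[[v]] <= bound + tol)
                rec(v, L, c(pathEdges, paste(node, v, sep = "|")),
                    c(pathNodes, v))
        }
    }
    if (!is.null(toT[[source]]) && is.finite(toT[[source]]) &&
        toT[[source]] <= bound + tol)
        rec(source, 0, character(), source)
    list(edges = as.list(bestEdge), nodes = as.list(bestNode))
}

# Exhaustive enumeration of simple paths source -> target; returns a list
# of list(nodes=, len=)
simplePaths <- function(edges, source, target, maxLen = Inf) {
    out <- split(seq_len(nrow(edges)), edges$source)
    acc <- list()
    rec <- function(node, len, visited) {
        if (node == target) {
            acc[[length(acc) + 1L]] <<- list(nodes = visited, len = len)
            return()
        }
        for (i in out[[node]]) {
            v <- edges$target[i]
            L <- len + edges$weight[i]
            if (!v %in% visited && L <= maxLen + 1e-9)
                rec(v, L, c(visited, v))
        }
    }
    rec(source, 0, source)
    acc
}

# Dense stationary distribution: solve pi (P - I) = 0 with sum(pi) = 1
denseStationary <- function(P) {
    P <- as.matrix(P)
    n <- nrow(P)
    A <- t(P) - diag(n)
    A[n, ] <- 1
    solve(A, c(rep(0, n - 1L), 1))
}

# Two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins, summing point probabilities <= observed (with the same
# 1e-7 relative slack convention as the two-sided exact test)
enumFisherP <- function(k, m, n, N) {
    ks <- max(0L, m + n - N):min(m, n)
    logp <- lchoose(m, ks) + lchoose(N - m, n - ks) - lchoose(N, n)
    p <- exp(logp)
    pk <- p[ks == k]
    sum(p[p <= pk * (1 + 1e-7)])
}

# Random directed graph as an edge data.frame
randomDigraph <- function(n, p, seed, wchoices = c(1, 2, 3, 5, 6, 8)) {
    set.seed(seed)
    pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
    pairs <- pairs[pairs$s != pairs$t, ]
    sel <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    data.frame(source = sprintf("n%02d", sel$s),
               target = sprintf("n%02d", sel$t),
               weight = sample(wchoices, nrow(sel), replace = TRUE))
}

# Build an AnnotatedNetwork from an edge data.frame through the public API
makeNet <- function(edges, source = character(),
                    extraNodes = character()) {
    mem <- unique(c(edges$source, edges$target, extraNodes, source))
    pw <- new("Pathway", id = "pw1", sourceDb = "TEST", members = mem,
              interactions = data.frame(source = edges$source,
                                        target = edges$target,
                                        type = "other", sign = "unknown"),
              groups = list())
    mergePathways(list(pw), sourceId = source)
}

# Weight vector aligned with a network's edge-table order
netWeights <- function(net, edges) {
    ed <- edgeTable(net)
    edges$weight[match(paste(ed$source, ed$target),
                       paste(edges$source, edges$target))]
}

# Minimal TargetSet construction for annotation tests
tsFor <- function(ids, tag = "site-level", direction = "up") {
    new("TargetSet",
        members = if (length(ids)) data.frame(id = ids, tag = tag,
                                              direction = direction)
                  else data.frame(id = character(), tag = character(),
                                  direction = character()),
        peptideRecords = data.frame())
}

# Empty GAF / stub ontology helpers
emptyGaf <- function() data.frame(protein_id = character(),
                                  go_id = character(),
                                  evidence = character())
stubObo <- function(terms = c("GO:0004713", "GO:0004725"),
                    is_a = list(), part_of = list())
    list(terms = terms, is_a = is_a, part_of = part_of)

# Flag modifiers on a network without touching GO machinery
setModifiers <- function(net, ids) {
    annotateModifiers(net, emptyGaf(), stubObo(), manualAllow = ids)
}

# Compare a PathSubnetwork against the walk-enumeration oracle
expectMatchesOracle <- function(sub, edges, source, targets, eps) {
    dS <- bfDistances(edges, source)
    reach <- targets[vapply(targets, function(t)
        !is.null(dS[[t]]) && is.finite(dS[[t]]), logical(1))]
    edgeBest <- list(); nodeBest <- list()
    for (t in reach) {
        bound <- (1 + eps) * dS[[t]]
        enum <- walkEnumeration(edges, source, t, bound)
        for (e in names(enum$edges)) {
            ov <- enum$edges[[e]] - dS[[t]]
            edgeBest[[e]] <- min(edgeBest[[e]] %||% Inf, ov)
        }
        for (v in names(enum$nodes)) {
            ov <- enum$nodes[[v]] - dS[[t]]
            nodeBest[[v]] <- min(nodeBest[[v]] %||% Inf, ov)
        }
    }
    got <- edgeTable(sub)
    gotKeys <- paste(got$source, got$target, sep = "|")
    expect_setequal(gotKeys, as.character(names(edgeBest)))
    nd <- nodeTable(sub)
    expect_setequal(nd$id, as.character(names(nodeBest)))
    if (length(gotKeys)) {
        ord <- match(gotKeys, names(edgeBest))
        expect_equal(got$overflow, pmax(unlist(edgeBest)[ord], 0),
                     tolerance = 1e-8, ignore_attr = TRUE)
        expect_equal(
            nd$overflow,
            pmax(unlist(nodeBest)[match(nd$id, names(nodeBest))], 0),
            tolerance = 1e-8, ignore_attr = TRUE)
    }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
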