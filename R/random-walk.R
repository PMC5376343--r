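## Random walk with return probability to the source: transition model,
## stationary distribution, and the weighted / topology-only score pair.

.edgeWeightVector <- function(assignment, use = c("base", "refined")) {
    use <- match.arg(use)
    tb <- assignment@table
    w <- if (use == "refined") tb$refined else tb$base
    if (use == "refined" && any(is.na(w)))
        stop("refined distances not yet computed; run scoreNodes/",
             "refineDistances first")
    setNames(w, paste(tb$source, tb$target, sep = "\r"))
}

#' Build the random-walk transition model
#'
#' Transition probabilities derive from edge distances (a higher distance is
#' a lower weight): for a node i with successors,
#' \code{p(i,j) = (1 - p0) * (1/d(i,j)) / sum_k(1/d(i,k))}, and every node
#' carries an explicit return entry of probability \code{p0} to the origin;
#' terminal nodes return to the origin with probability 1. The model is
#' restricted to the origin-reachable component, where the return edges make
#' the chain ergodic.
#'
#' @param net an exploded [AnnotatedNetwork-class].
#' @param distances a [DistanceAssignment-class].
#' @param source origin node id.
#' @param p0 return probability, strictly in (0, 1); default 0.15.
#' @param equalWeights ignore distances and use the topology only
#'   (all distances 1).
#' @param use which distance column to use (\code{"base"} default).
#' @return a [WalkModel-class].
#' @export
buildWalk <- function(net, distances, source, p0 = 0.15,
                      equalWeights = FALSE, use = "base") {
    if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
    if (!source %in% net@nodes$id) stop("source node absent: ", source)
    g <- asIgraph(net)
    comp <- sort(igraph::subcomponent(g, source, mode = "out")$name)
    nodeOrder <- c(source, setdiff(comp, source))
    n <- length(nodeOrder)
    idx <- setNames(seq_len(n), nodeOrder)
    ed <- net@edges
    keep <- ed$source %in% nodeOrder   # successors of reachable nodes are reachable
    ed <- ed[keep, , drop = FALSE]
    w <- if (equalWeights) rep(1, nrow(ed))
         else unname(.edgeWeightVector(distances, use)[
             paste(ed$source, ed$target, sep = "\r")])
    if (any(is.na(w))) stop("missing distance for a network edge")
    if (any(w <= 0)) stop("non-positive edge distance")
    iRow <- idx[ed$source]; jCol <- idx[ed$target]
    inv <- 1 / w
    denom <- tapply(inv, iRow, sum)
    p <- (1 - p0) * inv / denom[as.character(iRow)]
    hasSucc <- as.integer(names(denom))
    ret <- ifelse(seq_len(n) %in% hasSucc, p0, 1)
    P <- Matrix::sparseMatrix(
        i = c(iRow, seq_len(n)), j = c(jCol, rep(idx[source], n)),
        x = c(p, ret), dims = c(n, n))
    new("WalkModel", P = methods::as(P, "CsparseMatrix"), p0 = p0,
        nodeOrder = nodeOrder)
}

#' Stationary distribution of a walk model
#'
#' Solves \code{pi P = pi} by power iteration, returning the normalized
#' stationary row vector. With the return edges the chain is ergodic on the
#' reachable component, so the distribution exists, is unique and strictly
#' positive there.
#'
#' @param model a [WalkModel-class].
#' @param tol convergence tolerance on the L1 residual
#'   \code{||pi P - pi||_1} (default 1e-10).
#' @param maxIter iteration cap (default 1e5); non-convergence is an error
#'   reporting the residual.
#' @return named numeric vector summing to 1.
#' @export
stationaryDistribution <- function(model, tol = 1e-10, maxIter = 100000L) {
    P <- model@P
    n <- nrow(P)
    x <- rep(1 / n, n)
    for (it in seq_len(maxIter)) {
        xn <- as.numeric(x %*% P)
        xn <- xn / sum(xn)
        res <- sum(abs(xn - x))
        x <- xn
        if (res <= tol) return(setNames(x, model@nodeOrder))
    }
    stop(sprintf(
        "power iteration did not converge in %d iterations (residual %.3g)",
        maxIter, res))
}

#' Score nodes by the weighted and topology-only stationary distributions
#'
#' Runs the walk twice on a shared node order: once with the assigned
#' distances (scores \code{pi}) and once with all edges at equal weight
#' (the topology baseline \code{pi0} that eliminates topological bias when
#' forming the ratio \code{pi/pi0}).
#'
#' @inheritParams buildWalk
#' @param tol,maxIter passed to [stationaryDistribution()].
#' @return a [WalkScores-class].
#' @export
scoreNodes <- function(net, distances, source, p0 = 0.15, tol = 1e-10,
                       maxIter = 100000L, use = "base") {
    mw <- buildWalk(net, distances, source, p0, equalWeights = FALSE,
                    use = use)
    m0 <- buildWalk(net, distances, source, p0, equalWeights = TRUE,
                    use = use)
    pi1 <- stationaryDistribution(mw, tol, maxIter)
    pi0 <- stationaryDistribution(m0, tol, maxIter)
    new("WalkScores", pi = pi1, pi0 = pi0[names(pi1)])
}

#' Refine a network's edge distances via the random walk
#'
#' Convenience wrapper: [scoreNodes()] followed by [refineDistances()].
#'
#' @inheritParams scoreNodes
#' @param distances a [DistanceAssignment-class] with base distances.
#' @return the refined [DistanceAssignment-class].
#' @export
refineNetworkDistances <- function(net, distances, source, p0 = 0.15,
                                   tol = 1e-10, maxIter = 100000L) {
    refineDistances(distances,
                    scoreNodes(net, distances, source, p0, tol, maxIter))
}

#' Simulate walk trajectories (cross-validation helper)
#'
#' A seeded trajectory sampler provided only to cross-check the algebraic
#' stationary distribution; it is never used to compute scores.
#'
#' @param model a [WalkModel-class].
#' @param steps number of steps to simulate.
#' @param burnin steps discarded before counting visits.
#' @param seed RNG seed.
#' @return named numeric vector of visit frequencies.
#' @export
simulateWalk <- function(model, steps = 100000L, burnin = 1000L,
                         seed = 1L) {
    set.seed(seed)
    P <- as.matrix(model@P)
    n <- nrow(P)
    visits <- numeric(n)
    state <- 1L
    for (s in seq_len(steps + burnin)) {
        state <- sample.int(n, 1L, prob = P[state, ])
        if (s > burnin) visits[state] <- visits[state] + 1
    }
    setNames(visits / sum(visits), model@nodeOrder)
}
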