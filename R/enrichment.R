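## Pathway over-representation: Fisher exact test, p-value selection,
## underrepresentation removal, and coverage rescue.

#' Fisher exact enrichment of one pathway in a target list
#'
#' Builds the 2x2 table (in-pathway / out-of-pathway vs target / non-target)
#' over a background set and computes the Fisher exact p-value. A pathway is
#' over-represented when its in-pathway target fraction is at least the
#' background fraction: \code{k/m >= n/N}.
#'
#' @param targets character vector of target ids (restricted to background).
#' @param pathway a [Pathway-class] object, or a character vector of members.
#' @param background character vector of background ids (nonempty; must
#'   contain the targets).
#' @param alternative sidedness of the test: \code{"two.sided"} (default,
#'   followed by the ratio-based over-representation filter) or
#'   \code{"greater"}.
#' @return one-row data.frame with columns \code{pathway_id}, \code{k},
#'   \code{m}, \code{n}, \code{N}, \code{p_value}, \code{overrepresented}.
#' @importFrom stats fisher.test p.adjust
#' @export
fisherEnrichment <- function(targets, pathway, background,
                             alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    if (!length(background)) stop("empty background set")
    pid <- if (is(pathway, "Pathway")) pathway@id else NA_character_
    mem <- if (is(pathway, "Pathway")) pathway@members else pathway
    background <- unique(background)
    targets <- intersect(unique(targets), background)
    mem <- intersect(unique(mem), background)
    k <- length(intersect(mem, targets))
    m <- length(mem); n <- length(targets); N <- length(background)
    p <- fisher.test(matrix(c(k, m - k, n - k, N - m - n + k), nrow = 2),
                     alternative = alternative)$p.value
    data.frame(pathway_id = pid, k = k, m = m, n = n, N = N,
               p_value = min(p, 1), # guard fp overshoot
               overrepresented = m > 0 && k / m >= n / N)
}

#' Enrichment of a pathway collection
#'
#' Applies [fisherEnrichment()] to every pathway containing at least one
#' target, against a common background. A Benjamini-Hochberg adjusted column
#' is reported for transparency but plays no role in selection (selection
#' uses the raw p-value).
#'
#' @param targets character vector of target ids.
#' @param pathways list of [Pathway-class] objects.
#' @param background background id set; by default the union of all pathway
#'   members of the collection.
#' @param alternative see [fisherEnrichment()].
#' @return data.frame, one row per tested pathway, with an extra \code{padj}
#'   column.
#' @export
enrichPathways <- function(targets, pathways,
                           background = unique(unlist(lapply(pathways,
                                                             slot, "members"))),
                           alternative = "two.sided") {
    res <- do.call(rbind, lapply(pathways, function(pw) {
        if (!length(intersect(pw@members, targets))) return(NULL)
        fisherEnrichment(targets, pw, background, alternative)
    }))
    if (is.null(res))
        res <- fisherEnrichment(targets, character(), background)[0, ]
    res$padj <- p.adjust(res$p_value, method = "BH")
    res[order(res$p_value, res$pathway_id), , drop = FALSE]
}

#' Select over-represented pathways below a p-value cutoff
#'
#' Keeps pathways with \code{overrepresented = TRUE} and raw
#' \code{p_value < alpha} (strict); under-represented pathways are removed
#' regardless of their p-value. Monotone in \code{alpha}.
#'
#' @param results data.frame from [enrichPathways()].
#' @param alpha p-value cutoff (default 0.1).
#' @return character vector of selected pathway ids.
#' @export
selectPathways <- function(results, alpha = 0.1) {
    if (!nrow(results)) return(character())
    sort(results$pathway_id[results$overrepresented &
                            results$p_value < alpha])
}

#' Rescue pathways covering otherwise-uncovered targets
#'
#' For each target that belongs to at least one pathway of the database but
#' to no selected pathway, adds a containing pathway so that after
#' selection-plus-rescue every target present in the database is covered.
#'
#' @param pathways list of all [Pathway-class] objects of one database.
#' @param selected character vector of already-selected pathway ids.
#' @param targets character vector of target ids.
#' @param results enrichment data.frame (needed for the best-p policy).
#' @param policy \code{"best-p"} (default): per uncovered target, the
#'   containing pathway with the smallest p-value, ties broken by smallest
#'   pathway then lexicographic id; or \code{"all-containing"}.
#' @return character vector of rescued pathway ids, disjoint from
#'   \code{selected}.
#' @export
rescuePathways <- function(pathways, selected, targets, results = NULL,
                           policy = c("best-p", "all-containing")) {
    policy <- match.arg(policy)
    ids <- vapply(pathways, slot, character(1), "id")
    stopifnot(all(selected %in% ids))
    memberOf <- lapply(pathways, slot, "members")
    names(memberOf) <- ids
    covered <- unique(unlist(memberOf[selected]))
    rescued <- character()
    for (t in setdiff(targets, covered)) {
        containing <- ids[vapply(memberOf, function(v) t %in% v, logical(1))]
        containing <- setdiff(containing, selected)
        if (!length(containing)) next
        if (policy == "all-containing") {
            rescued <- union(rescued, containing)
        } else {
            pv <- if (!is.null(results))
                setNames(results$p_value, results$pathway_id)[containing]
            else setNames(rep(1, length(containing)), containing)
            pv[is.na(pv)] <- 1
            sz <- lengths(memberOf[containing])
            ord <- order(pv, sz, containing)
            rescued <- union(rescued, containing[ord[1L]])
        }
    }
    sort(setdiff(rescued, selected))
}

#' Write an enrichment report
#'
#' @param results data.frame from [enrichPathways()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @importFrom utils write.table
#' @export
writeEnrichmentReport <- function(results, path) {
    write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
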