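test_that("ratio filtering keeps a 10% variation, boundary included", {
    tab <- data.frame(id = c("A", "B", "C"),
                      silac_ratio = c(1.25, 1.02, 0.80))
    m <- targetMembers(selectRatioTargets(tab, 0.1))
    expect_equal(m$id, c("A", "C"))
    expect_equal(m$direction, c("up", "down"))
    expect_equal(unique(m$tag), "complex-level")

    bnd <- targetMembers(selectRatioTargets(
        data.frame(id = c("A", "B"), silac_ratio = c(1.10, 0.90)), 0.1))
    expect_setequal(bnd$id, c("A", "B"))

    expect_equal(nrow(targetMembers(selectRatioTargets(
        data.frame(id = character(), silac_ratio = numeric())))), 0L)

    expect_warning(
        out <- selectRatioTargets(data.frame(id = c("A", "B"),
                                             silac_ratio = c(-1, 1.5))),
        "non-positive")
    expect_equal(targetMembers(out)$id, "B")
})

test_that("a vanishing threshold retains every protein with ratio != 1", {
    set.seed(42)
    tab <- data.frame(id = sprintf("p%02d", 1:30),
                      silac_ratio = c(rep(1, 5), runif(25, 0.5, 2)))
    m <- targetMembers(selectRatioTargets(tab, 1e-9))
    expect_setequal(m$id, tab$id[abs(tab$silac_ratio - 1) >= 1e-9])
})

test_that("condition-exclusive peptide selection collapses oxidation", {
    pep <- data.frame(
        sequence = c("AAA", "BBB"), phosphosite = c("Y10", "Y20"),
        oxidation_state = "none", condition = c("pos", "neg"))
    out <- selectExclusivePeptides(pep)
    expect_equal(out$pos$sequence, "AAA")
    expect_equal(out$neg$sequence, "BBB")
    expect_equal(nrow(out$excluded_shared), 0L)

    ox <- data.frame(sequence = "AAA", phosphosite = "Y10",
                     oxidation_state = c("none", "ox"),
                     condition = c("pos", "neg"))
    out <- selectExclusivePeptides(ox)
    expect_equal(nrow(out$pos), 0L)
    expect_equal(nrow(out$neg), 0L)
    expect_equal(nrow(out$excluded_shared), 1L)

    dup <- data.frame(sequence = "AAA", phosphosite = "Y10",
                      oxidation_state = "none",
                      condition = c("pos", "pos"))
    out <- selectExclusivePeptides(dup)
    expect_equal(nrow(out$pos), 1L)
})

test_that("exclusive partition invariants hold on random tables", {
    set.seed(7)
    for (i in 1:10) {
        pep <- data.frame(
            sequence = sample(c("AA", "BB", "CC", "DD"), 20,
                              replace = TRUE),
            phosphosite = sample(c("Y1", "Y2"), 20, replace = TRUE),
            oxidation_state = sample(c("none", "ox"), 20,
                                     replace = TRUE),
            condition = sample(c("pos", "neg"), 20, replace = TRUE))
        out <- selectExclusivePeptides(pep)
        key <- function(d) paste(d$sequence, d$phosphosite)
        expect_length(intersect(key(out$pos), key(out$neg)), 0L)
        expect_length(intersect(c(key(out$pos), key(out$neg)),
                                key(out$excluded_shared)), 0L)
    }
})

test_that("malformed phosphosites are rejected with a warning", {
    pep <- data.frame(sequence = c("AAA", "BBB"),
                      phosphosite = c("Y10", "bad!"),
                      oxidation_state = "none", condition = "pos")
    expect_warning(out <- selectExclusivePeptides(pep), "malformed")
    expect_equal(out$pos$sequence, "AAA")
})

test_that("peptide-to-protein mapping includes ambiguous matches", {
    idx <- data.frame(sequence = c("AAA", "AAA", "BBB", "CCC"),
                      protein_id = c("P1", "P2", "P3", "P3"))
    pep <- data.frame(sequence = c("AAA", "BBB", "CCC"),
                      phosphosite = c("Y1", "Y2", "Y3"),
                      condition = c("pos", "pos", "neg"))
    ts <- mapPeptidesToProteins(pep, idx)
    m <- targetMembers(ts)
    expect_setequal(m$id, c("P1", "P2", "P3"))
    expect_equal(m$direction[m$id == "P1"], "up")
    expect_equal(m$direction[m$id == "P3"], "mixed")
    expect_equal(unique(m$tag), "site-level")
    expect_equal(nrow(targetMembers(mapPeptidesToProteins(pep[0, ], idx))),
                 0L)
    expect_warning(
        mapPeptidesToProteins(
            data.frame(sequence = "ZZZ", phosphosite = "Y9",
                       condition = "pos"), idx),
        "orphan")
})

test_that("direct-substrate selection honours curation lists", {
    iv <- data.frame(protein_id = c("A", "B", "M", "M", "X"),
                     sequence = c("p1", "p2", "p3", "p4", "p5"))
    cellular <- c("p1", "p4")
    # plain matching: A in, B out
    m <- targetMembers(selectDirectSubstrates(iv, cellular))
    expect_setequal(m$id, c("A", "M"))
    # per-peptide exclusion of p4 removes M's only match
    cur <- list(exclude_peptides = data.frame(protein_id = "M",
                                              sequence = "p4"))
    m <- targetMembers(selectDirectSubstrates(iv, cellular, cur))
    expect_setequal(m$id, "A")
    # ...but M survives if another peptide matches (MAP1B-style)
    m <- targetMembers(selectDirectSubstrates(iv, c("p1", "p3", "p4"),
                                              cur))
    expect_setequal(m$id, c("A", "M"))
    # forced inclusion and absent-exclusion warning
    cur2 <- list(include_proteins = "COF1", exclude_proteins = "NOPE")
    expect_warning(m <- targetMembers(
        selectDirectSubstrates(iv, cellular, cur2)), "NOPE")
    expect_true("COF1" %in% m$id)
    # case-insensitive sequence comparison (modification marks)
    iv2 <- data.frame(protein_id = "Z", sequence = "ITSFPESEGYSyETSTK")
    m <- targetMembers(selectDirectSubstrates(iv2, "ITSFPESEGYSYETSTK"))
    expect_equal(m$id, "Z")
})

test_that("merging accumulates tags and is order independent", {
    a <- tsFor("A", "complex-level")
    b <- tsFor(c("A", "B"), "site-level")
    m <- targetMembers(mergeTargetSets(list(a, b)))
    expect_equal(sort(m$tag[m$id == "A"]),
                 c("complex-level", "site-level"))
    m2 <- targetMembers(mergeTargetSets(list(b, a)))
    expect_equal(m, m2)
    # associativity on member sets
    c_ <- tsFor("C", "direct-substrate")
    left <- mergeTargetSets(list(mergeTargetSets(list(a, b)), c_))
    right <- mergeTargetSets(list(a, mergeTargetSets(list(b, c_))))
    expect_equal(targetMembers(left), targetMembers(right))
    # disjoint sizes add, overlap reported
    ov <- targetOverlap(list(x = a, y = b))
    expect_equal(ov$n[ov$combination == "x+y"], 1L)
    expect_equal(sum(ov$n), 2L)
})

test_that("shipped curation defaults expose the reference lists", {
    cur <- curationDefaults()
    expect_true(all(c("Q14247", "P08670") %in% cur$exclude_proteins))
    expect_equal(cur$exclude_peptides$protein_id, "P46821")
    expect_setequal(cur$include_proteins, c("P23528", "Q9Y281"))
})
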