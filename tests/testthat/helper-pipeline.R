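# Run the complete pipeline (generate fixture files -> read -> curate ->
# enrich -> assemble -> weight -> walk -> extract) for one seed.
runFixturePipeline <- function(seed, epsilon = 0.2,
                               mode = "refined", ...) {
    dir <- file.path(tempdir(), sprintf("fx_seed%d", seed))
    unlink(dir, recursive = TRUE)
    fx <- generateFixture(fixtureSpec(seed = seed, ...), dir)
    gt <- fx$groundTruth
    cfg <- runConfig(dir, file.path(dir, "out"), epsilon = epsilon)
    targets <- suppressWarnings(cmdTargets(cfg))
    build <- suppressMessages(cmdBuild(cfg, sourceId = gt$source,
                                       targets = targets))
    extract <- cmdExtract(cfg, build, mode = mode,
                          targets = gt$plantedTargets)
    list(dir = dir, groundTruth = gt, cfg = cfg, targets = targets,
         build = build, extract = extract)
}
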