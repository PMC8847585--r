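test_that("config invariants are enforced", {
    expect_error(synthConfig(archetypeFractions = c(
        baseline = 0.5, methylated = 0.2, quiescent = 0.1,
        active = 0.1, prc2_target = 0.2)), "sum to 1")
    expect_error(synthConfig(meanCount = -1), "positive")
    expect_error(synthConfig(spikeinDepths = c(0, 100)), "positive")
})

test_that("gene placement is empty-safe, deterministic and disjoint", {
    cfg <- smallConfig()
    expect_length(simulateGenes(synthConfig(nGenes = 0, seed = 1)), 0)
    g1 <- simulateGenes(cfg)
    g2 <- simulateGenes(cfg)
    expect_identical(g1, g2)
    expect_length(g1, 300)
    expect_true(all(GenomicRanges::width(g1) >= 1))
    hits <- GenomicRanges::findOverlaps(g1, ignore.strand = TRUE,
                                        drop.self = TRUE)
    expect_length(hits, 0)
    # promoter windows never collide either (3 kb flanks guaranteed)
    prom <- GenomicRanges::promoters(g1, 3000, 3000)
    expect_length(GenomicRanges::findOverlaps(prom, ignore.strand = TRUE,
                                              drop.self = TRUE), 0)
})

test_that("insufficient chromosome space names the chromosome", {
    expect_error(
        simulateGenes(synthConfig(nGenes = 100,
                                  chromSizes = c(tiny = 5e4), seed = 1)),
        "tiny")
})

test_that("archetype fractions are honored exactly", {
    g <- simulateGenes(smallConfig())
    tab <- table(g$archetype)
    expect_equal(as.integer(tab[c("baseline", "methylated", "quiescent",
                                  "active", "prc2_target")]),
                 c(105, 45, 45, 60, 45))
})

test_that("tracks separate archetypes and respect noise settings", {
    cfg <- smallConfig()
    g <- simulateGenes(cfg)
    om <- simulateMultiOmics(g, config = cfg)
    truth <- setNames(as.character(g$archetype), names(g))
    k27 <- promoterSignal(om$tracks$h3k27me3, g)
    prc2 <- truth == "prc2_target"
    expect_gt(mean(k27[prc2]), mean(k27[!prc2]))
    beta <- methylationLevel(om$cpg, g)
    expect_true(all(beta >= 0 & beta <= 1, na.rm = TRUE))
    # zero-noise limit: promoter signal equals the archetype mean exactly
    cfg0 <- smallConfig(signalNoise = 0)
    g0 <- simulateGenes(cfg0)
    om0 <- simulateMultiOmics(g0, config = cfg0)
    k40 <- promoterSignal(om0$tracks$h3k4me3, g0)
    active <- names(g0)[g0$archetype == "active"]
    expect_equal(unname(k40[active]), rep(8, length(active)),
                 tolerance = 1e-12)
})

test_that("unknown archetype labels are rejected", {
    cfg <- smallConfig()
    g <- simulateGenes(cfg)
    truth <- setNames(rep("mystery", length(g)), names(g))
    expect_error(simulateMultiOmics(g, truth, cfg), "mystery")
})

test_that("counts are NB with the configured treatment effect", {
    # null configuration: no archetype has nonzero expected fold change
    cfg0 <- smallConfig(effectLog2FC = 0)
    g0 <- simulateGenes(cfg0)
    se0 <- simulateCounts(g0, config = cfg0)
    cnt0 <- SummarizedExperiment::assay(se0)
    ctrl <- se0$condition == "control"
    lfc0 <- log2((rowMeans(cnt0[, !ctrl]) + 1) /
                 (rowMeans(cnt0[, ctrl]) + 1))
    for (a in levels(g0$archetype))
        expect_lt(abs(mean(lfc0[g0$archetype == a])), 0.15)
    expect_true(all(cnt0 >= 0) && all(cnt0 == round(cnt0)))

    # Monte-Carlo mean over >= 500 prc2_target genes at large mean count
    cfg <- synthConfig(nGenes = 3400, meanCount = 2000, seed = 5,
                       chromSizes = c(chrL1 = 1.8e7, chrL2 = 1.8e7))
    g <- simulateGenes(cfg)
    se <- simulateCounts(g, config = cfg)
    cnt <- SummarizedExperiment::assay(se)
    prc2 <- g$archetype == "prc2_target"
    expect_gte(sum(prc2), 500)
    ctrl <- se$condition == "control"
    lfc <- log2((rowMeans(cnt[, !ctrl]) + 1) / (rowMeans(cnt[, ctrl]) + 1))
    expect_equal(mean(lfc[prc2]), 2, tolerance = 0.2)

    # dispersion sanity: variance exceeds mean within every archetype arm
    for (a in levels(g0$archetype)) {
        sub <- cnt0[g0$archetype == a, ctrl]
        expect_gt(mean(apply(sub, 1, var)), mean(rowMeans(sub)))
    }
})

test_that("count generation validates its preconditions", {
    cfg <- smallConfig(nReplicates = 1)
    g <- simulateGenes(cfg)
    expect_error(simulateCounts(g, config = cfg), "2 replicates")
})

test_that("cohort marker correlation matches the configuration", {
    cfg <- synthConfig(nGenes = 300, cohortN = 500, cohortCor = -0.8,
                       seed = 3)
    g <- simulateGenes(cfg)
    truth <- setNames(as.character(g$archetype), names(g))
    coh <- simulateCohort(truth, cfg)
    expr <- cohortExpr(coh)
    prc2 <- names(truth)[truth == "prc2_target"]
    r <- cor(expr[, "EZH2"], rowMeans(expr[, prc2]))
    expect_gt(r, -0.95); expect_lt(r, -0.6)

    cfg0 <- synthConfig(nGenes = 300, cohortN = 500, cohortCor = 0,
                        seed = 3)
    coh0 <- simulateCohort(truth, cfg0)
    expr0 <- cohortExpr(coh0)
    expect_lt(abs(cor(expr0[, "EZH2"], rowMeans(expr0[, prc2]))), 0.2)

    expect_identical(simulateCohort(truth, cfg), coh)
    expect_error(simulateCohort(truth, synthConfig(cohortN = 4)), ">= 8")
})

test_that("generators are order-independent through named sub-streams", {
    cfg <- smallConfig(seed = 11)
    g <- simulateGenes(cfg)
    truth <- setNames(as.character(g$archetype), names(g))
    # cohort drawn before counts must equal cohort drawn after
    cohA <- simulateCohort(truth, cfg)
    invisible(simulateCounts(g, config = cfg))
    cohB <- simulateCohort(truth, cfg)
    expect_identical(cohA, cohB)
})

test_that("stronger separation never hurts downstream clustering", {
    skip_if_not_installed("mclust")
    ari <- vapply(c(0.5, 0.25), function(noise) {
        cfg <- synthConfig(nGenes = 300, signalNoise = noise, seed = 13)
        g <- simulateGenes(cfg)
        om <- simulateMultiOmics(g, config = cfg)
        se <- simulateCounts(g, config = cfg)
        deg <- degTable(se)
        f <- suppressMessages(buildFeatureMatrix(
            setNames(deg$log2fc, rownames(deg)),
            suppressWarnings(methylationLevel(om$cpg, g)),
            promoterSignal(om$tracks$h3k4me3, g),
            promoterSignal(om$tracks$atac, g),
            promoterSignal(om$tracks$h3k27me3, g)))
        m <- kmeansFit(zscoreFeatures(f), 5, seed = 13)
        mclust::adjustedRandIndex(clusterAssignments(m),
                                  as.character(g$archetype))
    }, numeric(1))
    expect_gte(ari[2], ari[1] - 0.01)
})
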