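blobData <- function(centers, n = 40, sd = 0.3, seed = 5) {
    set.seed(seed)
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
        sweep(matrix(rnorm(n * ncol(centers), 0, sd), ncol = ncol(centers)),
              2, centers[i, ], "+")))
    rownames(x) <- sprintf("p%03d", seq_len(nrow(x)))
    attr(x, "label") <- rep(seq_len(nrow(centers)), each = n)
    x
}

test_that("feature assembly drops incomplete genes and keeps H3K27me3 out", {
    g <- paste0("g", 1:5)
    v <- function(x) setNames(x, g)
    expect_message(
        f <- buildFeatureMatrix(v(1:5), v(c(0.1, NA, 0.3, 0.4, 0.5)),
                                v(1:5), v(1:5), v(5:1)),
        "dropped")
    expect_equal(rownames(f@features), c("g1", "g3", "g4", "g5"))
    expect_equal(f@dropped, "g2")
    expect_false("h3k27me3" %in% colnames(f@features))
    expect_equal(unname(f@heldout), c(5, 3, 2, 1))
})

test_that("z-scoring uses population sd and handles degeneracy", {
    z <- zscoreFeatures(cbind(a = c(0, 2), b = c(5, 5)))
    expect_equal(unname(z[, "a"]), c(-1, 1))
    expect_equal(unname(z[, "b"]), c(0, 0))
    set.seed(6)
    m <- matrix(rnorm(80, 3, 2), ncol = 4,
                dimnames = list(NULL, letters[1:4]))
    z <- zscoreFeatures(m)
    expect_true(all(abs(colMeans(z)) < 1e-12))
    expect_true(all(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1)
                    < 1e-12))
    # idempotence
    expect_equal(zscoreFeatures(z), z, tolerance = 1e-9)
    expect_error(zscoreFeatures(matrix(1, 1, 2)), "2 genes")
})

test_that("k-means recovers separable structure exactly", {
    x <- rbind(matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE),
               matrix(rep(c(10, 10), 7), ncol = 2, byrow = TRUE))
    rownames(x) <- sprintf("r%02d", 1:12)
    m <- kmeansFit(x, 2, seed = 1)
    expect_equal(m@inertia, 0)
    expect_setequal(split(names(clusterAssignments(m)),
                          clusterAssignments(m)),
                    list(sprintf("r%02d", 1:5), sprintf("r%02d", 6:12)))
    expect_equal(sort(m@centers[, 1]), c(0, 10), ignore_attr = TRUE)
    # duplicate rows always share a cluster
    expect_length(unique(clusterAssignments(m)[1:5]), 1)
    expect_error(kmeansFit(x, 3, seed = 1), "distinct rows")
})

test_that("Lloyd inertia trace is non-increasing and seeded", {
    x <- blobData(rbind(c(0, 0), c(3, 0), c(0, 3)), sd = 1)
    m1 <- kmeansFit(x, 3, seed = 9)
    expect_true(all(diff(m1@trace) <= 1e-9))
    m2 <- kmeansFit(x, 3, seed = 9)
    expect_identical(clusterAssignments(m1), clusterAssignments(m2))
    # agrees with the reference Lloyd implementation from the same start
    set.seed(11)
    init <- x[sample(nrow(x), 3), ]
    ref <- stats::kmeans(x, init, algorithm = "Lloyd", iter.max = 100)
    ours <- prc2sig:::.lloyd(x, init, tol = 1e-9, maxIter = 100)
    expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("silhouette matches the four-point hand computation", {
    z <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
    s <- meanSilhouette(z, c(1, 1, 2, 2))
    # by hand: a = 0.1 for every point; b = 10.05 or 9.95
    hand <- mean(c((10.05 - 0.1) / 10.05, (10.05 - 0.1) / 10.05,
                   (9.95 - 0.1) / 9.95, (9.95 - 0.1) / 9.95))
    expect_equal(s, hand)
    expect_equal(round(s, 3), 0.99)
    expect_error(meanSilhouette(z, rep(1, 4)), "two clusters")
})

test_that("silhouette is near zero for random labels, bounded always", {
    set.seed(12)
    z <- matrix(rnorm(200), ncol = 2)
    s <- meanSilhouette(z, sample(1:2, 100, replace = TRUE))
    expect_lt(abs(s), 0.2)
    for (k in 2:4) {
        lab <- sample(k, 100, replace = TRUE)
        sk <- meanSilhouette(z, lab)
        expect_gte(sk, -1); expect_lte(sk, 1)
    }
})

test_that("silhouette agrees with the cluster-package reference", {
    skip_if_not_installed("cluster")
    set.seed(13)
    z <- blobData(rbind(c(0, 0), c(4, 1)), n = 30, sd = 0.8)
    lab <- attr(z, "label")
    ref <- mean(cluster::silhouette(lab, dist(z))[, "sil_width"])
    expect_equal(meanSilhouette(z, lab), ref, tolerance = 1e-12)
})

test_that("model selection finds well-separated blob counts", {
    x <- blobData(rbind(c(0, 0), c(8, 8)), n = 50, sd = 0.5, seed = 14)
    m <- selectK(x, kRange = 2:6, seed = 14, nInit = 5)
    expect_equal(m@k, 2L)
    expect_equal(nrow(silhouetteTable(m)), 5)
    expect_error(selectK(x, kRange = integer(0)), "feasible")
})

test_that("model selection is invariant to gene row order", {
    skip_if_not_installed("mclust")
    x <- blobData(rbind(c(0, 0), c(5, 0), c(0, 5)), n = 30, sd = 0.4,
                  seed = 15)
    m1 <- selectK(x, 2:5, seed = 15, nInit = 5)
    set.seed(16)
    perm <- sample(nrow(x))
    m2 <- selectK(x[perm, ], 2:5, seed = 15, nInit = 5)
    expect_equal(m1@k, m2@k)
    a1 <- clusterAssignments(m1)
    a2 <- clusterAssignments(m2)[names(a1)]
    expect_equal(mclust::adjustedRandIndex(a1, a2), 1)
})

test_that("held-out H3K27me3 labels exactly one PRC2-target cluster", {
    x <- blobData(rbind(c(0, 0), c(6, 0)), n = 20, sd = 0.3, seed = 17)
    m <- kmeansFit(x, 2, seed = 17)
    cl <- clusterAssignments(m)
    held <- setNames(ifelse(cl == 2, 9, 1) + rnorm(length(cl), 0, 0.1),
                     names(cl))
    m <- assignTypes(m, held)
    expect_equal(sum(typeMap(m) == "prc2_target"), 1)
    expect_equal(unname(typeMap(m)[["2"]]), "prc2_target")
    # tie goes to the lower cluster index, with a warning
    tied <- setNames(rep(1, length(cl)), names(cl))
    expect_warning(mt <- assignTypes(m, tied), "tie")
    expect_equal(unname(typeMap(mt)[["1"]]), "prc2_target")
    expect_error(assignTypes(m, held[-1]), "missing held-out")
})

test_that("the held-out column never influences the partition", {
    cfg <- smallConfig(seed = 19)
    sim <- simulateStudy(cfg)
    sf <- studyFeatures(sim)
    z <- zscoreFeatures(sf$features)
    m <- kmeansFit(z, 5, seed = 19)
    set.seed(20)
    permHeld <- setNames(sample(sf$features@heldout),
                         names(sf$features@heldout))
    m2 <- kmeansFit(z, 5, seed = 19)
    expect_identical(clusterAssignments(m), clusterAssignments(m2))
    t1 <- assignTypes(m, sf$features@heldout)
    t2 <- assignTypes(m2, permHeld)
    expect_identical(clusterAssignments(t1), clusterAssignments(t2))
})

test_that("typing recovers the simulated PRC2-target genes", {
    skip_if_not_installed("mclust")
    cfg <- smallConfig(seed = 23)
    sim <- simulateStudy(cfg)
    sf <- studyFeatures(sim)
    m <- kmeansFit(zscoreFeatures(sf$features), 5, seed = 23)
    m <- assignTypes(m, sf$features@heldout)
    truth <- archetypeTruth(sim)
    found <- typeGenes(m, "prc2_target")
    want <- names(truth)[truth == "prc2_target"]
    jaccard <- length(intersect(found, want)) /
        length(union(found, want))
    expect_gte(jaccard, 0.8)
    expect_gte(length(intersect(found, want)) / length(want), 0.9)
})

test_that("signature overlap is exact set arithmetic", {
    sig <- overlapSignature(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
    expect_equal(signatureGenes(sig), c("g2", "g3"))
    expect_equal(unname(vennCounts(sig)), c(3L, 3L, 2L))
    empty <- overlapSignature(c("a", "b"), c("c", "d"))
    expect_length(signatureGenes(empty), 0)
    expect_equal(unname(vennCounts(empty)), c(2L, 2L, 0L))
    sub <- overlapSignature(c("a", "b"), c("a", "b", "c"))
    expect_equal(signatureGenes(sub), c("a", "b"))
})
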