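# brute-force hypergeometric oracle: enumerate all tables with the same
# margins and sum the probabilities of overlaps >= a
fisherOracle <- function(a, b, c, d) {
    n <- a + b + c + d
    rowSig <- a + b; colSet <- a + c
    lo <- max(0, rowSig + colSet - n); hi <- min(rowSig, colSet)
    probs <- vapply(lo:hi, function(x)
        choose(colSet, x) * choose(n - colSet, rowSig - x),
        numeric(1)) / choose(n, rowSig)
    sum(probs[(lo:hi) >= a])
}

test_that("Fisher enrichment matches the hand-enumerated example", {
    fe <- fisherEnrich(3, 1, 1, 3)
    expect_equal(fe$p, 17 / 70)
    expect_equal(fe$oddsRatio, 9)
    expect_error(fisherEnrich(-1, 1, 1, 1), "nonnegative")
})

test_that("zero overlap at the feasible minimum gives p = 1", {
    expect_equal(fisherEnrich(0, 2, 2, 4)$p, 1)
})

test_that("Fisher p equals brute-force enumeration on random tables", {
    set.seed(101)
    for (i in 1:200) {
        cells <- sample(0:12, 4, replace = TRUE)
        if (sum(cells) == 0) cells <- c(1, 1, 1, 1)
        p <- fisherEnrich(cells[1], cells[2], cells[3], cells[4])$p
        expect_equal(p, fisherOracle(cells[1], cells[2], cells[3],
                                     cells[4]), tolerance = 1e-12)
    }
})

test_that("enrichment p is monotone non-increasing in the overlap", {
    # fixed margins: universe 40, signature 10, set 12
    ps <- vapply(2:10, function(a)
        fisherEnrich(a, 10 - a, 12 - a, 40 - 22 + a)$p, numeric(1))
    expect_true(all(diff(ps) <= 1e-15))
})

test_that("gene-set enrichment table is consistent and BH-adjusted", {
    universe <- paste0("g", 1:50)
    signature <- paste0("g", 1:10)
    sets <- list(self = signature,
                 half = paste0("g", 6:25),
                 off = paste0("g", 30:45),
                 alien = paste0("x", 1:5))
    expect_warning(enr <- enrichGenesets(signature, sets, universe),
                   "alien")
    expect_equal(nrow(enr), 3)
    expect_equal(enr$set[1], "self")   # maximal overlap, smallest p
    expect_equal(unname(enr$padj), unname(bhAdjust(enr$p)))
    expect_equal(enr$a + enr$b + enr$c + enr$d, rep(50L, 3))
    expect_error(enrichGenesets(signature, sets, character()), "universe")
    expect_error(enrichGenesets("zz", sets, universe), "subset")
})

test_that("GSEA enrichment score matches hand-run walks", {
    scores <- setNames(c(4, 3, 2, 1), paste0("g", 1:4))
    # all hits ranked first, weight 0 -> maximal front-loading, ES = 1
    es1 <- gseaPreranked(scores, c("g1", "g2"), weight = 0, nPerm = 50,
                         seed = 1)
    expect_equal(es1$es, 1)
    # interleaved hits at ranks 1 and 3: walk 0.5, 0, 0.5, 0 -> ES 0.5
    es2 <- gseaPreranked(scores, c("g1", "g3"), weight = 0, nPerm = 50,
                         seed = 1)
    expect_equal(es2$es, 0.5)
    # reversing the ranking negates the score (weight 0)
    es3 <- gseaPreranked(-scores, c("g1", "g2"), weight = 0, nPerm = 50,
                         seed = 1)
    expect_equal(es3$es, -1)
    expect_gte(es2$pPerm, 1 / 51)
    expect_error(gseaPreranked(scores, "absent"), "intersect")
})

test_that("GSEA agrees with an independent running-sum implementation", {
    skip_if_not_installed("fgsea")
    set.seed(103)
    scores <- setNames(sort(rnorm(60), decreasing = TRUE),
                       paste0("g", 1:60))
    hits <- sample(names(scores), 12)
    ours <- gseaPreranked(scores, hits, weight = 1, nPerm = 10, seed = 1)
    ref <- fgsea::calcGseaStat(scores, which(names(scores) %in% hits),
                               gseaParam = 1)
    expect_equal(ours$es, ref, tolerance = 1e-12)
})

test_that("GSEA permutation p is approximately uniform on random sets", {
    set.seed(104)
    scores <- setNames(rnorm(150), paste0("g", 1:150))
    ps <- vapply(1:200, function(i)
        gseaPreranked(scores, sample(names(scores), 15), weight = 1,
                      nPerm = 99, seed = i)$pPerm, numeric(1))
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
})

test_that("Kruskal-Wallis matches the rank-formula oracle", {
    kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
    expect_equal(kw$H, 27 / 7, tolerance = 1e-12)   # ~3.857
    expect_equal(kw$df, 1)
    degenerate <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
    expect_equal(degenerate$H, 0)
    expect_equal(degenerate$p, 1)
    expect_error(kruskalWallis(list(1:3)), "two groups")
    expect_error(kruskalWallis(list(1:3, numeric())), "non-empty")

    kwOracle <- function(groups) {
        x <- unlist(groups)
        n <- length(x)
        r <- rank(x)                         # midranks for ties
        Rj <- vapply(split(r, rep(seq_along(groups), lengths(groups))),
                     sum, numeric(1))
        H <- 12 / (n * (n + 1)) * sum(Rj^2 / lengths(groups)) -
            3 * (n + 1)
        ties <- table(x)
        H / (1 - sum(ties^3 - ties) / (n^3 - n))
    }
    set.seed(105)
    for (i in 1:100) {
        g <- lapply(seq_len(sample(2:4, 1)), function(j)
            sample(1:8, sample(3:8, 1), replace = TRUE))
        if (length(unique(unlist(g))) == 1) next
        expect_equal(kruskalWallis(g)$H, kwOracle(g), tolerance = 1e-10)
    }
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
    set.seed(106)
    g <- list(rnorm(10), rnorm(8, 1), rnorm(12, 2))
    h1 <- kruskalWallis(g)$H
    expect_equal(kruskalWallis(lapply(g, exp))$H, h1, tolerance = 1e-12)
    expect_equal(kruskalWallis(lapply(g, function(x) 5 * x - 2))$H, h1,
                 tolerance = 1e-12)
})
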