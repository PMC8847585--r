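#' @importFrom stats phyper pchisq kruskal.test fisher.test
NULL

#' Fisher's exact enrichment test (one-sided)
#'
#' Upper-tail hypergeometric probability of observing an overlap at least
#' as large as \code{a} at fixed margins, for the 2x2 table
#' (a = signature genes in the set, b = signature genes outside it,
#' c = set genes outside the signature, d = remaining universe genes),
#' plus the sample odds ratio \code{ad/bc} (infinite when \code{bc = 0}).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return list with elements \code{p} and \code{oddsRatio}.
#' @examples
#' fisherEnrich(3, 1, 1, 3)  # p = 17/70, OR = 9
#' @export
fisherEnrich <- function(a, b, c, d) {
    cells <- c(a = a, b = b, c = c, d = d)
    if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
        stop("contingency cells must be nonnegative integers")
    # X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c); P(X >= a)
    p <- phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
    or <- if (b * c == 0) {
        if (a * d == 0) NaN else Inf
    } else a * d / (b * c)
    list(p = p, oddsRatio = or)
}

#' Gene-set enrichment of a signature by Fisher's exact test
#'
#' Intersects each gene set with the universe, builds the 2x2 table
#' against the signature, tests enrichment one-sided, and adjusts across
#' sets with Benjamini-Hochberg. Sets that are empty after intersection
#' with the universe are skipped with a warning.
#'
#' @param signature character vector of signature genes (must be within
#'   the universe).
#' @param genesets named list of character vectors, e.g. from
#'   \code{\link{readGmt}}.
#' @param universe character vector of all testable genes.
#' @return \code{\link[S4Vectors]{DataFrame}} sorted by p with columns
#'   \code{set, a, b, c, d, oddsRatio, p, padj}.
#' @export
enrichGenesets <- function(signature, genesets, universe) {
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty universe")
    signature <- unique(as.character(signature))
    if (!all(signature %in% universe))
        stop("signature must be a subset of the universe")
    sets <- lapply(genesets, function(s) intersect(s, universe))
    empty <- lengths(sets) == 0L
    if (any(empty)) {
        warning("skipping ", sum(empty),
                " gene set(s) disjoint from the universe: ",
                paste(utils::head(names(sets)[empty], 5), collapse = ", "))
        sets <- sets[!empty]
    }
    if (!length(sets)) stop("no testable gene sets")
    rows <- lapply(names(sets), function(nm) {
        s <- sets[[nm]]
        a <- length(intersect(signature, s))
        b <- length(signature) - a
        cc <- length(s) - a
        d <- length(universe) - a - b - cc
        fe <- fisherEnrich(a, b, cc, d)
        data.frame(set = nm, a = a, b = b, c = cc, d = d,
                   oddsRatio = fe$oddsRatio, p = fe$p)
    })
    out <- do.call(rbind, rows)
    out$padj <- bhAdjust(out$p)
    out <- out[order(out$p), ]
    rownames(out) <- NULL
    DataFrame(out)
}

#' Preranked GSEA with a gene-permutation null
#'
#' Minimal preranked gene-set enrichment: genes are ordered by decreasing
#' score and a running sum is walked down the list, incrementing at set
#' members by \code{|score|^weight} (normalized by the members' total)
#' and decrementing at non-members by \code{1/(N - |S|)}. The enrichment
#' score ES is the signed maximal deviation from zero. The null
#' distribution permutes gene labels (random member positions);
#' \code{pPerm = (1 + #(|ES*| >= |ES|)) / (nPerm + 1)}, and NES divides
#' ES by the mean |ES*| of the same-sign permutations.
#'
#' @param scores named numeric vector of ranking scores (any order;
#'   sorted internally, decreasing).
#' @param geneset character vector; must intersect the ranked list.
#' @param weight exponent on |score| for hit increments (0 gives the
#'   classical Kolmogorov-Smirnov walk; default 1).
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return list with \code{es}, \code{nes}, \code{pPerm}, \code{nPerm},
#'   \code{nHits}, \code{seed}.
#' @export
gseaPreranked <- function(scores, geneset, weight = 1, nPerm = 1000,
                          seed = 42) {
    if (anyNA(scores) || any(!is.finite(scores)))
        stop("scores must be finite")
    ord <- order(scores, decreasing = TRUE)
    scores <- scores[ord]
    hits <- names(scores) %in% geneset
    nHits <- sum(hits)
    if (nHits == 0L)
        stop("gene set does not intersect the ranked list")
    N <- length(scores)
    if (nHits == N) stop("gene set covers the whole ranked list")
    esFromHits <- function(hitIdx) {
        inc <- numeric(N)
        w <- abs(scores[hitIdx])^weight
        tot <- sum(w)
        inc[hitIdx] <- if (tot > 0) w / tot else 1 / length(hitIdx)
        inc[-hitIdx] <- -1 / (N - length(hitIdx))
        run <- cumsum(inc)
        run[which.max(abs(run))]
    }
    es <- esFromHits(which(hits))
    perm <- .withSeed(.subSeed(seed, "gsea_perm"), {
        vapply(seq_len(nPerm),
               function(i) esFromHits(sample.int(N, nHits)), numeric(1))
    })
    pPerm <- (1 + sum(abs(perm) >= abs(es))) / (nPerm + 1)
    sameSign <- perm[sign(perm) == sign(es)]
    nes <- if (length(sameSign)) es / mean(abs(sameSign)) else NA_real_
    list(es = es, nes = nes, pPerm = pPerm, nPerm = nPerm,
         nHits = nHits, seed = seed)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' H statistic with midrank ties correction and a chi-square p-value on
#' (number of groups - 1) degrees of freedom. When every value is
#' identical the ties correction is degenerate and the test is defined as
#' H = 0, p = 1.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with \code{H}, \code{p}, \code{df}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))  # H ~ 3.857
#' @export
kruskalWallis <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need at least two groups")
    if (any(lengths(groups) == 0L)) stop("groups must be non-empty")
    values <- unlist(groups, use.names = FALSE)
    if (length(values) < 3L) stop("need at least 3 observations in total")
    if (length(unique(values)) == 1L)
        return(list(H = 0, p = 1, df = length(groups) - 1L))
    g <- factor(rep(seq_along(groups), lengths(groups)))
    kt <- kruskal.test(values, g)
    list(H = unname(kt$statistic), p = kt$p.value,
         df = unname(kt$parameter))
}
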