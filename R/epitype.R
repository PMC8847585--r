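# Multi-omic k-means gene typing with silhouette-based model selection.

#' Assemble the per-gene multi-omic feature matrix
#'
#' Aligns the four clustering features (expression log2FC, promoter
#' methylation beta, H3K4me3 and ATAC promoter signal) and the held-out
#' promoter H3K27me3 by gene id. Genes missing any value are dropped and
#' recorded; H3K27me3 never enters the clustering columns and is used
#' only afterwards to label the PRC2-target type.
#'
#' @param log2fc,methylation,h3k4me3,atac,h3k27me3 named numeric vectors
#'   keyed by gene id (any order; the intersection of names is used).
#' @return an \code{\linkS4class{EpitypeFeatures}}.
#' @export
buildFeatureMatrix <- function(log2fc, methylation, h3k4me3, atac,
                               h3k27me3) {
    genes <- Reduce(intersect, list(names(log2fc), names(methylation),
                                    names(h3k4me3), names(atac),
                                    names(h3k27me3)))
    all <- unique(c(names(log2fc), names(methylation), names(h3k4me3),
                    names(atac), names(h3k27me3)))
    f <- cbind(expr_log2fc = log2fc[genes],
               methylation = methylation[genes],
               h3k4me3 = h3k4me3[genes],
               atac = atac[genes])
    rownames(f) <- genes
    keep <- stats::complete.cases(f) & !is.na(h3k27me3[genes])
    dropped <- sort(c(setdiff(all, genes), genes[!keep]))
    if (length(dropped))
        message(length(dropped),
                " gene(s) dropped for missing features")
    genes <- genes[keep]
    new("EpitypeFeatures", features = f[genes, , drop = FALSE],
        heldout = setNames(as.numeric(h3k27me3[genes]), genes),
        dropped = dropped)
}

#' Z-score feature columns
#'
#' Centers each column to mean 0 and scales to population standard
#' deviation 1 (divisor n, not n-1). Zero-variance columns map to all
#' zeros rather than erroring.
#'
#' @param x numeric matrix (genes x features) or an
#'   \code{\linkS4class{EpitypeFeatures}} (whose clustering columns are
#'   standardized; the held-out column is untouched).
#' @return object of the same class with standardized columns.
#' @export
zscoreFeatures <- function(x) {
    if (is(x, "EpitypeFeatures")) {
        x@features <- zscoreFeatures(x@features)
        return(x)
    }
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("need at least 2 genes to z-score")
    mu <- colMeans(x)
    sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
    z <- sweep(x, 2, mu)
    nz <- sdev > 0
    z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdev[nz], "/")
    z[, !nz] <- 0
    z
}

# squared Euclidean distances from each row of x to each row of centers
.sqDistToCenters <- function(x, centers) {
    outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to the squared
# distance to the nearest chosen center.
.kmeansppInit <- function(x, k) {
    n <- nrow(x)
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
    for (j in seq_len(k - 1L)) {
        tot <- sum(d2)
        idx[j + 1L] <- if (tot <= 0) sample.int(n, 1L)
            else sample.int(n, 1L, prob = d2 / tot)
        d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j + 1L], ])^2))
    }
    x[idx, , drop = FALSE]
}

# Lloyd iterations from a fixed set of initial centers, recording inertia
# after each iteration. Empty clusters are reseeded to the point farthest
# from its current center.
.lloyd <- function(x, centers, tol, maxIter) {
    trace <- numeric(0)
    assign <- rep(NA_integer_, nrow(x))
    inertia <- Inf
    for (iter in seq_len(maxIter)) {
        d2 <- .sqDistToCenters(x, centers)
        assign <- max.col(-d2, ties.method = "first")
        for (j in which(tabulate(assign, nrow(centers)) == 0L)) {
            far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
            assign[far] <- j
        }
        newInertia <- 0
        for (j in seq_len(nrow(centers))) {
            rows <- assign == j
            centers[j, ] <- colMeans(x[rows, , drop = FALSE])
            newInertia <- newInertia +
                sum(sweep(x[rows, , drop = FALSE], 2, centers[j, ])^2)
        }
        trace <- c(trace, newInertia)
        if (inertia - newInertia <= tol) { inertia <- newInertia; break }
        inertia <- newInertia
    }
    list(centers = centers, cluster = assign, inertia = inertia,
         trace = trace)
}

#' Fit k-means in z-scored feature space
#'
#' Lloyd's algorithm with k-means++ initialization, run \code{nInit}
#' times from the seeded stream; the restart with the lowest inertia
#' (total within-cluster sum of squares) wins. Deterministic given
#' \code{seed}.
#'
#' @param z numeric matrix of standardized features (genes x features),
#'   or an \code{\linkS4class{EpitypeFeatures}} whose feature matrix is
#'   used as-is.
#' @param k number of clusters (at most the number of distinct rows).
#' @param seed RNG seed for initialization.
#' @param nInit number of restarts (default 10).
#' @param tol stop when an iteration improves inertia by no more than
#'   this (default 1e-6).
#' @param maxIter Lloyd iteration cap per restart (default 300).
#' @return an \code{\linkS4class{EpitypeModel}}.
#' @export
kmeansFit <- function(z, k, seed = 42, nInit = 10, tol = 1e-6,
                      maxIter = 300) {
    if (is(z, "EpitypeFeatures")) z <- z@features
    z <- as.matrix(z)
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    nDistinct <- nrow(unique(z))
    if (k > nDistinct)
        stop("k = ", k, " exceeds the number of distinct rows (",
             nDistinct, ")")
    if (is.null(rownames(z)))
        rownames(z) <- sprintf("row%d", seq_len(nrow(z)))
    best <- NULL
    .withSeed(.subSeed(seed, "kmeans"), {
        for (i in seq_len(nInit)) {
            fit <- .lloyd(z, .kmeansppInit(z, k), tol, maxIter)
            if (is.null(best) || fit$inertia < best$inertia) best <- fit
        }
    })
    new("EpitypeModel", k = k, centers = best$centers,
        cluster = setNames(best$cluster, rownames(z)),
        inertia = best$inertia, trace = best$trace,
        nInit = as.integer(nInit), seed = as.integer(seed),
        silhouette = data.frame(), typeMap = character())
}

#' Mean silhouette coefficient of a clustering
#'
#' Standard silhouette: for each point, \code{a} is the mean distance to
#' its own cluster's other members and \code{b} the smallest mean
#' distance to any other cluster; \code{s = (b - a) / max(a, b)}. Points
#' in singleton clusters score 0. Returns the mean over points, in
#' [-1, 1].
#'
#' @param z numeric matrix of features (genes x features).
#' @param assignments integer cluster labels, one per row; at least two
#'   distinct non-empty clusters.
#' @return mean silhouette width.
#' @export
meanSilhouette <- function(z, assignments) {
    z <- as.matrix(z)
    assignments <- as.integer(as.factor(assignments))
    ks <- sort(unique(assignments))
    if (length(ks) < 2L)
        stop("silhouette requires at least two clusters")
    n <- nrow(z)
    d <- as.matrix(stats::dist(z))
    sizes <- tabulate(assignments, max(ks))
    # mean distance from each point to each cluster
    meanTo <- vapply(ks, function(j)
        rowSums(d[, assignments == j, drop = FALSE]) / sizes[j],
        numeric(n))
    s <- numeric(n)
    for (i in seq_len(n)) {
        ci <- assignments[i]
        if (sizes[ci] == 1L) { s[i] <- 0; next }
        a <- meanTo[i, ci] * sizes[ci] / (sizes[ci] - 1L)
        b <- min(meanTo[i, -ci])
        s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    mean(s)
}

#' Select the number of gene types by mean silhouette
#'
#' Fits \code{\link{kmeansFit}} for every k in \code{kRange}, scores each
#' solution with \code{\link{meanSilhouette}}, and returns the model for
#' the k that maximizes the mean silhouette (ties broken toward smaller
#' k). The full per-k table is kept in the returned model's
#' \code{silhouette} slot for audit, so the automatic choice can be
#' overridden.
#'
#' @inheritParams kmeansFit
#' @param kRange candidate cluster numbers (default 2:10).
#' @return the winning \code{\linkS4class{EpitypeModel}} with its
#'   \code{silhouette} table filled (columns k, silhouette, inertia).
#' @export
selectK <- function(z, kRange = 2:10, seed = 42, nInit = 10) {
    if (is(z, "EpitypeFeatures")) z <- z@features
    z <- as.matrix(z)
    kRange <- sort(unique(as.integer(kRange)))
    kRange <- kRange[kRange >= 2L & kRange <= nrow(unique(z))]
    if (!length(kRange)) stop("no feasible k in range")
    models <- vector("list", length(kRange))
    sil <- numeric(length(kRange))
    for (i in seq_along(kRange)) {
        models[[i]] <- kmeansFit(z, kRange[i], seed = seed, nInit = nInit)
        sil[i] <- meanSilhouette(z, clusterAssignments(models[[i]]))
    }
    tab <- data.frame(k = kRange, silhouette = sil,
                      inertia = vapply(models, function(m) m@inertia,
                                       numeric(1)))
    best <- models[[which.max(sil)]]   # which.max takes the first maximum
    best@silhouette <- tab
    best
}

#' Label clusters; identify the PRC2-target type by held-out H3K27me3
#'
#' The cluster with the highest mean held-out promoter H3K27me3 becomes
#' \code{prc2_target} (ties go to the lower cluster index, with a
#' warning). Remaining clusters are labeled from their centroid in
#' z-space: all-negative centroids are \code{quiescent}, centroids near
#' the origin are \code{baseline}, and otherwise the maximal feature
#' names the type (\code{methylation} -> methylated, \code{h3k4me3} or
#' \code{atac} -> active, \code{expr_log2fc} -> induced); duplicate
#' labels get an index suffix.
#'
#' @param model a fitted \code{\linkS4class{EpitypeModel}}.
#' @param heldout named numeric H3K27me3 per gene, covering every
#'   clustered gene.
#' @return the model with its \code{typeMap} slot filled.
#' @export
assignTypes <- function(model, heldout) {
    cl <- clusterAssignments(model)
    missing <- setdiff(names(cl), names(heldout)[!is.na(heldout)])
    if (length(missing))
        stop("missing held-out H3K27me3 for gene(s): ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) " ...")
    means <- vapply(seq_len(model@k), function(j)
        mean(heldout[names(cl)[cl == j]]), numeric(1))
    top <- which(means == max(means))
    if (length(top) > 1L)
        warning("tie in mean H3K27me3 between clusters ",
                paste(top, collapse = ", "), "; lower index wins")
    prc2 <- top[1]
    labels <- character(model@k)
    labels[prc2] <- "prc2_target"
    featLabel <- c(expr_log2fc = "induced", methylation = "methylated",
                   h3k4me3 = "active", atac = "active")
    for (j in setdiff(seq_len(model@k), prc2)) {
        cen <- model@centers[j, ]
        top <- colnames(model@centers)[which.max(cen)]
        labels[j] <- if (max(cen) < 0) "quiescent"
            else if (max(abs(cen)) < 0.5) "baseline"
            else if (!is.null(top) && top %in% names(featLabel))
                featLabel[[top]]
            else paste0("cluster", j)
    }
    dup <- duplicated(labels)
    labels[dup] <- paste0(labels[dup], "_", which(dup))
    model@typeMap <- setNames(labels, as.character(seq_len(model@k)))
    validObject(model)
    model
}

#' Extract the signature by overlapping type genes with up-DEGs
#'
#' The PRC2-target signature is the sorted intersection of the genes of
#' the H3K27me3-high type with the up-regulated DEGs; Venn counts are
#' recorded alongside.
#'
#' @param typeGenes character vector of genes in the selected type.
#' @param upDegs character vector of up-regulated genes.
#' @return a \code{\linkS4class{SignatureResult}}.
#' @examples
#' overlapSignature(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
#' @export
overlapSignature <- function(typeGenes, upDegs) {
    typeGenes <- unique(as.character(typeGenes))
    upDegs <- unique(as.character(upDegs))
    sig <- sort(intersect(typeGenes, upDegs))
    new("SignatureResult", typeGenes = typeGenes, upDegs = upDegs,
        signature = sig,
        counts = c(nType = length(typeGenes), nUp = length(upDegs),
                   nOverlap = length(sig)))
}

#' Genes belonging to a semantic type
#'
#' @param model an \code{\linkS4class{EpitypeModel}} with types assigned.
#' @param type semantic label, e.g. \code{"prc2_target"}.
#' @return character vector of gene ids.
#' @export
typeGenes <- function(model, type = "prc2_target") {
    if (!length(model@typeMap)) stop("run assignTypes() first")
    idx <- names(model@typeMap)[model@typeMap == type]
    if (!length(idx)) stop("no cluster labeled ", type)
    cl <- clusterAssignments(model)
    names(cl)[cl %in% as.integer(idx)]
}
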