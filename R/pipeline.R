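#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
NULL

.defaultConfig <- function() {
    list(
        stages = list(simulate = TRUE, quantify = TRUE, deg = TRUE,
                      cluster = TRUE, enrich = TRUE, cohort = TRUE),
        seed = 42,
        syndata = list(nGenes = 2000, effectLog2FC = 2,
                       nbDispersion = 0.05, meanCount = 200,
                       nReplicates = 3, cohortN = 498, cohortCor = -0.8,
                       signalNoise = 0.3),
        windowBp = 3000,
        pseudocount = 1,
        lfc = 1,
        alpha = 0.05,
        kmin = 2,
        kmax = 10,
        nInit = 10,
        cohortPseudocount = 1,
        cohortThreshold = 1
    )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults for missing keys (an empty document yields the full
#' default configuration) and collects every contradiction before
#' erroring, so a bad config reports all its problems at once.
#' Idempotent: normalizing a normalized config is a no-op.
#'
#' @param config named list (e.g. from \code{yaml::read_yaml}) or NULL.
#' @return the normalized configuration list.
#' @export
validateConfig <- function(config = NULL) {
    def <- .defaultConfig()
    if (is.null(config)) config <- list()
    merged <- utils::modifyList(def, config)
    errs <- character()
    chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
    chk(is.numeric(merged$alpha) && merged$alpha > 0 && merged$alpha <= 1,
        "alpha must lie in (0, 1]")
    chk(merged$kmin >= 2, "kmin must be >= 2")
    chk(merged$kmin <= merged$kmax, "kmin must not exceed kmax")
    chk(merged$windowBp > 0, "windowBp must be positive")
    chk(merged$lfc >= 0, "lfc must be nonnegative")
    chk(merged$pseudocount >= 0, "pseudocount must be nonnegative")
    chk(merged$syndata$nGenes > 0, "syndata$nGenes must be positive")
    chk(merged$syndata$nReplicates >= 2,
        "syndata$nReplicates must be >= 2")
    chk(merged$syndata$cohortN >= 8, "syndata$cohortN must be >= 8")
    chk(merged$nInit >= 1, "nInit must be >= 1")
    unknown <- setdiff(names(config), names(def))
    if (length(unknown))
        errs <- c(errs, paste("unknown key(s):",
                              paste(unknown, collapse = ", ")))
    if (length(errs))
        stop("invalid configuration:\n  ",
             paste(errs, collapse = "\n  "))
    merged
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing keys take defaults.
#' @return normalized configuration list.
#' @export
readRunConfig <- function(path) {
    validateConfig(yaml::read_yaml(path))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the signature-discovery pipeline end to end
#'
#' Executes the enabled stages in order — simulate the multi-omic study,
#' quantify promoter signal and methylation, test differential
#' expression, cluster genes and select k by silhouette, extract and
#' enrich the signature, and validate against the simulated cohort —
#' writing every artifact plus a checksummed manifest and a JSON run
#' report to \code{outdir}. A stage failure marks that stage failed in
#' the report and skips its downstream dependents. Fully reproducible
#' given the configured seed.
#'
#' @param config configuration list (see \code{\link{validateConfig}}).
#' @param outdir output directory.
#' @return the run report, invisibly (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config = NULL, outdir = tempfile("prc2sig_")) {
    cfg <- validateConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    report <- list(parameters = cfg, seeds = list(master = cfg$seed),
                   stages = list(), counts = list())
    state <- new.env(parent = emptyenv())
    artifacts <- character()

    runStage <- function(name, deps, fun) {
        if (!isTRUE(cfg$stages[[name]])) {
            report$stages[[name]] <<- list(status = "disabled")
            return()
        }
        missing <- deps[!vapply(deps, function(d)
            identical(report$stages[[d]]$status, "ok"), logical(1))]
        if (length(missing)) {
            report$stages[[name]] <<- list(
                status = "skipped",
                reason = paste("unmet dependency:",
                               paste(missing, collapse = ", ")))
            return()
        }
        res <- tryCatch({ fun(); list(status = "ok") },
                        error = function(e)
                            list(status = "failed",
                                 error = conditionMessage(e)))
        report$stages[[name]] <<- res
    }

    runStage("simulate", character(), function() {
        sd <- cfg$syndata
        state$sim <- simulateStudy(synthConfig(
            nGenes = sd$nGenes, effectLog2FC = sd$effectLog2FC,
            nbDispersion = sd$nbDispersion, meanCount = sd$meanCount,
            nReplicates = sd$nReplicates, cohortN = sd$cohortN,
            cohortCor = sd$cohortCor, signalNoise = sd$signalNoise,
            seed = cfg$seed))
        artifacts <<- c(artifacts,
                        writeSimulation(state$sim,
                                        file.path(outdir, "simulated")))
        report$counts$genesIn <<- length(state$sim@genes)
    })

    runStage("quantify", "simulate", function() {
        sim <- state$sim
        state$signal <- lapply(sim@tracks, promoterSignal,
                               annotation = sim@genes,
                               windowBp = cfg$windowBp)
        state$meth <- suppressWarnings(
            methylationLevel(sim@cpg, sim@genes, cfg$windowBp))
        df <- data.frame(gene_id = names(sim@genes),
                         h3k27me3 = state$signal$h3k27me3,
                         h3k4me3 = state$signal$h3k4me3,
                         atac = state$signal$atac,
                         methylation = as.numeric(state$meth))
        artifacts <<- c(artifacts,
                        .writeTsv(df, file.path(outdir,
                                                "promoter_signal.tsv")))
    })

    runStage("deg", "simulate", function() {
        sim <- state$sim
        state$deg <- degTable(sim@counts, pseudocount = cfg$pseudocount,
                              lfc = cfg$lfc, alpha = cfg$alpha)
        state$degCalls <- callDegs(state$deg, cfg$lfc, cfg$alpha)
        df <- data.frame(gene_id = rownames(state$deg),
                         as.data.frame(state$deg))
        artifacts <<- c(artifacts,
                        .writeTsv(df, file.path(outdir, "deg.tsv")))
        report$counts$nUp <<- length(state$degCalls$up)
        report$counts$nDown <<- length(state$degCalls$down)
    })

    runStage("cluster", c("quantify", "deg"), function() {
        feats <- suppressMessages(buildFeatureMatrix(
            log2fc = setNames(state$deg$log2fc, rownames(state$deg)),
            methylation = state$meth,
            h3k4me3 = state$signal$h3k4me3,
            atac = state$signal$atac,
            h3k27me3 = state$signal$h3k27me3))
        z <- zscoreFeatures(feats)
        model <- selectK(z, kRange = cfg$kmin:cfg$kmax,
                         seed = cfg$seed, nInit = cfg$nInit)
        model <- assignTypes(model, feats@heldout)
        state$model <- model
        cl <- clusterAssignments(model)
        state$types <- setNames(
            unname(typeMap(model)[as.character(cl)]), names(cl))
        sig <- overlapSignature(typeGenes(model, "prc2_target"),
                                state$degCalls$up)
        state$signature <- sig
        artifacts <<- c(
            artifacts,
            .writeTsv(data.frame(gene_id = names(cl), cluster = cl,
                                 type = state$types),
                      file.path(outdir, "assignments.tsv")),
            .writeTsv(silhouetteTable(model),
                      file.path(outdir, "silhouette.tsv")))
        p <- file.path(outdir, "signature.txt")
        writeLines(signatureGenes(sig), p)
        artifacts <<- c(artifacts, p)
        p <- file.path(outdir, "venn.json")
        write_json(as.list(vennCounts(sig)), p, auto_unbox = TRUE)
        artifacts <<- c(artifacts, p)
        report$counts$genesDropped <<- length(feats@dropped)
        report$counts$selectedK <<- model@k
        report$counts$signatureSize <<- length(signatureGenes(sig))
    })

    runStage("enrich", "cluster", function() {
        sim <- state$sim
        truth <- archetypeTruth(sim)
        universe <- rownames(state$deg)
        sets <- split(names(truth), truth)
        enr <- enrichGenesets(signatureGenes(state$signature),
                              sets, universe)
        artifacts <<- c(artifacts,
                        .writeTsv(as.data.frame(enr),
                                  file.path(outdir, "enrichment.tsv")))
        ranked <- setNames(state$deg$stat, rownames(state$deg))
        gsea <- gseaPreranked(ranked, sets$prc2_target,
                              seed = cfg$seed)
        p <- file.path(outdir, "gsea.json")
        write_json(gsea, p, auto_unbox = TRUE, digits = NA)
        artifacts <<- c(artifacts, p)
    })

    runStage("cohort", "cluster", function() {
        sim <- state$sim
        split <- quartileSplit(sim@cohort)
        fcAll <- stratifiedFC(sim@cohort, split,
                              pseudocount = cfg$cohortPseudocount)
        fc <- fcAll[setdiff(names(fcAll), markerGene(sim@cohort))]
        up <- callCohortUpDegs(fc, threshold = cfg$cohortThreshold)
        summ <- typeFCSummary(fc, state$types)
        p <- file.path(outdir, "cohort_split.json")
        write_json(list(marker = markerGene(sim@cohort),
                        low = lowGroup(split), high = highGroup(split),
                        bounds = split@bounds), p, auto_unbox = TRUE)
        artifacts <<- c(
            artifacts, p,
            .writeTsv(data.frame(gene_id = names(fc), log2fc = fc),
                      file.path(outdir, "cohort_fc.tsv")),
            .writeTsv(summ$summary,
                      file.path(outdir, "cohort_type_summary.tsv")))
        report$counts$cohortUpDegs <<- length(up)
        report$counts$cohortKruskalP <<- summ$kruskal$p
    })

    files <- setdiff(list.files(outdir, recursive = TRUE),
                     c("manifest.tsv", "report.json"))
    manifest <- data.frame(
        file = files,
        md5 = unname(md5sum(file.path(outdir, files))))
    .writeTsv(manifest, file.path(outdir, "manifest.tsv"))
    write_json(report, file.path(outdir, "report.json"),
               auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(report)
}
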