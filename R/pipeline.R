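## End-to-end orchestration of the simulated timecourse analysis:
## simulate -> downsample -> balance -> O/E -> decay -> compartments ->
## TADs -> interactions -> enrichment, with TSV/BED/bedGraph outputs and a
## reproducibility manifest.

#' @importFrom tools md5sum
NULL

#' Pipeline configuration
#'
#' Declarative configuration of the demonstration timecourse analysis:
#' simulated chromosomes, perturbation schedule and every analysis
#' threshold. Defaults mirror the package-wide defaults (40 kb bins,
#' 2-fold strength classification, TAD FDR 0.05, interaction FDR 0.01 with
#' 10-fold O/E, top/bottom deciles for condensate classes).
#'
#' @param nChroms number of simulated chromosomes
#' @param nBins,binSize,depth,nReplicates per-chromosome simulation size
#' @param decayExponent,compartmentAmplitude,tadBoost,loopBoost generator
#'   parameters, see \code{\link{simConfig}}
#' @param schedule a \code{\link{perturbationSchedule}}
#' @param strengthFold per-bin strength fold-change threshold
#' @param fdrTad boundary-change FDR threshold
#' @param fdrInteraction interaction-call FDR threshold
#' @param minOE interaction O/E filter
#' @param topQ signal decile fraction for interaction classes
#' @param rcpDistance distance (bp) for RCP fold changes
#' @param changedDistance distance (bp) for changed-interaction fractions
#' @param apaK APA window half-width in bins
#' @param seed master seed
#' @return list with class "pipelineConfig"
#' @export
pipelineConfig <- function(nChroms = 5L, nBins = 500L, binSize = 40000,
                           depth = 1e6, nReplicates = 2L,
                           decayExponent = 1.0, compartmentAmplitude = 1.0,
                           tadBoost = 2.0, loopBoost = 3.0,
                           schedule = perturbationSchedule(),
                           strengthFold = 2, fdrTad = 0.05,
                           fdrInteraction = 0.01, minOE = 10, topQ = 0.10,
                           rcpDistance = 10e6, changedDistance = 1e6,
                           apaK = 5L, seed = 1L) {
    cfg <- list(nChroms = as.integer(nChroms), nBins = as.integer(nBins),
                binSize = binSize, depth = depth,
                nReplicates = as.integer(nReplicates),
                decayExponent = decayExponent,
                compartmentAmplitude = compartmentAmplitude,
                tadBoost = tadBoost, loopBoost = loopBoost,
                schedule = schedule, strengthFold = strengthFold,
                fdrTad = fdrTad, fdrInteraction = fdrInteraction,
                minOE = minOE, topQ = topQ, rcpDistance = rcpDistance,
                changedDistance = changedDistance, apaK = as.integer(apaK),
                seed = as.integer(seed))
    class(cfg) <- "pipelineConfig"
    validatePipelineConfig(cfg)
    cfg
}

#' Validate a pipeline configuration
#' @param cfg a pipelineConfig
#' @return invisibly TRUE; stops on an invalid configuration
#' @export
validatePipelineConfig <- function(cfg) {
    if (!inherits(cfg, "pipelineConfig")) stop("not a pipelineConfig")
    tps <- cfg$schedule$timepoints
    if (length(tps) < 2 || tps[1] != "0")
        stop("configuration error: timepoints must include the baseline ",
             "'0' first")
    if (tail(tps, 1) != "withdrawal")
        stop("configuration error: timepoints must end with 'withdrawal'")
    stopifnot(cfg$fdrTad > 0, cfg$fdrTad < 1,
              cfg$fdrInteraction > 0, cfg$fdrInteraction < 1,
              cfg$topQ > 0, cfg$topQ < 0.5, cfg$minOE >= 1,
              cfg$strengthFold > 1, cfg$nReplicates >= 2)
    invisible(TRUE)
}

write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full timecourse analysis pipeline
#'
#' Simulates the configured timecourse and runs every stage (depth
#' normalization, balancing, O/E, distance decay, compartments, TADs,
#' significant interactions, enrichment), writing tabular results and a
#' JSON reproducibility manifest to \code{outdir}. Identical configuration
#' and seed give byte-identical outputs and manifest hashes.
#'
#' @param cfg a \code{\link{pipelineConfig}}
#' @param outdir output directory (created if missing)
#' @param verbose log stage progress via \code{message}
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(cfg, outdir, verbose = TRUE) {
    validatePipelineConfig(cfg)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (verbose) message("[HiCflux] ", ...)
    tps <- cfg$schedule$timepoints
    baseTp <- tps[1]
    chromNames <- paste0("chr", seq_len(cfg$nChroms))
    perChrom <- list()

    for (cc in seq_len(cfg$nChroms)) {
        say("chromosome ", chromNames[cc], ": simulate")
        sc <- simConfig(nBins = cfg$nBins, binSize = cfg$binSize,
                        decayExponent = cfg$decayExponent,
                        compartmentAmplitude = cfg$compartmentAmplitude,
                        tadBoost = cfg$tadBoost, loopBoost = cfg$loopBoost,
                        depth = cfg$depth, nReplicates = cfg$nReplicates,
                        seed = cfg$seed * 1000L + cc)
        tc <- simulateTimecourse(sc, cfg$schedule,
                                 chromName = chromNames[cc])
        ## depth normalization across every replicate of every timepoint
        say("chromosome ", chromNames[cc], ": downsample + balance")
        flat <- unlist(lapply(tc, `[[`, "matrices"), recursive = FALSE)
        flat <- downsampleToMin(flat, seed = cfg$seed * 1000L + cc)
        k <- 0L
        stages <- list()
        baseTruth <- tc[[baseTp]]$truth
        orientation <- simulateSignalTrack(
            truthParams(baseTruth)$baselineProfile, enrichment = 1,
            noiseSd = 0.2, seed = cfg$seed * 1000L + cc + 1L,
            chrom = chromNames[cc], binSize = cfg$binSize)
        for (tp in tps) {
            k <- k + 1L
            reps <- flat[((k - 1L) * cfg$nReplicates + 1L):
                         (k * cfg$nReplicates)]
            merged <- mergeReplicates(reps)
            bal <- iceBalance(merged)
            oe <- oeTransform(bal)
            stages[[tp]] <- list(reps = reps, merged = merged, bal = bal,
                                 oe = oe, truth = tc[[tp]]$truth)
        }
        perChrom[[chromNames[cc]]] <- list(stages = stages,
                                           orientation = orientation,
                                           truth = baseTruth)
    }

    files <- character()
    addFile <- function(p) files <<- c(files, p)

    ## ---- distance decay -------------------------------------------------
    say("stage: distance decay (RCP, fold changes, changed fractions)")
    rcpTab <- data.frame()
    fcTab <- data.frame()
    cfTab <- data.frame()
    curves <- list()
    for (cn in names(perChrom)) {
        curves[[cn]] <- lapply(perChrom[[cn]]$stages,
                               function(s) rcp(s$bal))
        for (tp in tps)
            rcpTab <- rbind(rcpTab, data.frame(chrom = cn, timepoint = tp,
                curves[[cn]][[tp]]))
    }
    balReps0 <- lapply(perChrom, function(pc)
        lapply(pc$stages[[baseTp]]$reps, iceBalance))
    ## clamp the evaluation distances to what the chromosomes can support
    maxDist <- (cfg$nBins - 1) * cfg$binSize
    rcpDist <- min(cfg$rcpDistance, maxDist)
    chgDist <- min(cfg$changedDistance, maxDist)
    for (tp in setdiff(tps, baseTp)) {
        fc <- rcpFoldChange(lapply(curves, `[[`, tp),
                            lapply(curves, `[[`, baseTp),
                            rcpDist)
        fcTab <- rbind(fcTab, data.frame(timepoint = tp,
            distance = rcpDist, meanLog2FC = fc$mean, sd = fc$sd,
            p = fc$p))
        for (cn in names(perChrom)) {
            s <- perChrom[[cn]]$stages
            v <- changedFraction(s[[tp]]$bal, balReps0[[cn]],
                                 chgDist)
            cfTab <- rbind(cfTab, data.frame(chrom = cn, timepoint = tp,
                distance = chgDist, increased = v["increased"],
                decreased = v["decreased"], unchanged = v["unchanged"]))
        }
    }
    addFile(write_tsv(rcpTab, file.path(outdir, "rcp.tsv")))
    addFile(write_tsv(fcTab, file.path(outdir, "rcp_foldchange.tsv")))
    addFile(write_tsv(cfTab, file.path(outdir, "changed_fractions.tsv")))

    ## ---- compartments ---------------------------------------------------
    say("stage: compartments (PC1, strength, saddle, homogeneity, switch)")
    compTab <- data.frame()
    switchTab <- data.frame()
    strengthTab <- data.frame()
    for (cn in names(perChrom)) {
        s <- perChrom[[cn]]$stages
        profiles <- list()
        tadsets <- list()
        strength <- list()
        for (tp in tps) {
            prof <- computePC1(s[[tp]]$oe, perChrom[[cn]]$orientation,
                               timepoint = tp)
            tadsets[[tp]] <- callTADs(s[[tp]]$bal)
            profiles[[tp]] <- smoothByTADs(prof, tadsets[[tp]])
            strength[[tp]] <- perBinStrength(s[[tp]]$oe, profiles[[tp]])
            sad <- saddle(s[[tp]]$oe, profiles[[tp]])
            hom <- homogeneity(sameTypeGroupMeans(s[[tp]]$oe,
                                                  profiles[[tp]], "A"))
            regs <- compartmentRegions(profiles[[tp]])
            aStats <- regionSizeStats(regs, "A")
            compTab <- rbind(compTab, data.frame(chrom = cn,
                timepoint = tp, saddleScore = sad$score, homogeneityA = hom,
                meanASize = aStats$meanSize,
                totalALength = aStats$totalLength,
                eigenvalueFraction = profiles[[tp]]@eigenvalueFraction))
            if (tp != baseTp) {
                sc <- classifyStrengthChange(strength[[tp]],
                                             strength[[baseTp]],
                                             cfg$strengthFold)
                strengthTab <- rbind(strengthTab, data.frame(chrom = cn,
                    timepoint = tp,
                    strengthened = sc$proportions[["strengthened"]],
                    weakened = sc$proportions[["weakened"]],
                    unchanged = sc$proportions[["unchanged"]]))
            }
        }
        sw <- classifySwitch(profiles)
        switchTab <- rbind(switchTab, data.frame(chrom = cn,
            class = names(sw$proportions),
            proportion = as.numeric(sw$proportions)))
        perChrom[[cn]]$profiles <- profiles
        perChrom[[cn]]$tadsets <- tadsets
        if (cn == names(perChrom)[1]) {
            for (tp in tps)
                addFile(writeBedGraph(profiles[[tp]],
                    file.path(outdir, paste0("pc1_", cn, "_t", tp,
                                             ".bedGraph"))))
            addFile(writeBed(compartmentRegions(profiles[[baseTp]]),
                             file.path(outdir, paste0("compartments_", cn,
                                                      "_t0.bed"))))
        }
    }
    addFile(write_tsv(compTab, file.path(outdir, "compartments.tsv")))
    addFile(write_tsv(strengthTab,
                      file.path(outdir, "strength_changes.tsv")))
    addFile(write_tsv(switchTab, file.path(outdir, "switch_classes.tsv")))

    ## ---- TADs -----------------------------------------------------------
    say("stage: TADs (calling, differential boundaries, reorganization)")
    tadTab <- data.frame()
    eventTab <- data.frame()
    for (cn in names(perChrom)) {
        s <- perChrom[[cn]]$stages
        tt <- perChrom[[cn]]$tadsets
        di0 <- directionIndex(s[[baseTp]]$reps)
        for (tp in tps) {
            at <- ata(s[[tp]]$oe, tt[[tp]])
            tadTab <- rbind(tadTab, data.frame(chrom = cn, timepoint = tp,
                nDomains = nrow(domains(tt[[tp]])),
                intraTadMean = at$intraTadMean, ataBodyMean = at$bodyMean))
        }
        for (tp in intersect(c("2", "30"), tps)) {
            diT <- directionIndex(s[[tp]]$reps)
            ch <- testBoundaryChange(diT, di0,
                                     boundaries(tt[[baseTp]]),
                                     boundaries(tt[[tp]]),
                                     fdr = cfg$fdrTad, timepoint = tp)
            ev <- classifyReorganization(tt[[baseTp]], tt[[tp]], ch)
            if (nrow(ev$events))
                eventTab <- rbind(eventTab, data.frame(chrom = cn,
                    timepoint = tp, ev$events))
        }
    }
    addFile(write_tsv(tadTab, file.path(outdir, "tads.tsv")))
    addFile(write_tsv(eventTab, file.path(outdir, "tad_events.tsv")))

    ## ---- interactions ---------------------------------------------------
    say("stage: significant interactions and APA")
    callTab <- data.frame()
    apaTab <- data.frame()
    for (cn in names(perChrom)) {
        s <- perChrom[[cn]]$stages
        condTrack <- simulateSignalTrack(
            truthParams(perChrom[[cn]]$truth)$baselineProfile,
            enrichment = 2, noiseSd = 0.1,
            seed = cfg$seed * 1000L + match(cn, names(perChrom)) + 500L,
            chrom = cn, binSize = cfg$binSize)
        agg <- aggregateTADPairs(s[[baseTp]]$merged,
                                 perChrom[[cn]]$tadsets[[baseTp]])
        calls <- callSignificant(agg, cfg$fdrInteraction, cfg$minOE)
        calls <- classifyBySignal(calls, condTrack, cfg$topQ,
                                  seed = cfg$seed + 77L)
        ## all tested pairs are reported; calls are significant == TRUE rows
        callTab <- rbind(callTab, data.frame(chrom = cn, calls))
        anchors <- loopAnchors(perChrom[[cn]]$truth)
        isLong <- (anchors[, 2] - anchors[, 1]) >=
            truthParams(perChrom[[cn]]$stages[[baseTp]]$truth)$longRangeMinBins
        for (tp in tps) {
            for (grp in c("long", "short")) {
                sel <- if (grp == "long") isLong else !isLong
                if (!any(sel)) next
                ap <- apa(s[[tp]]$oe, anchors[sel, , drop = FALSE],
                          k = cfg$apaK)
                apaTab <- rbind(apaTab, data.frame(chrom = cn,
                    timepoint = tp, anchorSet = grp,
                    centerScore = ap$centerScore,
                    cornerMean = ap$cornerMean, n = ap$n))
            }
        }
    }
    addFile(write_tsv(callTab, file.path(outdir, "interaction_calls.tsv")))
    addFile(write_tsv(apaTab, file.path(outdir, "apa.tsv")))

    ## ---- enrichment -----------------------------------------------------
    say("stage: signal enrichment statistics")
    enrTab <- data.frame()
    for (cn in names(perChrom)) {
        condTrack <- simulateSignalTrack(
            truthParams(perChrom[[cn]]$truth)$baselineProfile,
            enrichment = 2, noiseSd = 0.1,
            seed = cfg$seed * 1000L + match(cn, names(perChrom)) + 500L,
            chrom = cn, binSize = cfg$binSize)
        regs <- compartmentRegions(perChrom[[cn]]$profiles[[baseTp]])
        aRegs <- regs[regs$label == "A"]
        enrTab <- rbind(enrTab, data.frame(chrom = cn, regionSet = "A",
            foldEnrichment = foldEnrichment(condTrack, aRegs),
            spearmanRho = pseudoClusterCorrelation(condTrack, aRegs),
            ranksumP = regionVsRestTest(condTrack, aRegs)))
    }
    addFile(write_tsv(enrTab, file.path(outdir, "enrichment.tsv")))

    ## ---- manifest -------------------------------------------------------
    say("stage: manifest")
    files <- sort(unique(files))
    manifest <- list(
        package = "HiCflux",
        seed = cfg$seed,
        sizes = list(nChroms = cfg$nChroms, nBins = cfg$nBins,
                     binSize = cfg$binSize, depth = cfg$depth,
                     nReplicates = cfg$nReplicates),
        thresholds = list(strengthFold = cfg$strengthFold,
                          fdrTad = cfg$fdrTad,
                          fdrInteraction = cfg$fdrInteraction,
                          minOE = cfg$minOE, topQ = cfg$topQ,
                          rcpDistance = cfg$rcpDistance,
                          changedDistance = cfg$changedDistance,
                          apaK = cfg$apaK),
        timepoints = tps,
        files = lapply(files, function(f)
            list(name = basename(f), md5 = unname(md5sum(f)))))
    manifestPath <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    say("done: ", length(files), " result files in ", outdir)
    invisible(manifest)
}
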