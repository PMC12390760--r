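#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline with its documented default.
#' Unknown keys in a user configuration are rejected by [runPipeline()].
#'
#' @return nested list of parameter blocks.
#' @export
defaultConfig <- function() {
    list(
        seed = 1L,
        outdir = "chimeRclip-run",
        genome = list(nChroms = 6L, nGenes = 840L, nMirnas = 12L,
                      nFamilies = 4L, chromLength = 400000L),
        sim = list(nReadsIP = 50000L, nReadsInput = 50000L,
                   chimeraFraction = 0.02, backgroundFraction = 0.30,
                   repeatFraction = 0.05, pcrDuplicationRate = 0.10,
                   seqErrorRate = 0.001, umiLength = 10L,
                   adapter = "AGATCGGAAGAGCACACGTCT", readLength = 75L,
                   fractions = c("cytoplasm", "nucleus", "chromatin"),
                   replicates = 2L, nSiteGenes = 10L),
        preprocess = list(minOverlap = 3L, maxMismatchRate = 0.1,
                          minLength = 18L, delim = "_"),
        align = list(k = 16L, maxMismatches = 2L),
        chimera = list(minMirnaMatch = 18L, maxMismatches = 1L,
                       minTargetLength = 18L),
        quant = list(minReads = 3L, minLog2fc = 3),
        families = list(allowlistOnly = TRUE, topN = 8L),
        prioritize = list(minAbsLog2fc = 1, strictGt5 = TRUE),
        expressionTable = NULL
    )
}

## Merge a user config into the defaults, rejecting unknown keys.
mergeConfig <- function(user, defaults = defaultConfig(), path = "") {
    if (is.null(user)) return(defaults)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste0(path, unknown, collapse = ", "))
    for (nm in names(user)) {
        if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
            defaults[[nm]] <- mergeConfig(user[[nm]], defaults[[nm]],
                                          paste0(path, nm, "$"))
        } else {
            defaults[[nm]] <- user[[nm]]
        }
    }
    defaults
}

#' Read a run configuration from a YAML file
#' @param path YAML file with any subset of the [defaultConfig()] keys.
#' @return the resolved configuration (defaults filled in).
#' @export
readRunConfig <- function(path) {
    mergeConfig(yaml::read_yaml(path))
}

libLabel <- function(fraction, replicate, role)
    sprintf("%s_rep%d_%s", fraction, replicate, role)

#' Write aligned fragments as BED plus a metadata TSV
#'
#' The pipeline's interchange format: a 6-column BED (0-based half-open,
#' name = read id, score = mismatch count) and a TSV sidecar with
#' \code{read_id}, \code{umi}, \code{sample}, \code{role},
#' \code{replicate}, \code{mirna_tag}, \code{mismatches}.
#'
#' @param fragments fragments \code{GRanges}.
#' @param prefix output path prefix (writes \code{<prefix>.bed} and
#'   \code{<prefix>.meta.tsv}).
#' @return invisibly, the two paths.
#' @export
writeFragments <- function(fragments, prefix) {
    mc <- S4Vectors::mcols(fragments)
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(fragments)),
                      start = GenomicRanges::start(fragments) - 1L,
                      end = GenomicRanges::end(fragments),
                      name = mc$read_id, score = mc$mismatches,
                      strand = as.character(GenomicRanges::strand(fragments)))
    bedPath <- paste0(prefix, ".bed")
    metaPath <- paste0(prefix, ".meta.tsv")
    write.table(bed, bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(as.data.frame(mc), metaPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(bed = bedPath, meta = metaPath))
}

#' Read fragments back from the BED + TSV interchange
#' @param prefix path prefix used by [writeFragments()].
#' @return fragments \code{GRanges}.
#' @export
readFragments <- function(prefix) {
    bedPath <- paste0(prefix, ".bed")
    if (file.size(bedPath) == 0L) return(emptyFragments())
    bed <- read.table(bedPath, sep = "\t",
                      col.names = c("chrom", "start", "end", "name",
                                    "score", "strand"),
                      colClasses = c("character", "integer", "integer",
                                     "character", "integer", "character"))
    meta <- read.table(paste0(prefix, ".meta.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(bed$chrom,
        IRanges::IRanges(bed$start + 1L, bed$end), strand = bed$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
    gr
}

## Final peaks GRanges -> flat data.frame (0-based half-open, tallies
## serialized as name:count;...).
peaksToDf <- function(gr, sample, peak_type) {
    mc <- S4Vectors::mcols(gr)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               sample = rep(sample, length(gr)),
               peak_type = rep(peak_type, length(gr)),
               ip_count = mc$ip_count, input_count = mc$input_count,
               ip_rpm = mc$ip_rpm, log2fc = mc$log2fc,
               p_value = mc$p_value,
               reproducible = mc$reproducible,
               annotation = mc$annotation, gene_id = mc$gene_id,
               mirna_counts = vapply(mc$mirna_counts, formatTally,
                                     character(1)))
}

#' Run the complete simulated chimeric eCLIP pipeline
#'
#' Orchestrates simulate, preprocess, repeat filtering, genome mapping,
#' chimera detection and resolution, UMI deduplication, allowlisting,
#' cluster calling, enrichment scoring, reproducibility filtering,
#' annotation, family summaries and candidate prioritization, with a
#' per-stage read accounting ledger. Deterministic for a fixed seed; all
#' intermediates are persisted under \code{outdir} so any downstream stage
#' can be re-run from files.
#'
#' @param config a (possibly partial) configuration list or the path to a
#'   YAML file; see [defaultConfig()].
#' @return invisibly, a list of class \code{eclipRun} carrying the bundle,
#'   simulation truth, per-library fragments, final peaks (GRanges and flat
#'   table), feature distribution, family summaries, candidate table,
#'   accounting ledger and output paths.
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- mergeConfig(config)
    outdir <- cfg$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    ## ---- simulate ----
    bundle <- makeGenome(nChroms = cfg$genome$nChroms,
                         nGenes = cfg$genome$nGenes,
                         nMirnas = cfg$genome$nMirnas,
                         nFamilies = cfg$genome$nFamilies,
                         seed = cfg$seed,
                         chromLength = cfg$genome$chromLength,
                         dir = file.path(outdir, "genome"))
    siteMap <- defaultSiteMap(bundle, cfg$sim$nSiteGenes)
    simArgs <- cfg$sim[setdiff(names(cfg$sim), "nSiteGenes")]
    params <- do.call(simParams, c(list(seed = cfg$seed, siteMap = siteMap),
                                   simArgs))
    sim <- simulateLibraries(bundle, params, file.path(outdir, "fastq"))

    mi <- as.data.frame(mirnaTable(bundle))
    features <- buildFeatureRanges(bundle)
    genomeIndex <- buildSeedIndex(chromosomes(bundle), cfg$align$k)
    repeatIndex <- buildSeedIndex(repeatSequences(bundle), cfg$align$k)
    allowNames <- if (isTRUE(cfg$families$allowlistOnly))
        mi$name[mi$allowlisted] else character(0)

    fragDir <- file.path(outdir, "fragments")
    dir.create(fragDir, showWarnings = FALSE)
    ledger <- list()
    note <- function(library, stage, n_in, n_kept, n_dropped) {
        ledger[[length(ledger) + 1L]] <<- data.frame(
            library = library, stage = stage,
            n_in = as.integer(unname(n_in)),
            n_kept = as.integer(unname(n_kept)),
            n_dropped = as.integer(unname(n_dropped)))
    }

    fragments <- list(); totals <- list()
    for (i in seq_len(nrow(sim$files))) {
        fraction <- sim$files$fraction[i]
        repl <- sim$files$replicate[i]
        role <- sim$files$role[i]
        lab <- libLabel(fraction, repl, role)

        raw <- readFastqReads(sim$files$path[i])
        pp <- preprocessReads(raw, umiLength = cfg$sim$umiLength,
                              delim = cfg$preprocess$delim,
                              adapter = cfg$sim$adapter,
                              minOverlap = cfg$preprocess$minOverlap,
                              maxMismatchRate = cfg$preprocess$maxMismatchRate,
                              minLength = cfg$preprocess$minLength)
        note(lab, "preprocess", pp$log["n_in"], pp$log["kept"],
             pp$log["dropped_no_umi"] + pp$log["dropped_short"])

        rf <- filterRepeats(pp$reads, repeatIndex, cfg$align$maxMismatches)
        note(lab, "repeat_filter", rf$log["n_in"], rf$log["kept"],
             rf$log["dropped_repeat"])

        gm <- mapReads(genomeIndex, rf$kept$sequence,
                       cfg$align$maxMismatches)
        uni <- gm$status == "unique"
        unm <- gm$status == "unmapped"
        ## unmapped reads are routed to chimera detection, hence kept here
        note(lab, "genome_map", nrow(rf$kept), sum(uni) + sum(unm),
             sum(gm$status == "multi"))

        meta <- data.frame(read_id = rf$kept$read_id, umi = rf$kept$umi,
                           sample = fraction, role = role,
                           replicate = repl)
        nonchim <- GenomicRanges::GRanges(
            gm$chrom[uni],
            IRanges::IRanges(gm$start[uni] + 1L, gm$end[uni]),
            strand = gm$strand[uni],
            read_id = meta$read_id[uni], umi = meta$umi[uni],
            sample = fraction, role = role, replicate = repl,
            mirna_tag = NA_character_, mismatches = gm$mismatches[uni])

        det <- detectChimeras(rf$kept$sequence[unm], mi,
                              cfg$chimera$minMirnaMatch,
                              cfg$chimera$maxMismatches,
                              cfg$chimera$minTargetLength)
        note(lab, "chimera_detect", det$log["n_in"], det$log["called"],
             det$log["no_call"] + det$log["mirna_only"] +
                 det$log["short_target"])
        res <- resolveChimeras(det$calls, genomeIndex,
                               meta[unm, , drop = FALSE],
                               cfg$align$maxMismatches)
        note(lab, "chimera_resolve", res$log["n_in"], res$log["kept"],
             res$log["dropped_multi"] + res$log["dropped_unmapped"])

        dnc <- deduplicateFragments(nonchim)
        note(lab, "dedup_nonchimeric", length(nonchim), length(dnc),
             attr(dnc, "removed"))
        dch <- deduplicateFragments(res$fragments)
        note(lab, "dedup_chimeric", length(res$fragments), length(dch),
             attr(dch, "removed"))

        al <- applyAllowlist(dch, allowNames)
        note(lab, "allowlist", length(dch), length(al$fragments),
             al$removed)

        writeFragments(dnc, file.path(fragDir, paste0(lab, "_nonchimeric")))
        writeFragments(al$fragments,
                       file.path(fragDir, paste0(lab, "_chimeric")))
        fragments[[lab]] <- list(nonchimeric = dnc, chimeric = dch,
                                 chimericAllowed = al$fragments)
        totals[[lab]] <- length(dnc) + length(dch)
    }

    ## ---- peaks per fraction ----
    peakList <- list(); peakDfs <- list()
    for (fraction in cfg$sim$fractions) {
        ip1 <- fragments[[libLabel(fraction, 1L, "IP")]]
        ip2 <- fragments[[libLabel(fraction, 2L, "IP")]]
        in1 <- fragments[[libLabel(fraction, 1L, "input")]]
        in2 <- fragments[[libLabel(fraction, 2L, "input")]]
        t1 <- totals[[libLabel(fraction, 1L, "IP")]]
        t2 <- totals[[libLabel(fraction, 2L, "IP")]]
        it1 <- totals[[libLabel(fraction, 1L, "input")]]
        it2 <- totals[[libLabel(fraction, 2L, "input")]]
        for (type in c("nonchimeric", "chimeric")) {
            f1 <- if (type == "nonchimeric") ip1$nonchimeric else
                ip1$chimericAllowed
            f2 <- if (type == "nonchimeric") ip2$nonchimeric else
                ip2$chimericAllowed
            s1 <- scorePeaks(callClusters(f1), t1, in1$nonchimeric, it1)
            s2 <- scorePeaks(callClusters(f2), t2, in2$nonchimeric, it2)
            fin <- filterReproduciblePeaks(s1, s2, cfg$quant$minReads,
                                           cfg$quant$minLog2fc)
            S4Vectors::mcols(fin)$ip_rpm <-
                S4Vectors::mcols(fin)$ip_count / (t1 + t2) * 1e6
            fin <- annotatePeaks(fin, features)
            peakList[[paste(fraction, type, sep = ".")]] <- fin
            peakDfs[[length(peakDfs) + 1L]] <-
                peaksToDf(fin, fraction, type)
        }
    }
    peaksDf <- do.call(rbind, peakDfs)
    write.table(peaksDf, file.path(outdir, "final_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    distribution <- featureDistribution(peaksDf)
    write.table(distribution, file.path(outdir, "feature_distribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    ## ---- family summaries over pooled IP replicates per fraction ----
    famList <- list()
    for (fraction in cfg$sim$fractions) {
        pooled <- c(fragments[[libLabel(fraction, 1L, "IP")]]$chimericAllowed,
                    fragments[[libLabel(fraction, 2L, "IP")]]$chimericAllowed)
        if (length(pooled) == 0L) {
            famList[[fraction]] <- data.frame()
            next
        }
        fs <- familyFractions(pooled, mi, cfg$families$topN)
        if (nrow(fs)) {
            cum <- attr(fs, "cumulative_top_n")
            fs <- cbind(data.frame(fraction = fraction), fs)
            attr(fs, "cumulative_top_n") <- cum
        }
        famList[[fraction]] <- fs
    }
    famDf <- do.call(rbind, famList[vapply(famList, nrow, integer(1)) > 0])
    if (!is.null(famDf))
        write.table(famDf, file.path(outdir, "family_summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)

    ## ---- prioritization ----
    expression <- if (is.null(cfg$expressionTable)) {
        simulateExpressionTable(bundle, siteMap, cfg$seed)
    } else if (is.character(cfg$expressionTable)) {
        read.table(cfg$expressionTable, sep = "\t", header = TRUE)
    } else as.data.frame(cfg$expressionTable)
    write.table(expression, file.path(outdir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- countUtr3ChimericPeaks(peaksDf, cfg$sim$fractions)
    candidates <- selectCandidates(counts, expression,
                                   cfg$prioritize$minAbsLog2fc,
                                   cfg$sim$fractions,
                                   cfg$prioritize$strictGt5)
    write.table(candidates, file.path(outdir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    accounting <- do.call(rbind, ledger)
    rownames(accounting) <- NULL
    write.table(accounting, file.path(outdir, "accounting.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfgEcho <- cfg
    cfgEcho$package_version <- as.character(utils::packageVersion("chimeRclip"))
    jsonlite::write_json(cfgEcho, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    out <- list(config = cfg, bundle = bundle, siteMap = siteMap,
                sim = sim, truth = sim$truth, fragments = fragments,
                totals = totals, peaks = peakList, peaksDf = peaksDf,
                distribution = distribution, familySummaries = famList,
                expression = expression, counts = counts,
                candidates = candidates, accounting = accounting,
                outdir = outdir)
    class(out) <- "eclipRun"
    invisible(out)
}

#' @export
print.eclipRun <- function(x, ...) {
    cat("chimeRclip pipeline run\n")
    cat(sprintf("  %d librar(ies), %d final peak(s), %d candidate gene(s)\n",
                nrow(x$sim$files), nrow(x$peaksDf),
                sum(x$candidates$selected)))
    cat(sprintf("  output: %s\n", x$outdir))
    invisible(x)
}

#' Evaluate chimera recovery against the simulation truth
#'
#' Compares the pipeline's deduplicated chimeric fragments with the planted
#' ground truth: which (miRNA family, target gene) pairs were recovered,
#' and whether any fragment was assigned to a different seed family than
#' the truth (cross-family misassignment). A planted pair is eligible when
#' at least one of its reads carries a target fragment of at least
#' \code{minTargetLength} nt.
#'
#' @param run an \code{eclipRun} from [runPipeline()], or a list of
#'   per-library fragment sets shaped like \code{run$fragments}.
#' @param truth,bundle,siteMap overridden when \code{run} is not an
#'   \code{eclipRun}.
#' @param minTargetLength eligibility threshold for planted reads.
#' @param delim UMI delimiter used during preprocessing.
#' @return list with \code{nPlanted}, \code{nEligible}, \code{nRecovered},
#'   \code{recoveryPct}, \code{crossFamilyMisassignments} and \code{pairs}
#'   (per-pair detail).
#' @export
chimeraRecovery <- function(run, truth = run$truth, bundle = run$bundle,
                            siteMap = run$siteMap, minTargetLength = 18L,
                            delim = "_") {
    mi <- as.data.frame(mirnaTable(bundle))
    famOf <- setNames(mi$family_id, mi$name)
    planted <- unique(data.frame(
        family = unname(famOf[siteMap$mirna[!is.na(siteMap$mirna)]]),
        gene_id = siteMap$gene_id[!is.na(siteMap$mirna)]))
    tChim <- truth[truth$read_class == "chimeric", , drop = FALSE]
    tChim$family <- unname(famOf[tChim$mirna])
    tChim$eligible <- tChim$end - tChim$start >= minTargetLength
    eligPairs <- unique(tChim[tChim$eligible, c("family", "gene_id")])

    frags <- if (inherits(run, "eclipRun")) run$fragments else run
    allChim <- do.call(c, unname(lapply(frags, `[[`, "chimeric")))
    tags <- S4Vectors::mcols(allChim)$mirna_tag
    obsFam <- unname(famOf[tags])

    ## gene assignment by same-strand overlap with the gene body
    ex <- exonRanges(bundle)
    spans <- unlist(range(S4Vectors::split(ex,
                                           S4Vectors::mcols(ex)$gene_id)))
    hits <- GenomicRanges::findOverlaps(allChim, spans,
                                        ignore.strand = FALSE)
    obs <- unique(data.frame(
        family = obsFam[S4Vectors::queryHits(hits)],
        gene_id = names(spans)[S4Vectors::subjectHits(hits)]))

    key <- function(df) paste(df$family, df$gene_id)
    recovered <- key(eligPairs) %in% key(obs)

    ## per-read family comparison against truth
    base <- stripUmiSuffix(S4Vectors::mcols(allChim)$read_id, delim)
    tFam <- setNames(tChim$family, tChim$read_id)
    known <- base %in% names(tFam)
    mis <- sum(obsFam[known] != tFam[base[known]])

    list(nPlanted = nrow(planted), nEligible = nrow(eligPairs),
         nRecovered = sum(recovered),
         recoveryPct = 100 * sum(recovered) / max(1L, nrow(eligPairs)),
         crossFamilyMisassignments = mis,
         pairs = cbind(eligPairs, recovered = recovered))
}
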