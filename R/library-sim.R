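#' Simulation parameters for chimeric eCLIP libraries
#'
#' Bundles every knob of the library simulator with validation. Defaults
#' describe a typical desk-scale run: single-end reads of 75 nt carrying a
#' 10 nt UMI at the 5' end, a 3' sequencing adapter, 2% of IP reads chimeric,
#' a size-matched input sequenced to the same depth as the IP but drawn from
#' transcriptome background only (no AGO2-site enrichment), PCR duplication
#' re-emitting a molecule's UMI+insert with independent sequencing errors.
#'
#' @param seed integer RNG seed; all draws flow from one stream seeded once.
#' @param nReadsIP,nReadsInput reads per library (per fraction and replicate).
#' @param chimeraFraction proportion of IP reads that are chimeric.
#' @param backgroundFraction proportion of IP reads drawn uniformly from the
#'   transcriptome.
#' @param repeatFraction proportion of IP reads drawn from repeat intervals.
#'   The remainder (1 - chimera - background - repeat) are nonchimeric reads
#'   from planted AGO2 sites.
#' @param pcrDuplicationRate proportion of reads that are PCR duplicates.
#' @param seqErrorRate per-base substitution probability.
#' @param umiLength UMI length in nt (first bases of the read).
#' @param adapter 3' adapter sequence.
#' @param readLength read length in nt.
#' @param fractions subcellular fraction labels to simulate.
#' @param replicates replicates per fraction.
#' @param siteMap data.frame of planted binding sites with columns
#'   \code{gene_id}, \code{region} (feature category, e.g. "UTR3"),
#'   \code{start}, \code{end} (0-based half-open genomic coordinates),
#'   \code{mirna} (name or NA for nonchimeric sites), \code{weight}.
#' @param minFragment,maxFragment nonchimeric insert length range (nt).
#' @param minTargetFragment,maxTargetFragment chimeric target fragment
#'   length range (nt).
#' @return a validated list of class \code{SimParams}.
#' @export
simParams <- function(seed = 1L, nReadsIP = 50000L, nReadsInput = nReadsIP,
                      chimeraFraction = 0.02, backgroundFraction = 0.30,
                      repeatFraction = 0.05, pcrDuplicationRate = 0.10,
                      seqErrorRate = 0.001, umiLength = 10L,
                      adapter = "AGATCGGAAGAGCACACGTCT", readLength = 75L,
                      fractions = c("cytoplasm", "nucleus", "chromatin"),
                      replicates = 2L, siteMap = NULL,
                      minFragment = 30L, maxFragment = 50L,
                      minTargetFragment = 18L, maxTargetFragment = 38L) {
    p <- as.list(environment())
    props <- c(chimeraFraction, backgroundFraction, repeatFraction,
               pcrDuplicationRate, seqErrorRate)
    if (any(props < 0 | props > 1))
        stop("all proportions must lie in [0, 1]")
    if (chimeraFraction + backgroundFraction + repeatFraction > 1)
        stop("read-class proportions must sum to at most 1")
    if (readLength <= umiLength + 18L)
        stop("readLength must exceed umiLength + minimum insert (18 nt)")
    if (nchar(adapter) < 3L) stop("adapter must be at least 3 nt")
    if (!is.null(siteMap)) {
        need <- c("gene_id", "region", "start", "end", "mirna", "weight")
        if (!all(need %in% colnames(siteMap)))
            stop("siteMap must have columns ",
                 paste(need, collapse = ", "))
    }
    class(p) <- "SimParams"
    p
}

#' Default planted-site map: chimeric and nonchimeric sites in 3' UTRs
#'
#' Places one chimeric site (with a miRNA drawn cyclically from the
#' allowlisted miRNAs, sorted by name) and one disjoint nonchimeric site in
#' the 3' UTR of each of the first \code{nSiteGenes} coding genes.
#'
#' @param bundle a [GenomeBundle-class].
#' @param nSiteGenes number of coding genes to plant sites in.
#' @param siteWidth site width in nt.
#' @return a siteMap data.frame (see [simParams()]).
#' @export
defaultSiteMap <- function(bundle, nSiteGenes = 10L, siteWidth = 60L) {
    feats <- buildFeatureRanges(bundle)
    utr3 <- feats[S4Vectors::mcols(feats)$category == "UTR3"]
    genes <- sort(unique(S4Vectors::mcols(utr3)$gene_id))
    if (length(genes) < nSiteGenes)
        stop(sprintf("only %d coding genes with a 3' UTR available, %d asked",
                     length(genes), nSiteGenes))
    genes <- genes[seq_len(nSiteGenes)]
    mi <- as.data.frame(mirnaTable(bundle))
    mi <- mi[mi$allowlisted, , drop = FALSE]
    mi <- mi[order(mi$name), , drop = FALSE]
    if (!nrow(mi)) stop("no allowlisted miRNAs in the bundle")
    rows <- lapply(seq_along(genes), function(i) {
        u <- utr3[S4Vectors::mcols(utr3)$gene_id == genes[i]][1]
        s0 <- GenomicRanges::start(u) - 1L   # 0-based
        e0 <- GenomicRanges::end(u)
        if (e0 - s0 < 2L * siteWidth + 70L)
            stop("3' UTR too short to host two disjoint sites")
        ## the nonchimeric site sits at the transcript's 3'-terminal end of
        ## the UTR (away from the CDS) so occupancy clusters stay inside
        ## the UTR; the chimeric site takes the CDS-proximal end
        lowSite <- c(s0 + 5L, s0 + 5L + siteWidth)
        highSite <- c(e0 - 5L - siteWidth, e0 - 5L)
        minus <- as.character(GenomicRanges::strand(u)) == "-"
        chim <- if (minus) highSite else lowSite
        plain <- if (minus) lowSite else highSite
        rbind(
            data.frame(gene_id = genes[i], region = "UTR3",
                       start = chim[1L], end = chim[2L],
                       mirna = mi$name[(i - 1L) %% nrow(mi) + 1L],
                       weight = 1),
            data.frame(gene_id = genes[i], region = "UTR3",
                       start = plain[1L], end = plain[2L],
                       mirna = NA_character_, weight = 1))
    })
    do.call(rbind, rows)
}

## Resolve and validate a site map against a bundle: genomic containment in
## the named region of the named gene, miRNA names, minimum width; attaches
## chrom/strand/host-exon bounds.
resolveSiteMap <- function(bundle, siteMap, minTargetFragment) {
    feats <- buildFeatureRanges(bundle)
    ti <- as.data.frame(transcriptInfo(bundle))
    mi <- as.data.frame(mirnaTable(bundle))
    ex <- exonRanges(bundle)
    sm <- siteMap
    sm$chrom <- ti$chrom[match(sm$gene_id, ti$gene_id)]
    sm$strand <- ti$strand[match(sm$gene_id, ti$gene_id)]
    if (anyNA(sm$chrom)) stop("siteMap names unknown gene(s)")
    bad <- !is.na(sm$mirna) & !(sm$mirna %in% mi$name)
    if (any(bad)) stop("siteMap names unknown miRNA(s): ",
                       paste(unique(sm$mirna[bad]), collapse = ", "))
    if (any(sm$end - sm$start < minTargetFragment))
        stop("site interval shorter than the minimum fragment length (",
             minTargetFragment, " nt)")
    fm <- S4Vectors::mcols(feats)
    for (i in seq_len(nrow(sm))) {
        reg <- feats[fm$gene_id == sm$gene_id[i] &
                     fm$category == sm$region[i]]
        site <- GenomicRanges::GRanges(sm$chrom[i],
            IRanges::IRanges(sm$start[i] + 1L, sm$end[i]),
            strand = sm$strand[i])
        cov <- GenomicRanges::intersect(reg, site, ignore.strand = TRUE)
        if (sum(GenomicRanges::width(cov)) < GenomicRanges::width(site))
            stop(sprintf("site %d not contained in %s of %s",
                         i, sm$region[i], sm$gene_id[i]))
    }
    ## host exon per site (sites must sit inside one exon: unspliced reads)
    siteGr <- GenomicRanges::GRanges(sm$chrom,
        IRanges::IRanges(sm$start + 1L, sm$end), strand = sm$strand)
    hit <- GenomicRanges::findOverlaps(siteGr, ex, type = "within")
    first <- !duplicated(S4Vectors::queryHits(hit))
    if (length(unique(S4Vectors::queryHits(hit))) < nrow(sm))
        stop("every site must lie within a single exon")
    exIdx <- S4Vectors::subjectHits(hit)[first]
    sm$exStart <- GenomicRanges::start(ex)[exIdx] - 1L
    sm$exEnd <- GenomicRanges::end(ex)[exIdx]
    sm$mirnaSeq <- mi$sequence[match(sm$mirna, mi$name)]
    sm
}

#' Simulate paired IP and size-matched input FASTQ libraries
#'
#' For every fraction and replicate, writes an IP and an input FASTQ
#' (4-line records, Phred+33, constant quality) plus a single truth TSV
#' covering every read. IP reads are a mixture of chimeric reads (full
#' mature miRNA at the 5' end of the insert, ligated to a target fragment
#' drawn from a planted site), nonchimeric site reads, transcriptome
#' background and repeat-derived reads; input reads are background only.
#' Each read is UMI + insert + (possibly partial) 3' adapter, truncated to
#' the read length; PCR duplicates re-emit an existing molecule's UMI and
#' insert with independent sequencing errors. Deterministic for a fixed
#' seed: outputs are byte-identical across runs.
#'
#' @param bundle a [GenomeBundle-class].
#' @param params a [simParams()] object; \code{params$siteMap} must be set
#'   when site-derived or chimeric reads are requested.
#' @param dir output directory for FASTQ and truth files.
#' @return invisibly, a list of class \code{eclipSim} with elements
#'   \code{files} (data.frame fraction/replicate/role/path), \code{truth}
#'   (data.frame, one row per read; coordinates 0-based half-open),
#'   \code{params}, \code{dir}.
#' @export
simulateLibraries <- function(bundle, params, dir) {
    stopifnot(inherits(params, "SimParams"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(params$seed)

    cf <- params$chimeraFraction; bf <- params$backgroundFraction
    rf <- params$repeatFraction
    sf <- 1 - cf - bf - rf
    sm <- NULL
    if (cf > 0 || sf > 0) {
        if (is.null(params$siteMap))
            stop("siteMap required when site or chimeric reads are requested")
        sm <- resolveSiteMap(bundle, params$siteMap, params$minTargetFragment)
    }
    chimSites <- sm[!is.na(sm$mirna), , drop = FALSE]
    plainSites <- sm[is.na(sm$mirna), , drop = FALSE]
    if (cf > 0 && (is.null(chimSites) || nrow(chimSites) == 0L))
        stop("chimeraFraction > 0 but siteMap assigns no miRNA to any site")
    if (sf > 0 && (is.null(plainSites) || nrow(plainSites) == 0L))
        stop("nonchimeric site reads requested but siteMap has no ",
             "miRNA-free sites")
    maxMirnaLen <- if (!is.null(chimSites) && nrow(chimSites))
        max(nchar(chimSites$mirnaSeq)) else 0L
    maxInsert <- max(params$maxFragment, maxMirnaLen + params$maxTargetFragment)
    if (params$umiLength + maxInsert + 3L > params$readLength)
        stop("readLength too short: UMI + largest insert + 3 nt of adapter ",
             "must fit (", params$umiLength + maxInsert + 3L, " > ",
             params$readLength, ")")

    chromStrs <- as.character(chromosomes(bundle))
    ex <- exonRanges(bundle)
    bgEx <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                       start = GenomicRanges::start(ex) - 1L,
                       end = GenomicRanges::end(ex),
                       strand = as.character(GenomicRanges::strand(ex)),
                       gene_id = S4Vectors::mcols(ex)$gene_id)
    bgEx$width <- bgEx$end - bgEx$start
    rp <- repeatRanges(bundle)
    rpDf <- data.frame(chrom = as.character(GenomicRanges::seqnames(rp)),
                       start = GenomicRanges::start(rp) - 1L,
                       end = GenomicRanges::end(rp))
    rpDf$width <- rpDf$end - rpDf$start

    extractSeq <- function(chrom, start0, end0, strand) {
        s <- substring(chromStrs[chrom], start0 + 1L, end0)
        if (any(strand == "-")) s[strand == "-"] <- revComp(s[strand == "-"])
        s
    }
    adapterPad <- paste0(params$adapter, strrep("A", params$readLength))
    qual <- strrep("I", params$readLength)

    genLibrary <- function(fraction, repl, role) {
        n <- if (role == "IP") params$nReadsIP else params$nReadsInput
        nU <- max(1L, round(n * (1 - params$pcrDuplicationRate)))
        nDup <- n - nU
        cls <- if (role == "IP") {
            sample(c("chimeric", "nonchimeric_site", "background", "repeat"),
                   nU, replace = TRUE, prob = c(cf, sf, bf, rf))
        } else rep("background", nU)

        chrom <- character(nU); start <- integer(nU); end <- integer(nU)
        strand <- character(nU); gene <- rep(NA_character_, nU)
        region <- rep(NA_character_, nU); mirna <- rep(NA_character_, nU)
        mirPrefix <- character(nU)

        i <- which(cls == "chimeric")
        if (length(i)) {
            r <- sample.int(nrow(chimSites), length(i), replace = TRUE,
                            prob = chimSites$weight)
            len <- sample(params$minTargetFragment:params$maxTargetFragment,
                          length(i), replace = TRUE)
            lo <- chimSites$start[r]
            hi <- chimSites$end[r] - len
            start[i] <- lo + floor(runif(length(i)) * (hi - lo + 1L))
            end[i] <- start[i] + len
            chrom[i] <- chimSites$chrom[r]; strand[i] <- chimSites$strand[r]
            gene[i] <- chimSites$gene_id[r]; region[i] <- chimSites$region[r]
            mirna[i] <- chimSites$mirna[r]
            mirPrefix[i] <- chimSites$mirnaSeq[r]
        }
        i <- which(cls == "nonchimeric_site")
        if (length(i)) {
            r <- sample.int(nrow(plainSites), length(i), replace = TRUE,
                            prob = plainSites$weight)
            len <- sample(params$minFragment:params$maxFragment,
                          length(i), replace = TRUE)
            lo <- pmax(plainSites$start[r] - 10L, plainSites$exStart[r])
            hi <- pmin(plainSites$end[r] + 10L, plainSites$exEnd[r]) - len
            hi <- pmax(hi, lo)
            start[i] <- lo + floor(runif(length(i)) * (hi - lo + 1L))
            end[i] <- start[i] + len
            chrom[i] <- plainSites$chrom[r]; strand[i] <- plainSites$strand[r]
            gene[i] <- plainSites$gene_id[r]
            region[i] <- plainSites$region[r]
        }
        i <- which(cls == "background")
        if (length(i)) {
            r <- sample.int(nrow(bgEx), length(i), replace = TRUE,
                            prob = bgEx$width)
            len <- pmin(sample(params$minFragment:params$maxFragment,
                               length(i), replace = TRUE), bgEx$width[r])
            start[i] <- bgEx$start[r] +
                floor(runif(length(i)) * (bgEx$width[r] - len + 1L))
            end[i] <- start[i] + len
            chrom[i] <- bgEx$chrom[r]; strand[i] <- bgEx$strand[r]
            gene[i] <- bgEx$gene_id[r]
        }
        i <- which(cls == "repeat")
        if (length(i)) {
            r <- sample.int(nrow(rpDf), length(i), replace = TRUE,
                            prob = rpDf$width)
            len <- pmin(sample(params$minFragment:params$maxFragment,
                               length(i), replace = TRUE), rpDf$width[r])
            start[i] <- rpDf$start[r] +
                floor(runif(length(i)) * (rpDf$width[r] - len + 1L))
            end[i] <- start[i] + len
            chrom[i] <- rpDf$chrom[r]; strand[i] <- "+"
        }

        insert <- paste0(mirPrefix, extractSeq(chrom, start, end, strand))
        umi <- chopString(randomDNA(nU * params$umiLength), params$umiLength)
        reads0 <- substr(paste0(umi, insert, adapterPad),
                         1L, params$readLength)

        src <- if (nDup > 0L) sample.int(nU, nDup, replace = TRUE)
               else integer(0)
        origIdx <- c(seq_len(nU), src)
        perm <- sample.int(n)
        origIdxP <- origIdx[perm]
        isDupP <- perm > nU
        reads <- reads0[origIdxP]
        ids <- sprintf("%s-%s-r%d-%06d", fraction, role, repl, seq_len(n))
        uniquePos <- integer(nU)
        uniquePos[origIdxP[!isDupP]] <- which(!isDupP)
        dupOf <- rep(NA_character_, n)
        dupOf[isDupP] <- ids[uniquePos[origIdxP[isDupP]]]

        if (params$seqErrorRate > 0) {
            L <- params$readLength
            flat <- which(runif(n * L) < params$seqErrorRate)
            for (f in flat) {
                ri <- (f - 1L) %/% L + 1L
                p <- (f - 1L) %% L + 1L
                cur <- substr(reads[ri], p, p)
                substr(reads[ri], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
            }
        }

        path <- file.path(dir, sprintf("%s_rep%d_%s.fastq",
                                       fraction, repl, role))
        dna <- Biostrings::DNAStringSet(setNames(reads, ids))
        Biostrings::writeXStringSet(dna, path, format = "fastq",
            qualities = Biostrings::BStringSet(rep(qual, n)))

        truth <- data.frame(
            read_id = ids, fraction = fraction, role = role,
            replicate = repl, read_class = cls[origIdxP],
            mirna = mirna[origIdxP], chrom = chrom[origIdxP],
            start = as.integer(start[origIdxP]),
            end = as.integer(end[origIdxP]),
            strand = strand[origIdxP], gene_id = gene[origIdxP],
            region = region[origIdxP], umi = umi[origIdxP],
            insert = insert[origIdxP], duplicate_of = dupOf)
        list(path = path, truth = truth)
    }

    files <- list(); truths <- list(); k <- 0L
    for (fraction in params$fractions) for (repl in seq_len(params$replicates))
        for (role in c("IP", "input")) {
            k <- k + 1L
            g <- genLibrary(fraction, repl, role)
            files[[k]] <- data.frame(fraction = fraction, replicate = repl,
                                     role = role, path = g$path)
            truths[[k]] <- g$truth
        }
    files <- do.call(rbind, files)
    truth <- do.call(rbind, truths)
    truthPath <- file.path(dir, "truth.tsv")
    write.table(truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out <- list(files = files, truth = truth, truthPath = truthPath,
                params = params, dir = dir)
    class(out) <- "eclipSim"
    invisible(out)
}

#' Synthetic WT vs DROSHA-knockout expression comparison
#'
#' Genes carrying a planted chimeric site are emitted as significantly
#' upregulated in the knockout (de-repression upon global miRNA loss,
#' log2 fold change drawn from \code{[2, 4]}); all other genes get small,
#' non-significant changes. This stands in for the RT-qPCR-derived
#' expression input of candidate prioritization; it is synthetic, not a
#' measured dataset.
#'
#' @param bundle a [GenomeBundle-class].
#' @param siteMap the planted-site map used for simulation.
#' @param seed RNG seed.
#' @return data.frame with \code{gene_id}, \code{log2fc}, \code{significant}.
#' @export
simulateExpressionTable <- function(bundle, siteMap, seed = 1L) {
    set.seed(seed)
    genes <- sort(unique(as.data.frame(transcriptInfo(bundle))$gene_id))
    chim <- unique(siteMap$gene_id[!is.na(siteMap$mirna)])
    lfc <- round(rnorm(length(genes), 0, 0.3), 3)
    sig <- rep(0L, length(genes))
    up <- genes %in% chim
    lfc[up] <- round(runif(sum(up), 2, 4), 3)
    sig[up] <- 1L
    data.frame(gene_id = genes, log2fc = lfc, significant = sig)
}

#' Read a FASTQ file into a plain data.frame
#' @param path FASTQ file path.
#' @return data.frame with \code{read_id}, \code{sequence}, \code{quality}.
#' @export
readFastqReads <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               sequence = as.character(x),
               quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write reads to FASTQ (4-line records, Phred+33)
#' @param reads data.frame with \code{read_id}, \code{sequence},
#'   \code{quality}.
#' @param path output path.
#' @export
writeFastqReads <- function(reads, path) {
    dna <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
    Biostrings::writeXStringSet(dna, path, format = "fastq",
        qualities = Biostrings::BStringSet(reads$quality))
    invisible(path)
}
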