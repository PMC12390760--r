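#' Generate a toy genome bundle
#'
#' Builds random chromosomes hosting non-overlapping gene models (coding
#' genes with three exons, a CDS span and non-empty UTRs on both sides;
#' noncoding genes with two exons), repeat/rRNA-like intervals near each
#' chromosome end, and a set of mature miRNAs grouped into seed families
#' (identical 7-mer at positions 2-8 within a family). Deterministic for a
#' fixed \code{seed}.
#'
#' @param nChroms number of chromosomes.
#' @param nGenes total number of genes (coding + noncoding).
#' @param nMirnas number of mature miRNAs; must be >= \code{nFamilies}.
#' @param nFamilies number of seed families.
#' @param seed integer RNG seed.
#' @param chromLength length of every chromosome in nt.
#' @param nNoncoding how many of the genes are noncoding (default ~1/5,
#'   at least one when \code{nGenes >= 3}).
#' @param dir if non-NULL, [writeGenomeBundle()] is called on the result.
#' @return a [GenomeBundle-class] object.
#' @examples
#' gb <- makeGenome(nChroms = 1, nGenes = 4, nMirnas = 4, nFamilies = 2,
#'                  seed = 7, chromLength = 20000)
#' gb
#' @export
makeGenome <- function(nChroms = 2L, nGenes = 12L, nMirnas = 12L,
                       nFamilies = 4L, seed = 1L, chromLength = 60000L,
                       nNoncoding = if (nGenes >= 3L)
                           max(1L, nGenes %/% 5L) else 0L,
                       dir = NULL) {
    stopifnot(nGenes >= 1L, nFamilies >= 1L, nMirnas >= nFamilies,
              nChroms >= 1L, nNoncoding < nGenes || nGenes == nNoncoding)
    set.seed(seed)

    codingSpan <- 2300L; ncSpan <- 1100L
    tailReserve <- 900L   # repeat interval + margin at each chromosome end
    chromNames <- sprintf("chr%d", seq_len(nChroms))

    ## ---- place genes (balanced across chromosomes) ----
    biotype <- c(rep("coding", nGenes - nNoncoding),
                 rep("noncoding", nNoncoding))
    cursor <- rep(200L, nChroms)
    geneChrom <- integer(nGenes); geneStart <- integer(nGenes)
    for (i in seq_len(nGenes)) {
        span <- if (biotype[i] == "coding") codingSpan else ncSpan
        ch <- which.min(cursor)
        gap <- sample(300:800, 1L)
        if (cursor[ch] + span + tailReserve > chromLength)
            stop(sprintf(paste0("chromosome length %d too short to host %d ",
                                "genes: gene %d needs %d bp beyond offset %d"),
                         chromLength, nGenes, i, span + tailReserve,
                         cursor[ch]))
        geneChrom[i] <- ch
        geneStart[i] <- cursor[ch]
        cursor[ch] <- cursor[ch] + span + gap
    }
    geneStrand <- sample(c("+", "-"), nGenes, replace = TRUE)
    geneId <- sprintf("g%02d", seq_len(nGenes))
    txId <- sprintf("t%02d", seq_len(nGenes))

    ## ---- chromosome sequences ----
    chromSeq <- vapply(seq_len(nChroms), function(i) randomDNA(chromLength),
                       character(1))
    chromosomes <- Biostrings::DNAStringSet(setNames(chromSeq, chromNames))

    ## ---- exon / CDS models (1-based closed for GRanges) ----
    exL <- list(); cdsL <- list()
    for (i in seq_len(nGenes)) {
        g <- geneStart[i]
        if (biotype[i] == "coding") {
            exStarts <- g + c(0L, 900L, 1800L)
            exEnds <- exStarts + 500L        # half-open ends
            cdsL[[i]] <- data.frame(tx = txId[i], gene = geneId[i],
                                    chrom = chromNames[geneChrom[i]],
                                    start = g + 250L, end = g + 2050L,
                                    strand = geneStrand[i])
        } else {
            exStarts <- g + c(0L, 700L)
            exEnds <- exStarts + 400L
        }
        exL[[i]] <- data.frame(tx = txId[i], gene = geneId[i],
                               chrom = chromNames[geneChrom[i]],
                               start = exStarts, end = exEnds,
                               strand = geneStrand[i])
    }
    exDf <- do.call(rbind, exL)
    cdsDf <- do.call(rbind, cdsL)
    exons <- GenomicRanges::GRanges(exDf$chrom,
        IRanges::IRanges(exDf$start + 1L, exDf$end), strand = exDf$strand,
        transcript_id = exDf$tx, gene_id = exDf$gene)
    cds <- if (is.null(cdsDf)) {
        GenomicRanges::GRanges()
    } else {
        gr <- GenomicRanges::GRanges(cdsDf$chrom,
            IRanges::IRanges(cdsDf$start + 1L, cdsDf$end),
            strand = cdsDf$strand, gene_id = cdsDf$gene)
        names(gr) <- cdsDf$tx
        gr
    }
    txInfo <- data.frame(transcript_id = txId, gene_id = geneId,
                         chrom = chromNames[geneChrom], strand = geneStrand,
                         biotype = biotype)

    ## ---- repeats: one rRNA-like interval at the tail of each chromosome ----
    repeats <- GenomicRanges::GRanges(chromNames,
        IRanges::IRanges(chromLength - 700L + 1L, chromLength - 300L),
        strand = "+",
        name = sprintf("%s%d", rep(c("rRNA", "rep"),
                                   length.out = nChroms), seq_len(nChroms)))

    ## ---- miRNAs ----
    seeds <- character(0)
    while (length(unique(seeds)) < nFamilies)
        seeds <- unique(c(seeds, vapply(seq_len(nFamilies), function(i)
            randomDNA(7L), character(1))))
    seeds <- seeds[seq_len(nFamilies)]
    famOf <- sort(rep_len(seq_len(nFamilies), nMirnas))
    member <- unlist(lapply(split(famOf, famOf), seq_along), use.names = FALSE)
    mname <- sprintf("mir-%02d%s", famOf, letters[member])
    mseq <- vapply(seq_len(nMirnas), function(i) {
        len <- sample(20:23, 1L)
        s <- randomDNA(len)
        paste0(substr(s, 1L, 1L), seeds[famOf[i]], substr(s, 9L, len))
    }, character(1))
    allow <- rep(TRUE, nMirnas)
    famSize <- table(famOf)
    big <- as.integer(names(famSize)[famSize >= 2L])
    if (length(big))   # one non-allowlisted miRNA to exercise the filter
        allow[max(which(famOf == big[1L]))] <- FALSE
    mirnas <- data.frame(name = mname, sequence = mseq,
                         seed = substr(mseq, 2L, 8L),
                         family_id = sprintf("fam-%02d", famOf),
                         allowlisted = allow)

    bundle <- GenomeBundle(chromosomes, exons, cds, txInfo, repeats, mirnas)
    if (!is.null(dir)) writeGenomeBundle(bundle, dir)
    bundle
}

#' Write a GenomeBundle to standard text formats
#'
#' Emits genome FASTA, a GTF with gene/transcript/exon/CDS records (1-based
#' inclusive), mature miRNA FASTA, a family map TSV
#' (mirna, family_id, seed, allowlisted) and a repeats BED.
#'
#' @param bundle a [GenomeBundle-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths.
#' @export
writeGenomeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  mirnas = file.path(dir, "mirnas.fa"),
                  families = file.path(dir, "families.tsv"),
                  repeats = file.path(dir, "repeats.bed"))
    Biostrings::writeXStringSet(chromosomes(bundle), paths$genome)
    writeLines(formatGtf(bundle), paths$gtf)
    mi <- as.data.frame(mirnaTable(bundle))
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(mi$sequence, mi$name)),
        paths$mirnas)
    write.table(data.frame(mirna = mi$name, family_id = mi$family_id,
                           seed = mi$seed,
                           allowlisted = as.integer(mi$allowlisted)),
                paths$families, sep = "\t", quote = FALSE, row.names = FALSE)
    rep <- repeatRanges(bundle)
    write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(rep)),
                           start = GenomicRanges::start(rep) - 1L,
                           end = GenomicRanges::end(rep),
                           name = S4Vectors::mcols(rep)$name, score = 0L,
                           strand = as.character(GenomicRanges::strand(rep))),
                paths$repeats, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(paths)
}

## GTF lines for a bundle. CDS features are emitted per overlapping exon
## piece with proper frames; coordinates 1-based inclusive per the standard.
formatGtf <- function(bundle) {
    ti <- as.data.frame(transcriptInfo(bundle))
    ex <- exonRanges(bundle); cd <- cdsRanges(bundle)
    lines <- character(0)
    attr1 <- function(gene, tx = NULL, bt) {
        base <- sprintf('gene_id "%s";', gene)
        if (!is.null(tx)) base <- paste(base, sprintf('transcript_id "%s";', tx))
        paste(base, sprintf('gene_biotype "%s";', bt))
    }
    gtfBiotype <- function(b) if (b == "coding") "protein_coding" else "lncRNA"
    row <- function(chrom, feat, s, e, strand, frame, attrs)
        sprintf("%s\tchimeRclip\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                chrom, feat, s, e, strand, frame, attrs)
    for (i in seq_len(nrow(ti))) {
        tx <- ti$transcript_id[i]; gene <- ti$gene_id[i]
        bt <- gtfBiotype(ti$biotype[i])
        exi <- ex[S4Vectors::mcols(ex)$transcript_id == tx]
        exi <- GenomicRanges::sort(exi)
        s <- min(GenomicRanges::start(exi)); e <- max(GenomicRanges::end(exi))
        st <- ti$strand[i]
        lines <- c(lines,
            row(ti$chrom[i], "gene", s, e, st, ".", attr1(gene, NULL, bt)),
            row(ti$chrom[i], "transcript", s, e, st, ".", attr1(gene, tx, bt)),
            row(ti$chrom[i], "exon",
                GenomicRanges::start(exi), GenomicRanges::end(exi), st, ".",
                attr1(gene, tx, bt)))
        if (tx %in% names(cd)) {
            cdi <- cd[tx]
            pieces <- IRanges::intersect(IRanges::ranges(exi),
                                         IRanges::ranges(cdi))
            ord <- if (st == "+") order(IRanges::start(pieces)) else
                order(-IRanges::start(pieces))
            pieces <- pieces[ord]
            cum <- c(0L, cumsum(IRanges::width(pieces)))
            frames <- (3L - cum[seq_along(pieces)] %% 3L) %% 3L
            lines <- c(lines, row(ti$chrom[i], "CDS",
                                  IRanges::start(pieces),
                                  IRanges::end(pieces), st,
                                  as.character(frames), attr1(gene, tx, bt)))
        }
    }
    lines
}

#' Read a genome bundle back from its on-disk form
#'
#' Counterpart of [writeGenomeBundle()]. The GTF is parsed with
#' \pkg{rtracklayer}.
#'
#' @param genomeFa,gtf,mirnaFa,familyTsv,repeatsBed file paths; the last
#'   three are optional.
#' @return a [GenomeBundle-class].
#' @export
readGenomeBundle <- function(genomeFa, gtf, mirnaFa = NULL, familyTsv = NULL,
                             repeatsBed = NULL) {
    chromosomes <- Biostrings::readDNAStringSet(genomeFa)
    names(chromosomes) <- sub("\\s.*$", "", names(chromosomes))
    g <- rtracklayer::import(gtf)
    exg <- g[g$type == "exon"]
    exons <- GenomicRanges::granges(exg)
    S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
        transcript_id = exg$transcript_id, gene_id = exg$gene_id)
    cdg <- g[g$type == "CDS"]
    cds <- GenomicRanges::GRanges()
    if (length(cdg)) {
        spl <- S4Vectors::split(cdg, cdg$transcript_id)
        cds <- unlist(range(spl))
        S4Vectors::mcols(cds)$gene_id <- vapply(spl, function(x)
            x$gene_id[1], character(1))
    }
    txg <- g[g$type == "transcript"]
    bt <- txg$gene_biotype
    txInfo <- data.frame(
        transcript_id = txg$transcript_id, gene_id = txg$gene_id,
        chrom = as.character(GenomicRanges::seqnames(txg)),
        strand = as.character(GenomicRanges::strand(txg)),
        biotype = ifelse(bt == "protein_coding", "coding", "noncoding"))
    repeats <- GenomicRanges::GRanges()
    if (!is.null(repeatsBed)) {
        rb <- read.table(repeatsBed, sep = "\t",
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
        repeats <- GenomicRanges::GRanges(rb$chrom,
            IRanges::IRanges(rb$start + 1L, rb$end), strand = rb$strand,
            name = rb$name)
    }
    mirnas <- data.frame(name = character(0), sequence = character(0),
                         seed = character(0), family_id = character(0),
                         allowlisted = logical(0))
    if (!is.null(mirnaFa)) {
        ms <- Biostrings::readDNAStringSet(mirnaFa)
        mirnas <- data.frame(name = sub("\\s.*$", "", names(ms)),
                             sequence = as.character(ms))
        mirnas$seed <- substr(mirnas$sequence, 2L, 8L)
        if (!is.null(familyTsv)) {
            fm <- read.table(familyTsv, sep = "\t", header = TRUE)
            i <- match(mirnas$name, fm$mirna)
            mirnas$family_id <- fm$family_id[i]
            mirnas$allowlisted <- as.logical(fm$allowlisted[i])
        } else {
            mirnas <- assignFamilies(mirnas)
            mirnas$allowlisted <- TRUE
        }
    }
    GenomeBundle(chromosomes, exons, cds, txInfo, repeats, mirnas)
}
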