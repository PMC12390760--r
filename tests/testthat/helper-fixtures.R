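## Shared fixtures, built in code. Simulations are cached per-session so
## several test files can reuse the same small run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

tinyGenome <- function(seed = 42) {
    cached(paste0("tinyGenome", seed),
           makeGenome(nChroms = 1, nGenes = 5, nMirnas = 6, nFamilies = 3,
                      seed = seed, chromLength = 25000))
}

## A small full simulation: 1 fraction x 2 replicates, sites in two genes.
smallSim <- function(seed = 3, nReadsIP = 2000, seqErrorRate = 0,
                     pcrDuplicationRate = 0.1) {
    key <- paste("smallSim", seed, nReadsIP, seqErrorRate,
                 pcrDuplicationRate)
    cached(key, {
        gb <- tinyGenome()
        sm <- defaultSiteMap(gb, nSiteGenes = 2)
        p <- simParams(seed = seed, nReadsIP = nReadsIP,
                       nReadsInput = nReadsIP,
                       seqErrorRate = seqErrorRate,
                       pcrDuplicationRate = pcrDuplicationRate,
                       fractions = "cytoplasm", replicates = 2L,
                       siteMap = sm)
        sim <- simulateLibraries(gb, p, tempfile("smallsim"))
        list(bundle = gb, siteMap = sm, params = p, sim = sim)
    })
}

## Preprocessed + aligned fragments for one library of smallSim.
smallAligned <- function(libRow = 1L) {
    key <- paste("smallAligned", libRow)
    cached(key, {
        fx <- smallSim()
        gb <- fx$bundle
        idx <- buildSeedIndex(chromosomes(gb), 16)
        ri <- buildSeedIndex(repeatSequences(gb), 16)
        raw <- readFastqReads(fx$sim$files$path[libRow])
        pp <- preprocessReads(raw)
        rf <- filterRepeats(pp$reads, ri)
        gm <- mapReads(idx, rf$kept$sequence)
        list(fx = fx, idx = idx, repeatIdx = ri, pp = pp, rf = rf, gm = gm)
    })
}

## Build a fragments GRanges from a compact spec data.frame.
makeFrags <- function(df) {
    n <- nrow(df)
    GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        strand = df$strand,
        read_id = df$read_id %||d% sprintf("rd%04d", seq_len(n)),
        umi = df$umi %||d% sprintf("U%04d", seq_len(n)),
        sample = "cytoplasm", role = "IP", replicate = 1L,
        mirna_tag = df$mirna_tag %||d% rep(NA_character_, n),
        mismatches = 0L)
}
`%||d%` <- function(a, b) if (is.null(a)) b else a

## n fragments forming one block of given span.
fragBlock <- function(chrom, start, end, n, strand = "+", width = 25L,
                      prefix = "f") {
    starts <- round(seq(start, max(start, end - width), length.out = n))
    makeFrags(data.frame(chrom = chrom, start = starts,
                         end = pmin(starts + width, end),
                         strand = strand,
                         read_id = sprintf("%s_%s_%s_%d_%d", prefix, chrom,
                                           strand, start, seq_len(n)),
                         umi = sprintf("%s_%s_%s_%d_%d_U", prefix, chrom,
                                       strand, start, seq_len(n))))
}

randDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

emptyTestInput <- function() {
    GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                           strand = character(0))
}

## Hand-stacked annotation fixture: one chromosome, two coding and one
## noncoding transcript in overlapping configurations, plus 20 peaks with
## hand-derived feature categories.
stackedAnnotationFixture <- function() {
    cached("stackedAnnotation", {
        set.seed(99)
        chromosomes <- Biostrings::DNAStringSet(c(chrA = randDNA(2100)))
        exDf <- rbind(
            data.frame(tx = "tA", gene = "gA", s = c(101, 501, 901),
                       e = c(400, 800, 1200), strand = "+"),
            data.frame(tx = "tB", gene = "gB", s = c(401, 1301),
                       e = c(500, 1400), strand = "+"),
            data.frame(tx = "tC", gene = "gC", s = c(1501, 1801),
                       e = c(1700, 2000), strand = "-"))
        exons <- GenomicRanges::GRanges("chrA",
            IRanges::IRanges(exDf$s, exDf$e), strand = exDf$strand,
            transcript_id = exDf$tx, gene_id = exDf$gene)
        cds <- GenomicRanges::GRanges("chrA",
            IRanges::IRanges(c(201, 1551), c(1100, 1950)),
            strand = c("+", "-"), gene_id = c("gA", "gC"))
        names(cds) <- c("tA", "tC")
        txInfo <- data.frame(
            transcript_id = c("tA", "tB", "tC"),
            gene_id = c("gA", "gB", "gC"), chrom = "chrA",
            strand = c("+", "+", "-"),
            biotype = c("coding", "noncoding", "coding"))
        repeats <- GenomicRanges::GRanges("chrA",
            IRanges::IRanges(2050, 2090), strand = "+", name = "repA")
        mirnas <- data.frame(name = "mir-x",
                             sequence = "ACGTACGTACGTACGTACGT",
                             seed = "CGTACGT", family_id = "fam-x",
                             allowlisted = TRUE)
        bundle <- GenomeBundle(chromosomes, exons, cds, txInfo, repeats,
                               mirnas)
        pk <- data.frame(
            s = c(150, 250, 1110, 420, 550, 1320, 1250,  50, 150, 1520,
                  1900, 1960, 1750, 380, 1150,  90, 460, 1195, 1450, 1650),
            e = c(160, 260, 1120, 430, 560, 1330, 1260,  60, 160, 1530,
                  1910, 1970, 1760, 420, 1350, 110, 510, 1205, 1470, 1720),
            strand = c("+", "+", "+", "+", "+", "+", "+", "+", "-", "-",
                       "-", "-", "-", "+", "+", "+", "+", "+", "+", "-"),
            category = c("UTR5", "CDS", "UTR3", "intron", "CDS", "nc_exon",
                         "nc_intron", "intergenic", "intergenic", "UTR3",
                         "CDS", "UTR5", "intron", "CDS", "UTR3", "UTR5",
                         "CDS", "UTR3", "intergenic", "CDS"),
            gene = c("gA", "gA", "gA", "gA", "gA", "gB", "gB", "", "",
                     "gC", "gC", "gC", "gC", "gA", "gA", "gA", "gA", "gA",
                     "", "gC"))
        peaks <- GenomicRanges::GRanges("chrA",
            IRanges::IRanges(pk$s, pk$e), strand = pk$strand)
        list(bundle = bundle, peaks = peaks, expected = pk)
    })
}

## Independent brute-force oracles ----------------------------------------

## Hypergeometric tail by direct log-binomial summation.
bruteEnrichmentP <- function(ip, ipTot, inp, inpTot) {
    k <- ip + inp
    j <- seq(ip, min(ipTot, k))
    if (!length(j)) return(0)
    sum(exp(lchoose(ipTot, j) + lchoose(inpTot, k - j) -
            lchoose(ipTot + inpTot, k)))
}

## Connected components of the pairwise same-strand overlap graph.
bruteClusters <- function(df) {
    n <- nrow(df)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i) next
        if (df$chrom[i] == df$chrom[j] && df$strand[i] == df$strand[j] &&
            df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
            parent[find(j)] <- find(i)
        }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    out <- do.call(rbind, lapply(split(seq_len(n), comp), function(i)
        data.frame(chrom = df$chrom[i[1]], start = min(df$start[i]),
                   end = max(df$end[i]), strand = df$strand[i[1]],
                   ip_count = length(i))))
    out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

## Independent re-implementation of the candidate-selection criteria.
bruteSelect <- function(counts, expr, thr = 1, strict = TRUE,
                        fr = c("cytoplasm", "nucleus", "chromatin")) {
    sel <- character(0)
    for (i in seq_len(nrow(counts))) {
        v <- as.numeric(counts[i, fr])
        c1 <- if (strict) any(v > 5) else any(v >= 5)
        c2 <- all(v >= 1)
        j <- which(expr$gene_id == counts$gene_id[i])
        ok2 <- length(j) == 1 && abs(expr$log2fc[j]) >= thr &&
            as.logical(expr$significant[j])
        if ((c1 || c2) && ok2) sel <- c(sel, counts$gene_id[i])
    }
    sel
}

## Nine genes exercising every branch of the selection rule, including the
## strict ">5" boundary and the one-peak-in-all-fractions path.
nineGeneFixture <- function() {
    counts <- data.frame(
        gene_id = sprintf("g%d", 1:9),
        cytoplasm = c(6, 5, 1, 0, 2, 6, 1, 0, 7),
        nucleus   = c(0, 0, 1, 1, 2, 1, 1, 0, 3),
        chromatin = c(0, 0, 1, 1, 0, 2, 1, 0, 1))
    expr <- data.frame(
        gene_id = sprintf("g%d", c(1:8)),   # g9 missing: unknown
        log2fc = c(3.3, 2.0, 1.5, -2.0, 1.8, 0.4, 1.2, 2.5),
        significant = c(1, 1, 1, 1, 1, 1, 0, 1))
    list(counts = counts, expr = expr)
}

## Reference adapter trimmer: earliest start whose prefix-window qualifies.
bruteTrim <- function(seq, adapter, minOverlap, maxMismatchRate) {
    l <- nchar(seq); A <- nchar(adapter)
    for (i in seq_len(max(0L, l - minOverlap + 1L))) {
        ov <- min(l - i + 1L, A)
        if (ov < minOverlap) break
        mm <- sum(charToRaw(substr(seq, i, i + ov - 1L)) !=
                  charToRaw(substr(adapter, 1L, ov)))
        if (mm <= maxMismatchRate * ov + 1e-9)
            return(substr(seq, 1L, i - 1L))
    }
    seq
}
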