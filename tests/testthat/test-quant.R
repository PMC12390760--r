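test_that("deduplication collapses on (umi, chrom, start, strand) only", {
    fr <- makeFrags(data.frame(
        chrom = "chr1", start = c(100, 100, 100, 100, 200),
        end = c(140, 140, 150, 140, 240),
        strand = c("+", "+", "+", "-", "+"),
        read_id = sprintf("r%d", 1:5),
        umi = c("AAAA", "AAAA", "AAAA", "AAAA", "AAAA")))
    out <- deduplicateFragments(fr)
    ## same UMI/start/strand collapse even when ends differ; the minus
    ## strand fragment and the distant fragment survive
    expect_identical(length(out), 3L)
    expect_identical(attr(out, "removed"), 2L)
    ## first in read-id order survives
    expect_true("r1" %in% S4Vectors::mcols(out)$read_id)
    ## different UMIs at one position both survive
    fr2 <- makeFrags(data.frame(chrom = "chr1", start = c(5, 5),
                                end = c(30, 30), strand = "+",
                                read_id = c("a", "b"),
                                umi = c("AAAA", "CCCC")))
    expect_identical(length(deduplicateFragments(fr2)), 2L)
    ## idempotence and order-insensitivity of the survivor count
    expect_identical(length(deduplicateFragments(out)), 3L)
    expect_identical(attr(deduplicateFragments(fr[5:1]), "removed"), 2L)
    ## missing UMI is an error naming the read
    bad <- makeFrags(data.frame(chrom = "chr1", start = 1, end = 20,
                                strand = "+", read_id = "naked",
                                umi = ""))
    expect_error(deduplicateFragments(bad), "naked")
})

test_that("survivors equal truth non-duplicates on simulated data", {
    al <- smallAligned()
    fx <- al$fx
    tr <- fx$sim$truth
    lib <- fx$sim$files[1, ]
    uni <- al$gm$status == "unique"
    fr <- GenomicRanges::GRanges(
        al$gm$chrom[uni],
        IRanges::IRanges(al$gm$start[uni] + 1L, al$gm$end[uni]),
        strand = al$gm$strand[uni],
        read_id = al$rf$kept$read_id[uni], umi = al$rf$kept$umi[uni],
        mirna_tag = NA_character_)
    dd <- deduplicateFragments(fr)
    trLib <- tr[tr$fraction == lib$fraction & tr$replicate ==
                lib$replicate & tr$role == lib$role, ]
    mappedIds <- sub("_[ACGT]+$", "", al$rf$kept$read_id[uni])
    tm <- trLib[trLib$read_id %in% mappedIds, ]
    ## survivor count equals distinct original molecules among mapped
    ## reads: non-duplicates plus duplicates whose source was not mapped
    origin <- ifelse(is.na(tm$duplicate_of), tm$read_id, tm$duplicate_of)
    expect_identical(length(dd), length(unique(origin)))
})

test_that("cluster calling merges overlapping same-strand fragments", {
    fr <- makeFrags(data.frame(chrom = "chr1", start = c(100, 125),
                               end = c(130, 155), strand = "+"))
    cl <- callClusters(fr)
    expect_identical(length(cl), 1L)
    expect_identical(GenomicRanges::start(cl) - 1L, 100L)
    expect_identical(GenomicRanges::end(cl), 155L)
    expect_identical(S4Vectors::mcols(cl)$ip_count, 2L)
    ## same intervals, opposite strands -> two clusters
    fr2 <- makeFrags(data.frame(chrom = "chr1", start = c(100, 125),
                                end = c(130, 155), strand = c("+", "-")))
    expect_identical(length(callClusters(fr2)), 2L)
    ## book-ended fragments (gap 0) are not merged
    fr3 <- makeFrags(data.frame(chrom = "chr1", start = c(100, 130),
                                end = c(130, 160), strand = "+"))
    expect_identical(length(callClusters(fr3)), 2L)
})

test_that("clusters equal brute-force overlap-graph components", {
    set.seed(55)
    for (rep in 1:60) {
        n <- sample(5:60, 1)
        df <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                         start = sample(0:400, n, TRUE),
                         strand = sample(c("+", "-"), n, TRUE))
        df$end <- df$start + sample(10:60, n, TRUE)
        cl <- callClusters(makeFrags(df))
        got <- as.data.frame(cl)[, c("seqnames", "start", "end", "strand",
                                     "ip_count")]
        got <- data.frame(chrom = as.character(got$seqnames),
                          start = got$start - 1L, end = got$end,
                          strand = as.character(got$strand),
                          ip_count = got$ip_count)
        got <- got[order(got$chrom, got$start, got$strand), ]
        want <- bruteClusters(df)
        expect_equal(got, want, ignore_attr = TRUE)
        ## conservation: member counts sum to the fragment count
        expect_identical(sum(got$ip_count), n)
    }
})

test_that("peak scoring implements RPM, pseudocounted log2FC and exact p", {
    cl <- callClusters(fragBlock("chr1", 100, 160, 5))
    s <- scorePeaks(cl, ipTotal = 1e6,
                    inputFragments = emptyTestInput(), inputTotal = 1e6)
    expect_equal(S4Vectors::mcols(s)$ip_rpm, 5)
    ## symmetric counts and totals give log2fc 0
    inp <- fragBlock("chr1", 100, 160, 5, prefix = "inp")
    s2 <- scorePeaks(cl, 1000, inp, 1000)
    expect_equal(S4Vectors::mcols(s2)$log2fc, 0)
    expect_identical(S4Vectors::mcols(s2)$input_count, 5L)
    ## worked 2x2 table against direct hypergeometric summation
    p <- enrichmentP(8, 1000, 1, 1000)
    expect_equal(p, bruteEnrichmentP(8, 1000, 1, 1000), tolerance = 1e-12)
    expect_error(scorePeaks(cl, 0, inp, 1000), "positive")
})

test_that("threshold and reproducibility filters follow the peak criteria", {
    repA1 <- fragBlock("chr1", 100, 140, 10)
    repA2 <- fragBlock("chr1", 120, 160, 9, prefix = "g")
    repB1 <- fragBlock("chr1", 300, 330, 2)            # < 3 reads
    repB2 <- fragBlock("chr1", 300, 330, 5, prefix = "g")
    repD1 <- fragBlock("chr1", 700, 730, 10)           # not reproduced
    repE1 <- fragBlock("chr1", 900, 930, 10)           # strand mismatch
    repE2 <- fragBlock("chr1", 900, 930, 10, strand = "-", prefix = "g")
    s1 <- scorePeaks(callClusters(c(repA1, repB1, repD1, repE1)),
                     1000, emptyTestInput(), 1e5)
    s2 <- scorePeaks(callClusters(c(repA2, repB2, repE2)),
                     1000, emptyTestInput(), 1e5)
    fin <- filterReproduciblePeaks(s1, s2, minReads = 3, minLog2fc = 3)
    expect_identical(length(fin), 1L)
    expect_identical(GenomicRanges::start(fin) - 1L, 100L)
    expect_identical(GenomicRanges::end(fin), 160L)
    expect_identical(S4Vectors::mcols(fin)$ip_count, 19L)
    expect_true(all(S4Vectors::mcols(fin)$reproducible))
    ## log2fc exactly at the threshold is excluded (strict inequality)
    ip3 <- fragBlock("chr1", 100, 130, 3)
    inp49 <- fragBlock("chr1", 100, 130, 49, prefix = "inp")
    sx <- scorePeaks(callClusters(ip3), 1000, inp49, 1e5)
    expect_equal(S4Vectors::mcols(sx)$log2fc, 3)
    expect_identical(length(filterReproduciblePeaks(sx, sx, 3, 3)), 0L)
    expect_error(filterReproduciblePeaks(s1, s2, 0, 3), "positive")
})

test_that("p-values match the hypergeometric oracle over dense sweeps", {
    totals <- list(c(200, 200), c(100, 300), c(300, 50))
    for (tt in totals) {
        for (ip in c(0:12, tt[1])) for (inp in c(0:12, tt[2])) {
            expect_equal(enrichmentP(ip, tt[1], inp, tt[2]),
                         bruteEnrichmentP(ip, tt[1], inp, tt[2]),
                         tolerance = 1e-12)
        }
    }
})
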