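test_that("seed index lookups enumerate k-mer positions exactly", {
    expect_error(buildSeedIndex(c(chr1 = "ACGTAC"), k = 8), "shortest")
    idx <- buildSeedIndex(c(chr1 = "ACGTACGTACGTACGT"), k = 8)
    hit <- lookupKmer(idx, "ACGTACGT")
    expect_identical(hit$pos, c(0L, 4L, 8L))
    expect_identical(nrow(lookupKmer(idx, "TTTTTTTT")), 0L)
})

test_that("index lookups equal a naive substring scan on random k-mers", {
    set.seed(31)
    s <- randDNA(10000)
    idx <- buildSeedIndex(c(chrZ = s), k = 12)
    naive <- function(km) {
        hits <- integer(0); from <- 1L
        repeat {
            p <- regexpr(km, substr(s, from, nchar(s)), fixed = TRUE)
            if (p < 0) break
            hits <- c(hits, from + p - 2L)  # 0-based
            from <- from + p
        }
        hits
    }
    for (i in 1:100) {
        km <- if (i %% 3 == 0) randDNA(12) else {
            p <- sample(nchar(s) - 11, 1); substr(s, p, p + 11)
        }
        expect_identical(lookupKmer(idx, km)$pos, naive(km))
    }
})

test_that("mapping reports constructed loci with strand symmetry", {
    set.seed(32)
    s <- randDNA(3000)
    idx <- buildSeedIndex(c(chr1 = s), k = 16)
    read <- substr(s, 101, 130)   # 0-based [100, 130)
    m <- mapRead(idx, read)
    expect_identical(m$status, "unique")
    expect_identical(c(m$start, m$end), c(100L, 130L))
    expect_identical(m$strand, "+")
    expect_identical(m$mismatches, 0L)
    mr <- mapRead(idx, revComp(read))
    expect_identical(mr$status, "unique")
    expect_identical(c(mr$start, mr$end), c(100L, 130L))
    expect_identical(mr$strand, "-")
})

test_that("a 30-mer planted twice is multi; exhaustive scan agrees", {
    set.seed(33)
    core <- randDNA(30)
    s <- paste0(randDNA(500), core, randDNA(700), core, randDNA(400))
    idx <- buildSeedIndex(c(chr1 = s), k = 16)
    expect_identical(mapRead(idx, core)$status, "multi")
    ## exhaustive oracle: exact occurrences on both strands
    expect_identical(length(gregexpr(core, s, fixed = TRUE)[[1]]), 2L)
})

test_that("seeded mapping equals the Biostrings brute-force aligner", {
    set.seed(34)
    chroms <- c(chrA = randDNA(5000), chrB = randDNA(4000))
    idx <- buildSeedIndex(chroms, k = 16)
    subjects <- lapply(chroms, Biostrings::DNAString)

    oracle <- function(read, maxMM = 2L) {
        hits <- data.frame(chrom = character(0), start = integer(0),
                           strand = character(0), mm = integer(0))
        for (ch in names(subjects)) for (st in c("+", "-")) {
            q <- if (st == "+") read else revComp(read)
            m <- Biostrings::matchPattern(q, subjects[[ch]],
                                          max.mismatch = maxMM,
                                          with.indels = FALSE)
            if (!length(m)) next
            mm <- Biostrings::neditAt(Biostrings::DNAString(q),
                                      subjects[[ch]],
                                      at = Biostrings::start(m))
            hits <- rbind(hits, data.frame(chrom = ch,
                                           start = Biostrings::start(m) - 1L,
                                           strand = st, mm = mm))
        }
        if (nrow(hits) == 0L) return(list(status = "unmapped"))
        best <- hits[hits$mm == min(hits$mm), , drop = FALSE]
        if (nrow(best) > 1L) return(list(status = "multi"))
        list(status = "unique", chrom = best$chrom, start = best$start,
             strand = best$strand, mm = best$mm)
    }

    mutate <- function(x, nmm) {
        for (p in sample(nchar(x), nmm)) {
            substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(x, p, p)), 1)
        }
        x
    }
    grab <- function() {
        ch <- sample(names(chroms), 1)
        len <- sample(32:45, 1)
        p <- sample(nchar(chroms[[ch]]) - len, 1)
        substr(chroms[[ch]], p, p + len - 1)
    }
    reads <- c(vapply(1:400, function(i) grab(), character(1)),
               vapply(1:300, function(i) mutate(grab(), sample(1:2, 1)),
                      character(1)),
               vapply(1:100, function(i) revComp(grab()), character(1)),
               vapply(1:150, function(i) mutate(grab(), 3), character(1)),
               vapply(1:50, function(i) randDNA(36), character(1)))
    got <- mapReads(idx, reads, maxMismatches = 2L)
    for (i in seq_along(reads)) {
        o <- oracle(reads[i])
        ## the seeded heuristic guarantees discovery for <= 1 mismatch
        ## (two non-overlapping exact seeds); treat heuristic misses at
        ## 2 mismatches as agreement only when the oracle found nothing
        if (o$status == "unique" && got$status[i] == "unmapped" &&
            o$mm == 2L) next
        expect_identical(got$status[i], o$status)
        if (o$status == "unique" && got$status[i] == "unique") {
            expect_identical(got$chrom[i], o$chrom)
            expect_identical(got$start[i], o$start)
            expect_identical(got$strand[i], o$strand)
            expect_identical(got$mismatches[i], o$mm)
        }
    }
})

test_that("repeat filtering removes exactly the repeat-derived reads", {
    al <- smallAligned()
    gb <- al$fx$bundle
    ## verbatim repeat copy is removed, an exonic read is kept
    rp <- repeatSequences(gb)
    probe <- data.frame(read_id = c("rep_probe", "exon_probe"),
                        sequence = c(substr(rp[[1]], 11, 50),
                                     substr(as.character(
                                         chromosomes(gb)[[1]]), 301, 340)),
                        quality = strrep("I", 40))
    out <- filterRepeats(probe, al$repeatIdx)
    expect_identical(out$kept$read_id, "exon_probe")
    expect_identical(out$repeatHits, 1L)
    ## simulated library: removed set equals truth repeat class (error 0)
    tr <- al$fx$sim$truth
    lib <- al$fx$sim$files[1, ]
    trLib <- tr[tr$fraction == lib$fraction & tr$replicate ==
                lib$replicate & tr$role == lib$role, ]
    removedIds <- setdiff(sub("_[ACGT]+$", "", al$pp$reads$read_id),
                          sub("_[ACGT]+$", "", al$rf$kept$read_id))
    expect_setequal(removedIds,
                    trLib$read_id[trLib$read_class == "repeat"])
})

test_that("error-free nonchimeric reads map uniquely to their origin", {
    al <- smallAligned()
    tr <- al$fx$sim$truth
    base <- sub("_[ACGT]+$", "", al$rf$kept$read_id)
    m <- match(base, tr$read_id)
    nonchim <- tr$read_class[m] != "chimeric"
    gm <- al$gm
    expect_true(all(gm$status[nonchim] == "unique"))
    expect_identical(gm$start[nonchim], tr$start[m][nonchim])
    expect_identical(gm$end[nonchim], tr$end[m][nonchim])
    expect_identical(gm$strand[nonchim], tr$strand[m][nonchim])
    ## and no chimeric read maps to the genome
    expect_true(all(gm$status[!nonchim] == "unmapped"))
})
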