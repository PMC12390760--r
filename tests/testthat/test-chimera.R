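mirFixture <- function() {
    ## two same-seed family members differing only at position 20, plus an
    ## unrelated miRNA
    a <- "TAGCTTATCAGACTGATGTTGA"   # 22 nt, let-7a-like layout
    b <- a; substr(b, 20, 20) <- "C"
    data.frame(name = c("mir-aa", "mir-ab", "mir-zz"),
               sequence = c(a, b, "ACCCGTAGATCCGAACTTGTGG"))
}

test_that("a full miRNA plus target fragment is called exactly", {
    set.seed(41)
    mi <- mirFixture()
    target <- randDNA(30)
    read <- paste0(mi$sequence[1], target)
    det <- detectChimeras(read, mi)
    expect_identical(nrow(det$calls), 1L)
    expect_identical(det$calls$mirna, "mir-aa")
    expect_identical(det$calls$match_length, 22L)
    expect_identical(det$calls$target_start, 22L)
    expect_identical(det$calls$target, target)
    expect_identical(det$calls$mismatches, 0L)
})

test_that("reads without miRNA content yield no call", {
    ## fixed fixture verified once against all three miRNAs
    read <- "GGGGCCCCTTTTAAAAGGGG"
    det <- detectChimeras(read, mirFixture(), minMirnaMatch = 18)
    expect_identical(nrow(det$calls), 0L)
    expect_identical(unname(det$log["no_call"]), 1L)
    expect_error(detectChimeras(read, mirFixture()[0, ]), "empty miRNA")
})

test_that("same-seed ambiguity breaks ties lexicographically and is recorded", {
    set.seed(42)
    mi <- mirFixture()
    shared <- substr(mi$sequence[1], 1, 19)
    ## target chosen so position 20 mismatches both family members and
    ## position 21 disqualifies longer windows: both members tie at
    ## match_length 20 with one mismatch
    read <- paste0(shared, "GTC", randDNA(22))
    det <- detectChimeras(read, mi, minMirnaMatch = 18, maxMismatches = 1)

    ## exhaustive oracle: align every miRNA prefix at every usable length
    best <- NULL
    for (j in order(mi$name)) {
        for (L in seq(min(nchar(mi$sequence[j]), nchar(read)), 18)) {
            mm <- sum(charToRaw(substr(read, 1, L)) !=
                      charToRaw(substr(mi$sequence[j], 1, L)))
            if (mm <= 1) {
                cand <- list(name = mi$name[j], L = L, mm = mm)
                if (is.null(best) || cand$L > best$L ||
                    (cand$L == best$L && cand$mm < best$mm))
                    best <- c(cand, list(ties = character(0)))
                else if (cand$L == best$L && cand$mm == best$mm &&
                         cand$name != best$name)
                    best$ties <- union(best$ties, cand$name)
                break   # longest qualifying L found for this miRNA
            }
        }
    }
    expect_identical(det$calls$mirna, best$name)
    expect_identical(det$calls$match_length, best$L)
    expect_identical(det$calls$mirna, "mir-aa")   # lexicographic winner
    expect_identical(det$calls$ambiguous_with, "mir-ab")
    ## determinism including the tie-break
    det2 <- detectChimeras(read, mi, minMirnaMatch = 18, maxMismatches = 1)
    expect_identical(det$calls, det2$calls)
})

test_that("the 3'-end search handles target-first ligation geometry", {
    set.seed(44)
    mi <- mirFixture()
    target <- randDNA(28)
    read <- paste0(target, mi$sequence[3])
    ## the default 5' search finds nothing here
    expect_identical(nrow(detectChimeras(read, mi)$calls), 0L)
    det <- detectChimeras(read, mi, end = "3p")
    expect_identical(det$calls$mirna, "mir-zz")
    expect_identical(det$calls$match_length, nchar(mi$sequence[3]))
    expect_identical(det$calls$target, target)
    expect_identical(det$calls$target_start, 0L)
})

test_that("miRNA-only reads and short targets are excluded from clustering", {
    mi <- mirFixture()
    only <- detectChimeras(mi$sequence[3], mi)
    expect_identical(nrow(only$calls), 0L)
    expect_identical(unname(only$log["mirna_only"]), 1L)
    short <- detectChimeras(paste0(mi$sequence[3], "ACGTACGT"), mi,
                            minTargetLength = 18)
    expect_identical(nrow(short$calls), 0L)
    expect_identical(unname(short$log["short_target"]), 1L)
})

test_that("resolved targets map with the mirna tag; repeats drop as multi", {
    set.seed(43)
    uniqueSeg <- randDNA(400)
    dupSeg <- randDNA(60)
    genome <- c(chrM = paste0(uniqueSeg, dupSeg, randDNA(200), dupSeg))
    idx <- buildSeedIndex(genome, k = 16)
    mi <- mirFixture()
    calls <- data.frame(
        read = c(1L, 2L),
        mirna = c("mir-aa", "mir-zz"),
        match_length = 22L, mismatches = 0L, target_start = 22L,
        target = c(substr(uniqueSeg, 101, 135),
                   paste0(substr(dupSeg, 1, 35))),
        ambiguous_with = "")
    meta <- data.frame(read_id = c("r1_U", "r2_U"), umi = c("U1", "U2"),
                       sample = "cytoplasm", role = "IP", replicate = 1L)
    res <- resolveChimeras(calls, idx, meta)
    expect_identical(length(res$fragments), 1L)
    expect_identical(S4Vectors::mcols(res$fragments)$mirna_tag, "mir-aa")
    expect_identical(GenomicRanges::start(res$fragments) - 1L, 100L)
    expect_identical(unname(res$log["dropped_multi"]), 1L)
})

test_that("on error-free simulated data chimera recovery is exact", {
    al <- smallAligned()
    fx <- al$fx
    tr <- fx$sim$truth
    unm <- al$gm$status == "unmapped"
    det <- detectChimeras(al$rf$kept$sequence[unm],
                          mirnaTable(fx$bundle))
    lib <- fx$sim$files[1, ]
    meta <- data.frame(read_id = al$rf$kept$read_id,
                       umi = al$rf$kept$umi, sample = lib$fraction,
                       role = lib$role, replicate = lib$replicate)
    res <- resolveChimeras(det$calls, al$idx, meta[unm, , drop = FALSE])
    fr <- res$fragments
    base <- sub("_[ACGT]+$", "", S4Vectors::mcols(fr)$read_id)
    m <- match(base, tr$read_id)
    ## all resolved fragments are planted chimeras with the exact miRNA
    ## and target interval; no genome-mappable read was ever tested
    expect_true(all(tr$read_class[m] == "chimeric"))
    expect_identical(S4Vectors::mcols(fr)$mirna_tag, tr$mirna[m])
    expect_identical(GenomicRanges::start(fr) - 1L, tr$start[m])
    expect_identical(GenomicRanges::end(fr), tr$end[m])
    ## recovery is 100% of eligible planted chimeras in this library
    trLib <- tr[tr$fraction == lib$fraction &
                tr$replicate == lib$replicate & tr$role == lib$role &
                tr$read_class == "chimeric", ]
    eligible <- trLib$read_id[trLib$end - trLib$start >= 18]
    expect_setequal(base, eligible)
})
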