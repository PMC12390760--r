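test_that("seed families are equivalence classes of identical 7-mers", {
    mi <- data.frame(name = c("m1", "m2", "m3"),
                     sequence = c("AACGTACGTTTTTTTTTTTT",
                                  "GACGTACGTAAAAAAAAAAA",   # same 2-8
                                  "AACGTACCTTTTTTTTTTTT")) # one seed change
    out <- assignFamilies(mi)
    expect_identical(out$family_id[1], out$family_id[2])
    expect_false(out$family_id[1] == out$family_id[3])
    ## family named after the lexicographically smallest member
    expect_identical(out$family_id[1], "m1")
    ## an explicit family map wins, unknown names are rejected
    fm <- data.frame(mirna = c("m1", "m2", "m3"),
                     family_id = c("famX", "famX", "famY"))
    expect_identical(assignFamilies(mi, fm)$family_id,
                     c("famX", "famX", "famY"))
    expect_error(assignFamilies(mi, data.frame(mirna = "nope",
                                               family_id = "f")),
                 "nope")
})

test_that("random miRNA partitions match brute-force seed grouping", {
    set.seed(61)
    mi <- data.frame(name = sprintf("m%02d", 1:50),
                     sequence = vapply(1:50, function(i) randDNA(21),
                                       character(1)))
    ## force some shared seeds
    for (i in seq(2, 50, by = 7))
        substr(mi$sequence[i], 2, 8) <- substr(mi$sequence[i - 1], 2, 8)
    out <- assignFamilies(mi)
    want <- unname(vapply(substr(mi$sequence, 2, 8), function(s)
        min(mi$name[substr(mi$sequence, 2, 8) == s]), character(1)))
    expect_identical(out$family_id, want)
})

test_that("the allowlist keeps exactly the named miRNAs", {
    fr <- makeFrags(data.frame(chrom = "chr1",
                               start = seq(0, 900, by = 100),
                               end = seq(40, 940, by = 100),
                               strand = "+",
                               mirna_tag = rep(c("mA", "mB", "mC", "mD",
                                                 "mE"), 2)))
    expect_identical(length(applyAllowlist(
        fr, c("mA", "mB", "mC", "mD", "mE"))$fragments), 10L)
    none <- applyAllowlist(fr, "mZ")
    expect_identical(length(none$fragments), 0L)
    expect_identical(none$removed, 10L)
    mixed <- applyAllowlist(fr, c("mA", "mC"))
    expect_identical(length(mixed$fragments),
                     sum(S4Vectors::mcols(fr)$mirna_tag %in% c("mA", "mC")))
    ## empty allowlist = keep all
    expect_identical(length(applyAllowlist(fr, character(0))$fragments),
                     10L)
})

test_that("family fractions are ranked, conserved and arithmetic", {
    mi <- data.frame(name = c("mA", "mB", "mC"),
                     sequence = c("AACGTACGTTTTTTTTTTTT",
                                  "GACGTACGTAAAAAAAAAAA",
                                  "AAAAAAACGTACGTTTTTTT"))
    mi <- assignFamilies(mi)
    tags <- c(rep("mA", 40), rep("mB", 20), rep("mC", 40))
    fr <- makeFrags(data.frame(chrom = "chr1",
                               start = seq_along(tags) * 100,
                               end = seq_along(tags) * 100 + 30,
                               strand = "+", mirna_tag = tags))
    fs <- familyFractions(fr, mi, topN = 1)
    ## mA and mB share a family: 60/40 split
    expect_equal(fs$fraction, c(0.6, 0.4))
    expect_identical(fs$rank, 1:2)
    expect_equal(attr(fs, "cumulative_top_n"), 0.6)
    expect_identical(sum(fs$count), length(tags))
    ## all fragments in one family
    one <- familyFractions(fr[1:40], mi, topN = 1)
    expect_equal(one$fraction, 1)
    expect_equal(attr(one, "cumulative_top_n"), 1)
    expect_warning(familyFractions(fr[0], mi), "no chimeric")
})

test_that("estimated fractions track simulated family weights", {
    set.seed(62)
    weights <- c(0.3, 0.25, 0.2, 0.15, 0.1)
    mi <- data.frame(name = sprintf("m%d", 1:5),
                     sequence = vapply(1:5, function(i) randDNA(20),
                                       character(1)))
    mi <- assignFamilies(mi)
    stopifnot(length(unique(mi$family_id)) == 5L)
    tags <- sample(mi$name, 20000, replace = TRUE, prob = weights)
    fr <- makeFrags(data.frame(chrom = "chr1",
                               start = seq_along(tags),
                               end = seq_along(tags) + 25,
                               strand = "+", mirna_tag = tags))
    fs <- familyFractions(fr, mi)
    got <- fs$fraction[match(mi$family_id, fs$family_id)]
    expect_true(all(abs(got - weights) <= 0.02))
})

test_that("fractions are invariant to within-family tag permutation", {
    mi <- data.frame(name = c("mA", "mB"),
                     sequence = c("AACGTACGTTTTTTTTTTTT",
                                  "GACGTACGTAAAAAAAAAAA"))
    mi <- assignFamilies(mi)
    tags1 <- c(rep("mA", 30), rep("mB", 10))
    tags2 <- c(rep("mB", 30), rep("mA", 10))   # tie-break flipped
    mk <- function(tags) makeFrags(data.frame(
        chrom = "chr1", start = seq_along(tags) * 50,
        end = seq_along(tags) * 50 + 30, strand = "+", mirna_tag = tags))
    f1 <- familyFractions(mk(tags1), mi)
    f2 <- familyFractions(mk(tags2), mi)
    expect_identical(f1$fraction, f2$fraction)
    expect_identical(f1$family_id, f2$family_id)
})
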