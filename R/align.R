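#' Build a k-mer seed index over a set of sequences
#'
#' Every length-k substring of every (forward-strand) sequence is hashed to
#' its positions; reverse-strand hits are handled at query time by looking
#' up seeds of the reverse-complemented read. Internally the sequences are
#' concatenated with N-padding so extension works on one string; reported
#' coordinates are 0-based half-open per sequence.
#'
#' @param sequences named character vector or \code{DNAStringSet}.
#' @param k seed length (>= 8 and at most the shortest sequence length).
#' @return an object of class \code{SeedIndex}.
#' @export
buildSeedIndex <- function(sequences, k = 16L) {
    if (methods::is(sequences, "DNAStringSet"))
        sequences <- setNames(as.character(sequences), names(sequences))
    stopifnot(length(sequences) >= 1L, k >= 8L)
    k <- as.integer(k)
    lens <- nchar(sequences)
    if (k > min(lens))
        stop("k longer than the shortest indexed sequence")
    pad <- strrep("N", k)
    cat <- paste(sequences, collapse = pad)
    offsets <- c(0L, cumsum(lens + k))[seq_along(sequences)]
    starts <- unlist(lapply(seq_along(sequences), function(i)
        offsets[i] + 0:(lens[i] - k)), use.names = FALSE)
    kmers <- substring(cat, starts + 1L, starts + k)
    dt <- data.table::data.table(kmer = kmers, pos = starts, key = "kmer")
    structure(list(dt = dt, k = as.integer(k), cat = cat,
                   names = names(sequences) %||%
                       as.character(seq_along(sequences)),
                   lengths = unname(lens), offsets = unname(offsets),
                   total = nchar(cat)),
              class = "SeedIndex")
}

#' Query a seed index for the positions of one k-mer
#' @param index a \code{SeedIndex}.
#' @param kmer a length-k string.
#' @return data.frame with \code{seq} (sequence name) and \code{pos}
#'   (0-based start); zero rows if absent.
#' @export
lookupKmer <- function(index, kmer) {
    stopifnot(nchar(kmer) == index$k)
    q <- data.table::data.table(kmer = kmer)
    hits <- index$dt[q, on = "kmer", nomatch = NULL]$pos
    if (!length(hits))
        return(data.frame(seq = character(0), pos = integer(0)))
    i <- findInterval(hits, index$offsets)
    data.frame(seq = index$names[i], pos = hits - index$offsets[i])
}

#' Map reads with k-mer seeding and ungapped extension
#'
#' Candidate loci are collected from exact seed hits at the read's first and
#' last k bases, on both strands, then scored by full-length ungapped
#' comparison. A read is \code{unique} when exactly one location attains the
#' minimal mismatch count (<= \code{maxMismatches}), \code{multi} when
#' several tie, otherwise \code{unmapped}. Reverse-complement hits report
#' the minus strand with the interval in forward coordinates.
#'
#' @param index a \code{SeedIndex} built by [buildSeedIndex()].
#' @param sequences character vector of reads (each >= k nt).
#' @param maxMismatches maximum substitutions allowed.
#' @return data.frame, one row per read: \code{status}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{mismatches}.
#' @export
mapReads <- function(index, sequences, maxMismatches = 2L) {
    k <- index$k
    n <- length(sequences)
    L <- nchar(sequences)
    if (any(L < k)) stop("all reads must be at least k nt long")
    rc <- revComp(sequences)

    collect <- function(base, off, strand) {
        km <- substr(base, off + 1L, off + k)
        q <- data.table::data.table(kmer = km, read = seq_len(n),
                                    off = off)
        hits <- index$dt[q, on = "kmer", nomatch = NULL,
                         allow.cartesian = TRUE]
        if (nrow(hits) == 0L)
            return(data.frame(read = integer(0), start = integer(0),
                              strand = character(0)))
        data.frame(read = hits$read, start = hits$pos - hits$off,
                   strand = strand)
    }
    zero <- integer(n)
    cand <- rbind(collect(sequences, zero, "+"),
                  collect(sequences, L - k, "+"),
                  collect(rc, zero, "-"),
                  collect(rc, L - k, "-"))
    res <- data.frame(status = rep("unmapped", n), chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, mismatches = NA_integer_)
    if (nrow(cand) == 0L) return(res)

    cand <- cand[cand$start >= 0L &
                 cand$start + L[cand$read] <= index$total, , drop = FALSE]
    ## stay inside one indexed sequence (no extension across N padding)
    ci <- findInterval(cand$start, index$offsets)
    ok <- cand$start + L[cand$read] <=
        index$offsets[ci] + index$lengths[ci]
    cand <- cand[ok, , drop = FALSE]; ci <- ci[ok]
    if (nrow(cand) == 0L) return(res)
    key <- paste(cand$read, cand$start, cand$strand)
    dup <- duplicated(key)
    cand <- cand[!dup, , drop = FALSE]; ci <- ci[!dup]

    g <- substring(index$cat, cand$start + 1L, cand$start + L[cand$read])
    q <- ifelse(cand$strand == "+", sequences[cand$read], rc[cand$read])
    mm <- countMismatches(g, q)
    keep <- mm <= maxMismatches
    cand <- cand[keep, , drop = FALSE]; ci <- ci[keep]; mm <- mm[keep]
    if (nrow(cand) == 0L) return(res)

    ord <- order(cand$read, mm, cand$start, cand$strand)
    cand <- cand[ord, , drop = FALSE]; ci <- ci[ord]; mm <- mm[ord]
    first <- !duplicated(cand$read)
    bestIdx <- which(first)
    bestRead <- cand$read[first]
    bestMM <- mm[first]
    nBest <- vapply(seq_along(bestIdx), function(j) {
        i <- bestIdx[j]
        cnt <- 1L
        while (i + cnt <= nrow(cand) && cand$read[i + cnt] == bestRead[j] &&
               mm[i + cnt] == bestMM[j]) cnt <- cnt + 1L
        cnt
    }, integer(1))

    res$status[bestRead] <- ifelse(nBest == 1L, "unique", "multi")
    uni <- bestRead[nBest == 1L]
    ui <- bestIdx[nBest == 1L]
    res$chrom[uni] <- index$names[ci[ui]]
    res$start[uni] <- cand$start[ui] - index$offsets[ci[ui]]
    res$end[uni] <- res$start[uni] + L[uni]
    res$strand[uni] <- cand$strand[ui]
    res$mismatches[uni] <- mm[ui]
    res
}

#' Map a single read (convenience wrapper)
#' @inheritParams mapReads
#' @param sequence one read sequence.
#' @return a one-row data.frame, see [mapReads()].
#' @export
mapRead <- function(index, sequence, maxMismatches = 2L) {
    mapReads(index, sequence, maxMismatches)
}

#' Remove reads that align to repeat/rRNA sequences
#'
#' Reads aligning to any repeat sequence with at most \code{maxMismatches}
#' substitutions (either strand, via the same seeded aligner) are removed
#' and counted; all others pass through unchanged. Repeat filtering
#' precedes genome mapping.
#'
#' @param reads data.frame with a \code{sequence} column.
#' @param repeatIndex \code{SeedIndex} over the repeat sequences.
#' @param maxMismatches maximum substitutions for a repeat hit.
#' @return list with \code{kept} (the surviving rows), \code{repeatHits}
#'   (count removed) and \code{log}.
#' @export
filterRepeats <- function(reads, repeatIndex, maxMismatches = 2L) {
    m <- mapReads(repeatIndex, reads$sequence, maxMismatches)
    hit <- m$status != "unmapped"
    list(kept = reads[!hit, , drop = FALSE],
         repeatHits = sum(hit),
         log = c(n_in = nrow(reads), kept = sum(!hit),
                 dropped_repeat = sum(hit)))
}

#' Extract repeat-interval sequences from a bundle
#' @param bundle a [GenomeBundle-class].
#' @return named character vector of repeat sequences.
#' @export
repeatSequences <- function(bundle) {
    rp <- repeatRanges(bundle)
    chromStrs <- as.character(chromosomes(bundle))
    s <- substring(chromStrs[as.character(GenomicRanges::seqnames(rp))],
                   GenomicRanges::start(rp), GenomicRanges::end(rp))
    setNames(s, S4Vectors::mcols(rp)$name)
}

#' @export
print.SeedIndex <- function(x, ...) {
    cat(sprintf("SeedIndex: %d sequence(s), %d bp, k = %d\n",
                length(x$names), sum(x$lengths), x$k))
    invisible(x)
}
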