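#' Detect chimeric reads by reverse-mapping mature miRNAs
#'
#' For reads that failed to map to the genome (after repeat filtering), the
#' 5' end of every mature miRNA is aligned ungapped to the 5' end of the
#' read. The best call is the longest match with at most
#' \code{maxMismatches} substitutions and at least \code{minMirnaMatch}
#' matched bases; ties are broken by fewest mismatches, then by the
#' lexicographically smallest miRNA name, with the equally scoring others
#' recorded in \code{ambiguous_with}. A read whose residual target fragment
#' is shorter than \code{minTargetLength} yields no call; a read fully
#' covered by the miRNA match is counted as miRNA-only and excluded from
#' target clustering.
#'
#' @param sequences character vector of genome-unmapped read sequences.
#' @param mirnas data.frame with \code{name} and \code{sequence} columns
#'   (e.g. \code{mirnaTable(bundle)}).
#' @param minMirnaMatch minimum matched miRNA prefix length (nt).
#' @param maxMismatches maximum substitutions within the matched prefix.
#' @param minTargetLength minimum residual target length (nt).
#' @param end \code{"5p"} (default) searches for the miRNA at the read's
#'   5' end, the miR-eCLIP ligation geometry; \code{"3p"} searches the
#'   read's 3' end (miRNA 3'-terminal bases against the read's last
#'   bases) for chemistries that ligate in the opposite orientation, with
#'   the residual target taken 5' of the match.
#' @return list with \code{calls} (data.frame: \code{read}, \code{mirna},
#'   \code{match_length}, \code{mismatches}, \code{target_start} (0-based
#'   offset within the read, equals \code{match_length}), \code{target},
#'   \code{ambiguous_with}) and \code{log} (named counts: \code{n_in},
#'   \code{called}, \code{no_call}, \code{mirna_only},
#'   \code{short_target}).
#' @export
detectChimeras <- function(sequences, mirnas, minMirnaMatch = 18L,
                           maxMismatches = 1L, minTargetLength = 18L,
                           end = c("5p", "3p")) {
    mirnas <- as.data.frame(mirnas)
    if (nrow(mirnas) == 0L)
        stop("empty miRNA set: chimera detection needs mature miRNAs")
    end <- match.arg(end)
    minMirnaMatch <- as.integer(minMirnaMatch)
    maxMismatches <- as.integer(maxMismatches)
    minTargetLength <- as.integer(minTargetLength)
    ord <- order(mirnas$name)
    mnames <- mirnas$name[ord]
    mraw <- lapply(mirnas$sequence[ord], charToRaw)
    if (end == "3p") mraw <- lapply(mraw, rev)
    mlens <- lengths(mraw)

    n <- length(sequences)
    outRead <- integer(0); outMir <- character(0); outLen <- integer(0)
    outMM <- integer(0); outAmb <- character(0)
    status <- rep("no_call", n)
    for (r in seq_len(n)) {
        rraw <- charToRaw(sequences[r])
        if (end == "3p") rraw <- rev(rraw)
        rl <- length(rraw)
        bestL <- -1L; bestMM <- NA_integer_; bestJ <- integer(0)
        for (j in seq_along(mraw)) {
            Lmax <- min(mlens[j], rl)
            if (Lmax < minMirnaMatch) next
            mm <- cumsum(rraw[seq_len(Lmax)] != mraw[[j]][seq_len(Lmax)])
            okL <- which(mm[minMirnaMatch:Lmax] <= maxMismatches)
            if (!length(okL)) next
            Lj <- minMirnaMatch + max(okL) - 1L
            mmJ <- mm[Lj]
            if (Lj > bestL || (Lj == bestL && mmJ < bestMM)) {
                bestL <- Lj; bestMM <- mmJ; bestJ <- j
            } else if (Lj == bestL && mmJ == bestMM) {
                bestJ <- c(bestJ, j)
            }
        }
        if (bestL < 0L) next
        if (bestL == rl) { status[r] <- "mirna_only"; next }
        if (rl - bestL < minTargetLength) { status[r] <- "short_target"; next }
        status[r] <- "called"
        outRead <- c(outRead, r)
        outMir <- c(outMir, mnames[bestJ[1L]])
        outLen <- c(outLen, bestL)
        outMM <- c(outMM, bestMM)
        outAmb <- c(outAmb, paste(mnames[bestJ[-1L]], collapse = ","))
    }
    targets <- if (end == "5p") {
        substr(sequences[outRead], outLen + 1L,
               nchar(sequences[outRead]))
    } else {
        substr(sequences[outRead], 1L,
               nchar(sequences[outRead]) - outLen)
    }
    calls <- data.frame(read = outRead, mirna = outMir,
                        match_length = outLen, mismatches = outMM,
                        target_start = if (length(outRead))
                            ifelse(rep(end == "5p", length(outRead)),
                                   outLen, 0L) else integer(0),
                        target = targets,
                        ambiguous_with = outAmb)
    list(calls = calls,
         log = c(n_in = n, called = sum(status == "called"),
                 no_call = sum(status == "no_call"),
                 mirna_only = sum(status == "mirna_only"),
                 short_target = sum(status == "short_target")))
}

#' Map chimera target fragments to the genome
#'
#' The miRNA portion of each called read is trimmed and the remaining
#' target fragment is mapped with the seeded aligner. Uniquely mapped
#' fragments become aligned fragments carrying a \code{mirna_tag};
#' multi-mapped and unmapped fragments are counted and dropped.
#'
#' @param calls the \code{calls} data.frame from [detectChimeras()].
#' @param index a \code{SeedIndex} over the genome.
#' @param meta data.frame aligned with \code{calls} rows (or with the reads
#'   they index via \code{calls$read}) providing \code{read_id},
#'   \code{umi}, \code{sample}, \code{role}, \code{replicate}.
#' @param maxMismatches maximum substitutions for target mapping.
#' @return list with \code{fragments} (a \code{GRanges} with metadata
#'   columns \code{read_id}, \code{umi}, \code{sample}, \code{role},
#'   \code{replicate}, \code{mirna_tag}, \code{mismatches}) and \code{log}.
#' @export
resolveChimeras <- function(calls, index, meta, maxMismatches = 2L) {
    if (nrow(calls) == 0L) {
        return(list(fragments = emptyFragments(index),
                    log = c(n_in = 0L, kept = 0L, dropped_multi = 0L,
                            dropped_unmapped = 0L)))
    }
    m <- mapReads(index, calls$target, maxMismatches)
    uni <- m$status == "unique"
    mi <- meta[calls$read[uni], , drop = FALSE]
    frag <- GenomicRanges::GRanges(
        m$chrom[uni],
        IRanges::IRanges(m$start[uni] + 1L, m$end[uni]),
        strand = m$strand[uni],
        read_id = mi$read_id, umi = mi$umi, sample = mi$sample,
        role = mi$role, replicate = mi$replicate,
        mirna_tag = calls$mirna[uni], mismatches = m$mismatches[uni])
    list(fragments = frag,
         log = c(n_in = nrow(calls), kept = sum(uni),
                 dropped_multi = sum(m$status == "multi"),
                 dropped_unmapped = sum(m$status == "unmapped")))
}

## An empty fragments GRanges with the interchange metadata columns.
emptyFragments <- function(index = NULL) {
    GenomicRanges::GRanges(character(0), IRanges::IRanges(),
        strand = character(0),
        read_id = character(0), umi = character(0), sample = character(0),
        role = character(0), replicate = integer(0),
        mirna_tag = character(0), mismatches = integer(0))
}
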