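#' UMI-based PCR deduplication of aligned fragments
#'
#' Fragments sharing (UMI, chromosome, start, strand) collapse to a single
#' representative, the first in read-id order; the number of removals is
#' attached as the \code{"removed"} attribute. Idempotent and
#' order-insensitive in survivor count.
#'
#' @param fragments a \code{GRanges} with metadata columns \code{umi} and
#'   \code{read_id}.
#' @return the surviving fragments (\code{GRanges}), attribute
#'   \code{removed}.
#' @export
deduplicateFragments <- function(fragments) {
    if (length(fragments) == 0L) {
        attr(fragments, "removed") <- 0L
        return(fragments)
    }
    umi <- S4Vectors::mcols(fragments)$umi
    if (is.null(umi) || anyNA(umi) || any(umi == ""))
        stop("fragment without a UMI: ",
             paste(head(S4Vectors::mcols(fragments)$read_id[
                 is.na(umi) | umi == ""], 3L), collapse = ", "))
    key <- paste(umi, GenomicRanges::seqnames(fragments),
                 GenomicRanges::start(fragments),
                 GenomicRanges::strand(fragments))
    ord <- order(S4Vectors::mcols(fragments)$read_id)
    keep <- ord[!duplicated(key[ord])]
    out <- fragments[sort(keep)]
    attr(out, "removed") <- length(fragments) - length(keep)
    out
}

#' Call raw clusters from deduplicated fragments
#'
#' Strand-aware single-linkage merge of fragments overlapping by at least
#' 1 bp (book-ended fragments are not merged). The cluster interval is the
#' union of member intervals; \code{ip_count} is the member count; when
#' fragments carry a \code{mirna_tag}, per-cluster miRNA tallies are
#' accumulated into a \code{mirna_counts} list column. This is a documented
#' simplified cluster caller standing in for heavier CLIP peak callers; the
#' reported selection criteria (read support, fold enrichment,
#' reproducibility) are applied downstream exactly.
#'
#' @param fragments a deduplicated \code{GRanges} from one library.
#' @return a \code{GRanges} of clusters with metadata columns
#'   \code{ip_count} and \code{mirna_counts}.
#' @export
callClusters <- function(fragments) {
    if (length(fragments) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            ip_count = integer(0), mirna_counts = I(list()))
        return(gr)
    }
    red <- GenomicRanges::reduce(fragments, min.gapwidth = 0L,
                                 with.revmap = TRUE,
                                 ignore.strand = FALSE)
    revmap <- S4Vectors::mcols(red)$revmap
    tags <- S4Vectors::mcols(fragments)$mirna_tag
    counts <- lapply(revmap, function(i) {
        t <- tags[i]
        t <- t[!is.na(t)]
        if (!length(t)) return(integer(0))
        tab <- table(t)
        setNames(as.integer(tab), names(tab))
    })
    S4Vectors::mcols(red) <- S4Vectors::DataFrame(
        ip_count = lengths(revmap), mirna_counts = I(counts))
    red
}

#' Score a set of clusters against the paired size-matched input
#'
#' Per cluster: \code{input_count} is the number of deduplicated input
#' fragments overlapping the interval on the same strand;
#' \code{ip_rpm = ip_count / ip_total * 1e6};
#' \code{log2fc = log2(((ip_count + 1) / ip_total) /
#' ((input_count + 1) / input_total))} (a +1 read pseudocount on both sides
#' handles empty input); \code{p_value} is the one-sided exact
#' (hypergeometric-tail) test for enrichment of the cluster's reads in the
#' IP library versus the input library.
#'
#' @param clusters \code{GRanges} from [callClusters()].
#' @param ipTotal deduplicated mapped fragment total of the IP library.
#' @param inputFragments deduplicated input fragments (\code{GRanges}).
#' @param inputTotal deduplicated mapped fragment total of the input
#'   library.
#' @return the clusters with added metadata columns \code{input_count},
#'   \code{ip_rpm}, \code{log2fc}, \code{p_value}.
#' @export
scorePeaks <- function(clusters, ipTotal, inputFragments, inputTotal) {
    if (ipTotal <= 0L || inputTotal <= 0L)
        stop("library totals must be positive")
    ip <- S4Vectors::mcols(clusters)$ip_count
    inp <- GenomicRanges::countOverlaps(clusters, inputFragments,
                                        ignore.strand = FALSE)
    S4Vectors::mcols(clusters)$input_count <- inp
    S4Vectors::mcols(clusters)$ip_rpm <- ip / ipTotal * 1e6
    S4Vectors::mcols(clusters)$log2fc <-
        log2(((ip + 1) / ipTotal) / ((inp + 1) / inputTotal))
    S4Vectors::mcols(clusters)$p_value <-
        enrichmentP(ip, ipTotal, inp, inputTotal)
    clusters
}

#' One-sided exact enrichment p-value for a 2x2 table
#'
#' The probability, under the hypergeometric null, of drawing at least
#' \code{ipCount} IP-library reads among the \code{ipCount + inputCount}
#' reads of the peak, given \code{ipTotal} IP and \code{inputTotal} input
#' reads overall (Fisher's exact test, alternative "IP enriched").
#'
#' @param ipCount,ipTotal,inputCount,inputTotal 2x2 table entries
#'   (vectorised).
#' @return numeric vector of p-values.
#' @export
enrichmentP <- function(ipCount, ipTotal, inputCount, inputTotal) {
    stats::phyper(ipCount - 1, ipTotal, inputTotal, ipCount + inputCount,
                  lower.tail = FALSE)
}

#' Threshold and reproducibility filtering of scored peaks
#'
#' A peak passes when \code{ip_count >= minReads} and
#' \code{log2fc > minLog2fc} (strict). A passing peak is reproducible iff a
#' passing peak of the other replicate overlaps it by >= 1 bp on the same
#' strand. Final peaks are the per-overlap-pair interval unions,
#' deduplicated, with miRNA tallies summed over the distinct contributing
#' peaks.
#'
#' @param peaksRep1,peaksRep2 scored peaks of the two replicates (each
#'   against its own input).
#' @param minReads minimum deduplicated IP fragments per peak.
#' @param minLog2fc log2 fold-change threshold (strict inequality).
#' @return \code{GRanges} of final peaks with metadata \code{ip_count}
#'   (summed), \code{input_count} (summed), \code{log2fc} (minimum of the
#'   contributing peaks), \code{p_value} (maximum), \code{mirna_counts},
#'   \code{reproducible = TRUE}.
#' @export
filterReproduciblePeaks <- function(peaksRep1, peaksRep2, minReads = 3L,
                                    minLog2fc = 3) {
    if (minReads <= 0L || minLog2fc <= 0)
        stop("thresholds must be positive")
    passing <- function(p) {
        mc <- S4Vectors::mcols(p)
        p[mc$ip_count >= minReads & mc$log2fc > minLog2fc]
    }
    p1 <- passing(peaksRep1); p2 <- passing(peaksRep2)
    empty <- function() {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            ip_count = integer(0), input_count = integer(0),
            log2fc = numeric(0), p_value = numeric(0),
            mirna_counts = I(list()), reproducible = logical(0))
        gr
    }
    if (length(p1) == 0L || length(p2) == 0L) return(empty())
    hits <- GenomicRanges::findOverlaps(p1, p2, minoverlap = 1L,
                                        ignore.strand = FALSE)
    if (length(hits) == 0L) return(empty())
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    us <- pmin(GenomicRanges::start(p1)[q], GenomicRanges::start(p2)[s])
    ue <- pmax(GenomicRanges::end(p1)[q], GenomicRanges::end(p2)[s])
    chrom <- as.character(GenomicRanges::seqnames(p1))[q]
    strand <- as.character(GenomicRanges::strand(p1))[q]
    key <- paste(chrom, us, ue, strand)
    m1 <- S4Vectors::mcols(p1); m2 <- S4Vectors::mcols(p2)
    out <- lapply(split(seq_along(key), key), function(i) {
        qi <- unique(q[i]); si <- unique(s[i])
        tallies <- c(m1$mirna_counts[qi], m2$mirna_counts[si])
        all <- unlist(tallies)
        mc <- if (is.null(all) || !length(all)) integer(0) else
            vapply(split(unname(all), names(all)), sum, integer(1))
        list(chrom = chrom[i[1L]], start = us[i[1L]], end = ue[i[1L]],
             strand = strand[i[1L]],
             ip_count = sum(m1$ip_count[qi]) + sum(m2$ip_count[si]),
             input_count = sum(m1$input_count[qi]) + sum(m2$input_count[si]),
             log2fc = min(m1$log2fc[qi], m2$log2fc[si]),
             p_value = max(m1$p_value[qi], m2$p_value[si]),
             mirna_counts = mc)
    })
    num <- function(field) vapply(out, function(x)
        as.numeric(x[[field]]), numeric(1))
    gr <- GenomicRanges::GRanges(
        vapply(out, `[[`, character(1), "chrom"),
        IRanges::IRanges(num("start"), num("end")),
        strand = vapply(out, `[[`, character(1), "strand"))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ip_count = as.integer(num("ip_count")),
        input_count = as.integer(num("input_count")),
        log2fc = num("log2fc"),
        p_value = num("p_value"),
        mirna_counts = I(lapply(out, `[[`, "mirna_counts")),
        reproducible = TRUE)
    GenomicRanges::sort(gr)
}
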