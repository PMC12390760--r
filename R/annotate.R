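#' Decompose transcript models into annotation features
#'
#' Protein-coding transcripts yield CDS, 5'/3' UTR (orientation follows the
#' transcript strand) and intron features; noncoding transcripts yield
#' nc_exon and nc_intron features. Malformed models (a CDS span outside the
#' exon union) raise an annotation build error.
#'
#' @param bundle a [GenomeBundle-class].
#' @return \code{GRanges} with metadata columns \code{category},
#'   \code{gene_id}, \code{transcript_id}.
#' @export
buildFeatureRanges <- function(bundle) {
    ti <- as.data.frame(transcriptInfo(bundle))
    ex <- exonRanges(bundle); cd <- cdsRanges(bundle)
    out <- list()
    for (i in seq_len(nrow(ti))) {
        tx <- ti$transcript_id[i]
        exi <- IRanges::ranges(ex[S4Vectors::mcols(ex)$transcript_id == tx])
        exi <- sort(exi)
        span <- range(exi)
        introns <- IRanges::setdiff(span, exi)
        add <- function(ir, category) {
            if (length(ir) == 0L) return(NULL)
            data.frame(chrom = ti$chrom[i],
                       start = IRanges::start(ir), end = IRanges::end(ir),
                       strand = ti$strand[i], category = category,
                       gene_id = ti$gene_id[i], transcript_id = tx)
        }
        if (ti$biotype[i] == "coding") {
            cdi <- IRanges::ranges(cd[tx])
            cdsParts <- IRanges::intersect(exi, cdi)
            if (sum(IRanges::width(cdsParts)) == 0L)
                stop(sprintf("annotation build error: CDS of %s outside exons",
                             tx))
            left <- IRanges::intersect(
                exi, IRanges::IRanges(IRanges::start(span),
                                      IRanges::start(cdi) - 1L))
            right <- IRanges::intersect(
                exi, IRanges::IRanges(IRanges::end(cdi) + 1L,
                                      IRanges::end(span)))
            utr5 <- if (ti$strand[i] == "+") left else right
            utr3 <- if (ti$strand[i] == "+") right else left
            out[[length(out) + 1L]] <- rbind(
                add(cdsParts, "CDS"), add(utr5, "UTR5"), add(utr3, "UTR3"),
                add(introns, "intron"))
        } else {
            out[[length(out) + 1L]] <- rbind(
                add(exi, "nc_exon"), add(introns, "nc_intron"))
        }
    }
    df <- do.call(rbind, out)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand, category = df$category,
                           gene_id = df$gene_id,
                           transcript_id = df$transcript_id)
}

#' Default feature priority of the annotation hierarchy
#'
#' Protein-coding features outrank noncoding ones; among UTRs the 3' UTR
#' comes first (the canonical location of miRNA sites). Peaks overlapping
#' nothing are "intergenic".
#' @export
featurePriority <- function() {
    c("CDS", "UTR3", "UTR5", "intron", "nc_exon", "nc_intron")
}

#' Annotate peaks with a genomic feature category
#'
#' Collects all same-strand features overlapping each peak by >= 1 bp and
#' assigns the highest-priority category present; the gene id comes from
#' the transcript supplying the winning feature (ties resolved to the
#' lexicographically smallest gene id). Peaks with no overlap are
#' \code{intergenic} with an empty gene id. A pure function of the peak
#' interval, strand and annotation set.
#'
#' @param peaks \code{GRanges} of peaks (stranded).
#' @param features \code{GRanges} from [buildFeatureRanges()].
#' @param priority character vector ordering the six feature categories.
#' @return the peaks with metadata columns \code{annotation} and
#'   \code{gene_id} added.
#' @export
annotatePeaks <- function(peaks, features, priority = featurePriority()) {
    ann <- rep("intergenic", length(peaks))
    gene <- rep("", length(peaks))
    if (length(peaks)) {
        hits <- GenomicRanges::findOverlaps(peaks, features,
                                            minoverlap = 1L,
                                            ignore.strand = FALSE)
        if (length(hits)) {
            q <- S4Vectors::queryHits(hits)
            fm <- S4Vectors::mcols(features)
            rank <- match(fm$category[S4Vectors::subjectHits(hits)],
                          priority)
            g <- fm$gene_id[S4Vectors::subjectHits(hits)]
            ord <- order(q, rank, g)
            first <- !duplicated(q[ord])
            qf <- q[ord][first]
            ann[qf] <- priority[rank[ord][first]]
            gene[qf] <- g[ord][first]
        }
    }
    S4Vectors::mcols(peaks)$annotation <- ann
    S4Vectors::mcols(peaks)$gene_id <- gene
    peaks
}

#' Feature distribution of annotated peaks
#'
#' Per group (by default sample x peak type), the fraction of peaks in each
#' category. Fractions sum to 1 within each non-empty group; empty groups
#' are emitted with zero counts.
#'
#' @param peaks data.frame with an \code{annotation} column plus the
#'   grouping columns.
#' @param by character vector of grouping column names.
#' @param categories category universe (default: the six hierarchy classes
#'   plus intergenic).
#' @return data.frame with group columns, \code{category}, \code{count},
#'   \code{fraction}.
#' @export
featureDistribution <- function(peaks, by = c("sample", "peak_type"),
                                categories = c(featurePriority(),
                                               "intergenic")) {
    peaks <- as.data.frame(peaks)
    groups <- unique(peaks[, by, drop = FALSE])
    if (nrow(groups) == 0L) {
        res <- cbind(as.data.frame(setNames(rep(list(character(0)),
                                                length(by)), by)),
                     data.frame(category = character(0),
                                count = integer(0), fraction = numeric(0)))
        return(res)
    }
    out <- list()
    for (i in seq_len(nrow(groups))) {
        sel <- rep(TRUE, nrow(peaks))
        for (b in by) sel <- sel & peaks[[b]] == groups[[b]][i]
        cnt <- table(factor(peaks$annotation[sel], levels = categories))
        total <- sum(cnt)
        res <- cbind(groups[rep(i, length(categories)), , drop = FALSE],
                     data.frame(category = categories,
                                count = as.integer(cnt),
                                fraction = if (total > 0)
                                    as.integer(cnt) / total else 0))
        out[[i]] <- res
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
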