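#' GenomeBundle: a toy genome with annotation, repeats and miRNAs
#'
#' The coordinate substrate for simulation, alignment and annotation. It
#' holds chromosome sequences, transcript models (exons plus an optional
#' CDS span per coding transcript), repeat/rRNA-like intervals and a mature
#' miRNA table with seed-family assignments. All internal coordinates are
#' 0-based half-open; GRanges slots store the equivalent 1-based closed
#' ranges, the convention of the Bioconductor stack.
#'
#' @slot chromosomes \code{DNAStringSet} of chromosome sequences, unique names.
#' @slot exons \code{GRanges} of exons with metadata columns
#'   \code{transcript_id} and \code{gene_id}.
#' @slot cds \code{GRanges} of CDS genomic spans, one per coding transcript,
#'   names are transcript ids, metadata column \code{gene_id}.
#' @slot txInfo \code{DataFrame} with columns \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{biotype}
#'   ("coding" or "noncoding").
#' @slot repeats \code{GRanges} of repetitive/rRNA-like intervals.
#' @slot mirnas \code{DataFrame} with columns \code{name}, \code{sequence},
#'   \code{seed} (the 7-mer at positions 2-8), \code{family_id},
#'   \code{allowlisted}.
#'
#' @seealso [makeGenome()] which constructs bundles,
#'   [writeGenomeBundle()] / [readGenomeBundle()] for on-disk form.
#' @export
setClass("GenomeBundle",
    slots = c(
        chromosomes = "DNAStringSet",
        exons       = "GRanges",
        cds         = "GRanges",
        txInfo      = "DFrame",
        repeats     = "GRanges",
        mirnas      = "DFrame"
    )
)

validGenomeBundle <- function(object) {
    msg <- character(0)
    chromNames <- names(object@chromosomes)
    if (is.null(chromNames) || anyDuplicated(chromNames))
        msg <- c(msg, "chromosome names must be present and unique")
    lens <- setNames(Biostrings::width(object@chromosomes), chromNames)

    checkWithin <- function(gr, what) {
        sn <- as.character(GenomicRanges::seqnames(gr))
        if (!all(sn %in% chromNames))
            return(sprintf("%s on unknown chromosome", what))
        bad <- GenomicRanges::start(gr) < 1L |
            GenomicRanges::end(gr) > lens[sn]
        if (any(bad))
            return(sprintf("%s outside chromosome bounds", what))
        NULL
    }
    msg <- c(msg, checkWithin(object@exons, "exons"),
             checkWithin(object@repeats, "repeats"))

    ti <- object@txInfo
    need <- c("transcript_id", "gene_id", "chrom", "strand", "biotype")
    if (!all(need %in% colnames(ti))) {
        msg <- c(msg, "txInfo misses required columns")
    } else {
        if (anyDuplicated(ti$transcript_id))
            msg <- c(msg, "transcript ids must be unique")
        if (!all(ti$biotype %in% c("coding", "noncoding")))
            msg <- c(msg, "biotype must be coding or noncoding")
        coding <- ti$transcript_id[ti$biotype == "coding"]
        cdsTx <- names(object@cds)
        if (!all(cdsTx %in% coding))
            msg <- c(msg, "CDS present for a noncoding transcript")
        ## exons sorted & disjoint per transcript; CDS inside exon span
        exTx <- split(IRanges::ranges(object@exons),
                      S4Vectors::mcols(object@exons)$transcript_id)
        if (!all(vapply(exTx, IRanges::isDisjoint, logical(1))))
            msg <- c(msg, "exons of a transcript must be pairwise disjoint")
        for (tx in cdsTx) {
            ir <- exTx[[tx]]
            cd <- object@cds[tx]
            hit <- IRanges::overlapsAny(
                IRanges::IRanges(c(GenomicRanges::start(cd),
                                   GenomicRanges::end(cd)), width = 1L), ir)
            if (!all(hit))
                msg <- c(msg, sprintf("CDS of %s not within exons", tx))
        }
    }

    mi <- object@mirnas
    needM <- c("name", "sequence", "seed", "family_id", "allowlisted")
    if (!all(needM %in% colnames(mi))) {
        msg <- c(msg, "mirnas misses required columns")
    } else if (nrow(mi)) {
        if (anyDuplicated(mi$name))
            msg <- c(msg, "miRNA names must be unique")
        if (!all(nchar(mi$sequence) >= 18 & nchar(mi$sequence) <= 24))
            msg <- c(msg, "miRNA sequences must be 18-24 nt")
        if (!all(mi$seed == substr(mi$sequence, 2L, 8L)))
            msg <- c(msg, "seed must equal positions 2-8 of the sequence")
        perFam <- vapply(split(mi$seed, mi$family_id),
                         function(s) length(unique(s)) == 1L, logical(1))
        if (!all(perFam))
            msg <- c(msg, "members of one family must share an identical seed")
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenomeBundle", validGenomeBundle)

#' @describeIn GenomeBundle constructor from pre-built slots
#' @param chromosomes,exons,cds,txInfo,repeats,mirnas see slots
#' @export
GenomeBundle <- function(chromosomes, exons, cds, txInfo, repeats, mirnas) {
    si <- GenomeInfoDb::Seqinfo(names(chromosomes),
                                Biostrings::width(chromosomes))
    for (nm in c("exons", "cds", "repeats")) {
        gr <- get(nm)
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
        GenomeInfoDb::seqinfo(gr) <- si
        assign(nm, gr)
    }
    new("GenomeBundle", chromosomes = chromosomes, exons = exons, cds = cds,
        txInfo = S4Vectors::DataFrame(txInfo),
        repeats = repeats, mirnas = S4Vectors::DataFrame(mirnas))
}

#' @rdname GenomeBundle-accessors
#' @param x a \code{GenomeBundle}
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname GenomeBundle-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname GenomeBundle-accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @rdname GenomeBundle-accessors
#' @export
setGeneric("transcriptInfo", function(x) standardGeneric("transcriptInfo"))
#' @rdname GenomeBundle-accessors
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))
#' @rdname GenomeBundle-accessors
#' @export
setGeneric("mirnaTable", function(x) standardGeneric("mirnaTable"))

#' Accessors for GenomeBundle slots
#'
#' @name GenomeBundle-accessors
#' @param x a \code{GenomeBundle}
#' @return the corresponding slot
NULL

#' @rdname GenomeBundle-accessors
#' @export
setMethod("chromosomes", "GenomeBundle", function(x) x@chromosomes)
#' @rdname GenomeBundle-accessors
#' @export
setMethod("exonRanges", "GenomeBundle", function(x) x@exons)
#' @rdname GenomeBundle-accessors
#' @export
setMethod("cdsRanges", "GenomeBundle", function(x) x@cds)
#' @rdname GenomeBundle-accessors
#' @export
setMethod("transcriptInfo", "GenomeBundle", function(x) x@txInfo)
#' @rdname GenomeBundle-accessors
#' @export
setMethod("repeatRanges", "GenomeBundle", function(x) x@repeats)
#' @rdname GenomeBundle-accessors
#' @export
setMethod("mirnaTable", "GenomeBundle", function(x) x@mirnas)

setMethod("show", "GenomeBundle", function(object) {
    ti <- object@txInfo
    cat("GenomeBundle\n")
    cat(sprintf("  %d chromosome(s), total %d bp\n",
                length(object@chromosomes),
                sum(Biostrings::width(object@chromosomes))))
    cat(sprintf("  %d gene(s): %d coding, %d noncoding transcript(s)\n",
                length(unique(ti$gene_id)),
                sum(ti$biotype == "coding"), sum(ti$biotype == "noncoding")))
    cat(sprintf("  %d repeat interval(s)\n", length(object@repeats)))
    cat(sprintf("  %d miRNA(s) in %d seed famil(ies)\n",
                nrow(object@mirnas), length(unique(object@mirnas$family_id))))
})
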