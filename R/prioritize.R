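#' Count chimeric 3' UTR final peaks per gene and fraction
#'
#' Only peaks annotated UTR3 with \code{peak_type == "chimeric"} are
#' counted, grouped by gene and subcellular fraction.
#'
#' @param peaks data.frame of final peaks with columns \code{gene_id},
#'   \code{annotation}, \code{peak_type}, \code{sample}.
#' @param fractions fraction labels forming the count-table columns.
#' @param genes optional gene universe; defaults to the genes present in
#'   the filtered peaks. Genes without any qualifying peak get a row of
#'   zeros.
#' @return data.frame with \code{gene_id} and one integer column per
#'   fraction.
#' @export
countUtr3ChimericPeaks <- function(peaks,
                                   fractions = c("cytoplasm", "nucleus",
                                                 "chromatin"),
                                   genes = NULL) {
    peaks <- as.data.frame(peaks)
    sel <- peaks$annotation == "UTR3" & peaks$peak_type == "chimeric"
    peaks <- peaks[sel, , drop = FALSE]
    if (is.null(genes)) genes <- sort(unique(peaks$gene_id))
    out <- data.frame(gene_id = genes)
    for (f in fractions) {
        cnt <- table(factor(peaks$gene_id[peaks$sample == f],
                            levels = genes))
        out[[f]] <- as.integer(cnt)
    }
    out
}

#' Select candidate genes for experimental follow-up
#'
#' A gene is selected when it satisfies both criteria: (i) more than five
#' chimeric 3' UTR peaks in at least one fraction, or at least one chimeric
#' 3' UTR peak in every fraction; and (ii) altered expression between
#' wild-type and miRNA-depleted (DROSHA-knockout) cells, operationalized as
#' \code{|log2fc| >= minAbsLog2fc} together with a significance flag from
#' the expression table. Genes absent from the expression table are flagged
#' \code{expression_unknown} and never selected. Output is sorted by the
#' maximum per-fraction UTR3 count (descending), then gene id.
#'
#' @param countTable output of [countUtr3ChimericPeaks()].
#' @param expressionTable data.frame with \code{gene_id}, \code{log2fc},
#'   \code{significant} (0/1 or logical).
#' @param minAbsLog2fc expression-change threshold.
#' @param fractions the fraction set over which the criteria run.
#' @param strictGt5 if TRUE (default), criterion (i) reads "> 5" strictly;
#'   FALSE switches to ">= 5".
#' @return data.frame with per-gene counts, \code{any_fraction_gt5},
#'   \code{all_fractions_ge1}, \code{expr_log2fc}, \code{expr_significant},
#'   \code{expression_unknown}, \code{selected}.
#' @export
selectCandidates <- function(countTable, expressionTable,
                             minAbsLog2fc = 1,
                             fractions = c("cytoplasm", "nucleus",
                                           "chromatin"),
                             strictGt5 = TRUE) {
    stopifnot(all(fractions %in% colnames(countTable)))
    counts <- as.matrix(countTable[, fractions, drop = FALSE])
    gt5 <- if (strictGt5) apply(counts > 5L, 1L, any)
           else apply(counts >= 5L, 1L, any)
    all1 <- apply(counts >= 1L, 1L, all)
    i <- match(countTable$gene_id, expressionTable$gene_id)
    unknown <- is.na(i)
    lfc <- expressionTable$log2fc[i]
    sig <- as.logical(expressionTable$significant[i])
    altered <- !unknown & abs(lfc) >= minAbsLog2fc & sig
    out <- cbind(countTable,
                 data.frame(any_fraction_gt5 = gt5,
                            all_fractions_ge1 = all1,
                            expr_log2fc = lfc,
                            expr_significant = sig,
                            expression_unknown = unknown,
                            selected = (gt5 | all1) & altered))
    out <- out[order(-apply(counts, 1L, max), out$gene_id), ]
    rownames(out) <- NULL
    out
}
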