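#' A qPCR Ct record
#'
#' One sample x primer-set measurement with technical-replicate Ct values.
#' Technical replicates are averaged on the cycle scale before any
#' exponentiation (the standard convention).
#'
#' @param sample_id sample identifier.
#' @param condition condition label (e.g. WT, DROSHA_KO).
#' @param primer_set primer-set label.
#' @param target_role one of target, reference, inclusion, skipping,
#'   full_length.
#' @param ct numeric vector of technical-replicate Ct values (cycles, > 0).
#' @return a list of class \code{CtRecord}.
#' @export
ctRecord <- function(sample_id, condition, primer_set, target_role, ct) {
    roles <- c("target", "reference", "inclusion", "skipping", "full_length")
    if (!target_role %in% roles)
        stop("target_role must be one of ", paste(roles, collapse = ", "))
    ct <- as.numeric(ct)
    if (length(ct) == 0L || any(!is.finite(ct)) || any(ct <= 0))
        stop("ct values must be a non-empty vector of positive cycles")
    structure(list(sample_id = sample_id, condition = condition,
                   primer_set = primer_set, target_role = target_role,
                   ct = ct),
              class = "CtRecord")
}

meanCt <- function(x) {
    stopifnot(inherits(x, "CtRecord"))
    mean(x$ct)
}

#' Relative expression by the 2^-ddCt method
#'
#' \code{ddCt = (Ct_target - Ct_reference) - (Ct_target_ctrl -
#' Ct_reference_ctrl)}; the returned fold change is \code{2^-ddCt}. The
#' reference records carry the internal control gene (RPL19 in the assays
#' this reproduces); amplification efficiency is fixed at 2.
#'
#' @param target,reference CtRecords of the experimental sample.
#' @param targetCtrl,referenceCtrl CtRecords of the control sample.
#' @return the fold change (numeric scalar).
#' @export
relativeExpression <- function(target, reference, targetCtrl,
                               referenceCtrl) {
    for (x in list(target, reference, targetCtrl, referenceCtrl))
        if (!inherits(x, "CtRecord")) stop("inputs must be CtRecords")
    if (reference$target_role != "reference" ||
        referenceCtrl$target_role != "reference")
        stop("missing reference record")
    ddct <- (meanCt(target) - meanCt(reference)) -
        (meanCt(targetCtrl) - meanCt(referenceCtrl))
    2^-ddct
}

#' Exon inclusion:skipping ratio
#'
#' \code{2^-(Ct_inclusion - Ct_skipping)} from the same sample; when a
#' full-length normalization factor is supplied (the relative abundance
#' measured with the full-length primer set), the ratio is additionally
#' divided by it and both values are returned.
#'
#' @param inclusion,skipping CtRecords with the matching roles.
#' @param fullLengthNorm optional positive normalization factor.
#' @return list with \code{raw} and \code{normalized} (NA when no factor
#'   given).
#' @export
splicingRatio <- function(inclusion, skipping, fullLengthNorm = NULL) {
    if (!inherits(inclusion, "CtRecord") || !inherits(skipping, "CtRecord"))
        stop("inputs must be CtRecords")
    if (inclusion$target_role != "inclusion" ||
        skipping$target_role != "skipping")
        stop("role mismatch: need inclusion and skipping records")
    raw <- 2^-(meanCt(inclusion) - meanCt(skipping))
    norm <- NA_real_
    if (!is.null(fullLengthNorm)) {
        stopifnot(is.numeric(fullLengthNorm), fullLengthNorm > 0)
        norm <- raw / fullLengthNorm
    }
    list(raw = raw, normalized = norm)
}

#' Two-sample Student's t-test (pooled variance, two-tailed)
#'
#' The classical equal-variance t statistic computed in closed form.
#' Degenerate pooled variance with equal means returns t = 0, p = 1;
#' with different means t is infinite and p is 0.
#'
#' @param a,b numeric vectors of biological replicates (each n >= 2).
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
twoSampleTest <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2L || n2 < 2L)
        stop("each group needs at least 2 biological replicates")
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
    delta <- mean(a) - mean(b)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t <- if (se == 0) {
        if (delta == 0) 0 else sign(delta) * Inf
    } else delta / se
    p <- 2 * stats::pt(-abs(t), df)
    list(statistic = t, df = df, p.value = p)
}

#' Read a Ct table from TSV into CtRecords
#'
#' Expected columns: \code{sample_id}, \code{condition},
#' \code{primer_set}, \code{target_role}, then one or more \code{ct_rep*}
#' columns (NA cells are dropped per record).
#'
#' @param path TSV path.
#' @return list of [ctRecord()] objects.
#' @export
readCtTable <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    ctCols <- grep("^ct_rep", colnames(df), value = TRUE)
    if (!length(ctCols)) stop("no ct_rep* columns in ", path)
    lapply(seq_len(nrow(df)), function(i) {
        ct <- as.numeric(df[i, ctCols])
        ctRecord(df$sample_id[i], df$condition[i], df$primer_set[i],
                 df$target_role[i], ct[!is.na(ct)])
    })
}
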