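#' Extract 5' UMIs from reads
#'
#' Moves the first \code{umiLength} bases of each read into a UMI field and
#' appends it to the read id after \code{delim}, so downstream deduplication
#' can recover it from FASTQ alone. Reads shorter than \code{umiLength + 1}
#' are dropped and counted.
#'
#' @param reads data.frame with \code{read_id}, \code{sequence},
#'   \code{quality}.
#' @param umiLength UMI length in nt; 0 leaves reads unchanged (empty UMI).
#' @param delim delimiter between original id and UMI.
#' @return list with \code{reads} (columns as input plus \code{umi}) and
#'   \code{log} (named counts: \code{n_in}, \code{kept},
#'   \code{dropped_short}).
#' @export
extractUMIs <- function(reads, umiLength = 10L, delim = "_") {
    n <- nrow(reads)
    if (umiLength == 0L) {
        reads$umi <- ""
        return(list(reads = reads,
                    log = c(n_in = n, kept = n, dropped_short = 0L)))
    }
    keep <- nchar(reads$sequence) > umiLength
    out <- reads[keep, , drop = FALSE]
    out$umi <- substr(out$sequence, 1L, umiLength)
    out$read_id <- paste0(out$read_id, delim, out$umi)
    out$sequence <- substr(out$sequence, umiLength + 1L,
                           nchar(out$sequence))
    out$quality <- substr(out$quality, umiLength + 1L, nchar(out$quality))
    list(reads = out,
         log = c(n_in = n, kept = sum(keep),
                 dropped_short = n - sum(keep)))
}

#' Trim 3' adapters from read sequences
#'
#' Ungapped adapter matching: at each start position the read is compared to
#' the adapter prefix of the available overlap length; the earliest position
#' with overlap >= \code{minOverlap} and mismatch rate <=
#' \code{maxMismatchRate} wins, which removes the longest qualifying suffix.
#' A full internal adapter occurrence removes everything from its first
#' qualifying position onward. No match is a valid no-op.
#'
#' @param sequences character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param minOverlap minimum overlap in nt (>= 1).
#' @param maxMismatchRate maximum fraction of mismatching bases in the
#'   compared window.
#' @return character vector of trimmed sequences (same length as input).
#' @export
trimAdapters <- function(sequences, adapter, minOverlap = 3L,
                         maxMismatchRate = 0.1) {
    stopifnot(nchar(adapter) >= 1L, minOverlap >= 1L)
    A <- nchar(adapter)
    araw <- charToRaw(adapter)
    out <- sequences
    for (l in unique(nchar(sequences))) {
        if (l < minOverlap) next
        idx <- which(nchar(sequences) == l)
        m <- length(idx)
        ## l x m raw matrix of read bases
        M <- matrix(charToRaw(paste(sequences[idx], collapse = "")),
                    nrow = l)
        cut <- rep(NA_integer_, m)
        for (i in seq_len(l - minOverlap + 1L)) {
            ov <- min(l - i + 1L, A)
            if (ov < minOverlap) break
            mm <- colSums(M[i:(i + ov - 1L), , drop = FALSE] !=
                          araw[seq_len(ov)])
            hit <- is.na(cut) & mm <= maxMismatchRate * ov + 1e-9
            cut[hit] <- i
        }
        trim <- which(!is.na(cut))
        if (length(trim))
            out[idx[trim]] <- substr(sequences[idx[trim]], 1L,
                                     cut[trim] - 1L)
    }
    out
}

#' Preprocess a read table: UMI extraction, adapter trimming, length filter
#'
#' The first stages of the pipeline. Reads shorter than \code{minLength}
#' after trimming are discarded (too short to map or to contain a miRNA).
#'
#' @param reads data.frame with \code{read_id}, \code{sequence},
#'   \code{quality}.
#' @param umiLength,delim see [extractUMIs()].
#' @param adapter,minOverlap,maxMismatchRate see [trimAdapters()].
#' @param minLength minimum post-trim length in nt.
#' @return list with \code{reads} and a named \code{log} vector
#'   (\code{n_in}, \code{kept}, \code{dropped_no_umi},
#'   \code{dropped_short}).
#' @export
preprocessReads <- function(reads, umiLength = 10L, delim = "_",
                            adapter = "AGATCGGAAGAGCACACGTCT",
                            minOverlap = 3L, maxMismatchRate = 0.1,
                            minLength = 18L) {
    n <- nrow(reads)
    eu <- extractUMIs(reads, umiLength, delim)
    r <- eu$reads
    r$sequence <- trimAdapters(r$sequence, adapter, minOverlap,
                               maxMismatchRate)
    r$quality <- substr(r$quality, 1L, nchar(r$sequence))
    keep <- nchar(r$sequence) >= minLength
    list(reads = r[keep, , drop = FALSE],
         log = c(n_in = n,
                 kept = sum(keep),
                 dropped_no_umi = unname(eu$log["dropped_short"]),
                 dropped_short = sum(!keep)))
}
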