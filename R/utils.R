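## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## keyed data.table joins back the seed index
.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#' @param n length in nucleotides
#' @return a single character string over A/C/G/T
#' @keywords internal
randomDNA <- function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a character vector of DNA sequences
#' @param x character vector (A/C/G/T)
#' @return character vector of reverse complements
#' @export
revComp <- function(x) {
    if (length(x) == 0L) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Per-pair Hamming distance between equal-length strings. Fast path:
## string equality gives 0; only unequal pairs are compared byte-wise.
countMismatches <- function(a, b) {
    stopifnot(length(a) == length(b))
    out <- integer(length(a))
    ne <- which(a != b)
    if (length(ne)) {
        out[ne] <- mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)),
                          a[ne], b[ne], USE.NAMES = FALSE)
    }
    out
}

## Chop one long string into fixed-width pieces (vectorised UMI generation).
chopString <- function(x, width) {
    n <- nchar(x) %/% width
    if (n == 0L) return(character(0))
    from <- seq.int(1L, by = width, length.out = n)
    substring(x, from, from + width - 1L)
}

## Strip a "_<umi>" suffix appended to read ids by UMI extraction.
stripUmiSuffix <- function(ids, delim = "_") {
    sub(paste0("\\", delim, "[ACGTN]*$"), "", ids)
}

## Format a named integer vector as "name:count;name:count".
formatTally <- function(x) {
    if (is.null(x) || length(x) == 0L) return("")
    paste(sprintf("%s:%d", names(x), as.integer(x)), collapse = ";")
}
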