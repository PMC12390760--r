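#' Group miRNAs into seed families
#'
#' Without a family map, families are equivalence classes of identical
#' seeds, named after the lexicographically smallest member; with a map
#' (data.frame \code{mirna}, \code{family_id}), the map is used as given.
#' The seed window defaults to positions 2-8 (7-mer), the prevailing family
#' definition; positions 2-7 are available for the 6-mer convention.
#'
#' @param mirnas data.frame with \code{name} and \code{sequence} columns.
#' @param familyMap optional data.frame with columns \code{mirna},
#'   \code{family_id}.
#' @param seedWindow integer pair, 1-based positions of the seed.
#' @return \code{mirnas} with \code{seed} and \code{family_id} columns set.
#' @export
assignFamilies <- function(mirnas, familyMap = NULL,
                           seedWindow = c(2L, 8L)) {
    mirnas <- as.data.frame(mirnas)
    stopifnot(all(nchar(mirnas$sequence) >= seedWindow[2L]))
    mirnas$seed <- substr(mirnas$sequence, seedWindow[1L], seedWindow[2L])
    if (!is.null(familyMap)) {
        unknown <- setdiff(familyMap$mirna, mirnas$name)
        if (length(unknown))
            stop("family map names unknown miRNA(s): ",
                 paste(unknown, collapse = ", "))
        mirnas$family_id <- familyMap$family_id[
            match(mirnas$name, familyMap$mirna)]
    } else {
        fam <- vapply(split(mirnas$name, mirnas$seed), min, character(1))
        mirnas$family_id <- unname(fam[mirnas$seed])
    }
    mirnas
}

#' Restrict chimeric fragments to an allowlist of miRNAs
#'
#' Mirrors the restriction of chimeric peaks to miRNAs present in a curated
#' database (miRGeneDB-style). An empty allowlist keeps everything (logged
#' as a no-op by callers).
#'
#' @param fragments \code{GRanges} with a \code{mirna_tag} metadata column.
#' @param allowlist character vector of miRNA names; empty keeps all.
#' @return list with \code{fragments} (retained) and \code{removed}
#'   (count).
#' @export
applyAllowlist <- function(fragments, allowlist) {
    if (length(allowlist) == 0L)
        return(list(fragments = fragments, removed = 0L))
    keep <- S4Vectors::mcols(fragments)$mirna_tag %in% allowlist
    list(fragments = fragments[keep], removed = sum(!keep))
}

#' Family-level chimeric read fractions
#'
#' Per-family counts of deduplicated chimeric fragments, fractions of the
#' total, descending ranks, and the cumulative fraction of the top
#' \code{topN} families. Fractions are invariant to within-family tie
#' breaks made by chimera detection, since same-seed ambiguity never
#' crosses family lines.
#'
#' @param fragments deduplicated chimeric \code{GRanges} with
#'   \code{mirna_tag}.
#' @param mirnas data.frame with \code{name}, \code{family_id},
#'   \code{seed}.
#' @param topN how many top families the cumulative fraction covers.
#' @return data.frame \code{family_id}, \code{seed}, \code{members},
#'   \code{count}, \code{fraction}, \code{rank}; attribute
#'   \code{cumulative_top_n} holds the cumulative fraction of the top
#'   \code{topN} families.
#' @export
familyFractions <- function(fragments, mirnas, topN = 8L) {
    mirnas <- as.data.frame(mirnas)
    tags <- S4Vectors::mcols(fragments)$mirna_tag
    tags <- tags[!is.na(tags)]
    if (length(tags) == 0L) {
        warning("no chimeric fragments: empty family summary")
        out <- data.frame(family_id = character(0), seed = character(0),
                          members = character(0), count = integer(0),
                          fraction = numeric(0), rank = integer(0))
        attr(out, "cumulative_top_n") <- NA_real_
        return(out)
    }
    fam <- mirnas$family_id[match(tags, mirnas$name)]
    if (anyNA(fam))
        stop("fragment carries an unknown miRNA tag: ",
             paste(unique(tags[is.na(fam)]), collapse = ", "))
    cnt <- table(fam)
    out <- data.frame(family_id = names(cnt), count = as.integer(cnt))
    out$seed <- mirnas$seed[match(out$family_id, mirnas$family_id)]
    out$members <- vapply(out$family_id, function(f)
        paste(sort(mirnas$name[mirnas$family_id == f]), collapse = ","),
        character(1))
    out$fraction <- out$count / sum(out$count)
    out <- out[order(-out$count, out$family_id), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out <- out[, c("family_id", "seed", "members", "count", "fraction",
                   "rank")]
    attr(out, "cumulative_top_n") <-
        sum(out$fraction[seq_len(min(topN, nrow(out)))])
    out
}
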