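#' @keywords internal
"_PACKAGE"

## Rank dialect used by MetaPhlAn-style lineage strings, ordered from the
## root of the taxonomy downwards.
.rank_prefixes <- c(
  kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
  family = "f__", genus = "g__", species = "s__", strain = "t__"
)

#' Parse a rank-prefixed taxonomic lineage string
#'
#' Lineages follow the MetaPhlAn / curatedMetagenomicData dialect:
#' rank-prefixed names joined by a separator, e.g.
#' `"k__Bacteria|p__Firmicutes|...|s__Faecalibacterium_prausnitzii"`.
#'
#' @param x character vector of lineage strings.
#' @param sep separator between rank fields (default `"|"`).
#' @return A list with one element per lineage, each a named character
#'   vector of taxon names indexed by rank
#'   (`kingdom`, `phylum`, ..., `species`, `strain`).
#' @examples
#' parse_lineage("k__Bacteria|p__Firmicutes|s__x")
#' @export
parse_lineage <- function(x, sep = "|") {
  stopifnot(is.character(x))
  lapply(x, function(s) {
    fields <- strsplit(s, sep, fixed = TRUE)[[1]]
    if (length(fields) == 0L || any(!nzchar(fields)))
      stop("empty field in lineage '", s, "'", call. = FALSE)
    prefixes <- substr(fields, 1L, 3L)
    ranks <- names(.rank_prefixes)[match(prefixes, .rank_prefixes)]
    if (anyNA(ranks))
      stop("unknown rank prefix in lineage '", s, "'", call. = FALSE)
    idx <- match(ranks, names(.rank_prefixes))
    if (is.unsorted(idx, strictly = TRUE))
      stop("ranks out of order in lineage '", s, "'", call. = FALSE)
    names_only <- substring(fields, 4L)
    names(names_only) <- ranks
    names_only
  })
}

#' Rank of the deepest field of each lineage
#' @param x character vector of lineage strings.
#' @param sep field separator.
#' @return character vector of rank names.
#' @export
lineage_depth_rank <- function(x, sep = "|") {
  vapply(parse_lineage(x, sep), function(l) names(l)[length(l)], character(1))
}

## All prefixes of a lineage (including the full string), as lineage strings.
.lineage_prefixes <- function(s, sep = "|") {
  fields <- strsplit(s, sep, fixed = TRUE)[[1]]
  vapply(seq_along(fields), function(k)
    paste(fields[seq_len(k)], collapse = sep), character(1))
}

.looks_like_lineage <- function(x, sep = "|") {
  prefixes <- substr(x, 1L, 3L)
  mean(prefixes %in% .rank_prefixes) > 0.5
}
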