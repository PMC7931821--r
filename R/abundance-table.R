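#' Construct an abundance table
#'
#' The central container of the package: a samples x taxa matrix of
#' relative abundances (dimensionless fractions).  Rows are samples,
#' columns are taxa identified by rank-prefixed lineage strings.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids,taxon_ids identifiers; taken from `dimnames(values)`
#'   when missing.
#' @param rank_level taxonomic rank of the columns (default `"species"`).
#' @param normalized logical: do rows sum to 1?  Truncation (see
#'   [gan_simulate()]) breaks exact closure and is recorded by setting
#'   this to `FALSE`.
#' @param normalization character note recording any rescaling applied
#'   on input (`"none"`, `"percent"`, `"counts"`, ...).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values),
                            rank_level = "species",
                            normalized = NA, normalization = "none") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(taxon_ids)) stop("taxon_ids are required")
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon ids: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (length(sample_ids) != nrow(values) || length(taxon_ids) != ncol(values))
    stop("identifier lengths do not match the value matrix")
  if (any(!is.finite(values))) stop("non-finite abundance values")
  if (any(values < 0)) stop("negative abundance values")
  dimnames(values) <- list(sample_ids, taxon_ids)
  if (is.na(normalized)) {
    rs <- rowSums(values)
    normalized <- all(abs(rs - 1) < 1e-6 | rs == 0)
  }
  structure(
    list(values = values, rank_level = rank_level,
         normalized = normalized, normalization = normalization),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa (%s level)\n",
              nrow(x$values), ncol(x$values), x$rank_level))
  cat(sprintf("  row closure: %s; input normalization: %s\n",
              if (isTRUE(x$normalized)) "rows sum to 1" else "not closed",
              x$normalization))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
taxon_ids <- function(x) colnames(x$values)

#' Read a delimited abundance table
#'
#' Reads a TSV/CSV matrix with a header of identifiers and a leading
#' identifier column.  Orientation is auto-detected from which margin
#' parses as taxonomic lineages; internally samples are always rows.
#' Input may be fractions (rows sum to 1), percents (rows sum to 100) or
#' raw counts; unless `normalize = "none"` every row is divided by its
#' total so that output rows are closed compositions, and the detected
#' dialect is recorded in the `normalization` field.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param orientation `"auto"`, `"samples"` (rows are samples) or
#'   `"taxa"` (rows are taxa; the matrix is transposed on read).
#' @param normalize `"auto"` (divide rows by their totals) or `"none"`.
#' @param sep field separator; `NULL` = infer from the extension.
#' @param rank_level passed to [abundance_table()].
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, orientation = c("auto", "samples", "taxa"),
                                 normalize = c("auto", "none"), sep = NULL,
                                 rank_level = "species") {
  orientation <- match.arg(orientation)
  normalize <- match.arg(normalize)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", na.strings = character(0))
  m <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   rownames(raw)[bad[1]], colnames(raw)[j], raw[bad[1], j]),
           call. = FALSE)
    m[, j] <- v
  }
  if (anyNA(m)) stop("missing values in abundance table")
  if (any(m < 0)) stop("negative abundance values in ", path)
  if (orientation == "auto") {
    cols_lineage <- .looks_like_lineage(colnames(m))
    rows_lineage <- .looks_like_lineage(rownames(m))
    orientation <- if (rows_lineage && !cols_lineage) "taxa" else "samples"
  }
  if (orientation == "taxa") m <- t(m)
  normalization <- "none"
  if (normalize == "auto") {
    rs <- rowSums(m)
    med <- stats::median(rs[rs > 0])
    normalization <- if (is.na(med)) "none"
      else if (abs(med - 1) < 1e-3) "fractions"
      else if (abs(med - 100) < 1) "percent"
      else "counts"
    ## rows already closed to within double precision are left untouched
    nz <- rs > 0 & abs(rs - 1) > 1e-12
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  abundance_table(m, rank_level = rank_level, normalization = normalization)
}

#' Write an abundance table to delimited text
#'
#' Values are written with full double precision so that a
#' read-write-read round trip is stable to below 1e-9.
#'
#' @param table an [abundance_table()].
#' @param path output path; `.csv` writes comma-separated.
#' @param sep field separator; `NULL` = infer from the extension.
#' @export
write_abundance_table <- function(table, path, sep = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  v <- table$values
  df <- data.frame(sample_id = rownames(v),
                   format(v, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(v))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
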