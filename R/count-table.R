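#' Validate a taxa-by-sample count matrix
#'
#' Checks the invariants of the package's canonical count container: an
#' integer matrix with taxa as rows and samples as columns, unique taxon and
#' sample names, and no negative cells.
#'
#' @param counts A numeric matrix with rownames (taxa) and colnames (samples).
#' @return The validated matrix, in integer storage mode.
#' @export
taxa_count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("count table must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon names: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (ncol(counts) > 0L && anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Per-sample read depths
#'
#' @param counts A validated count matrix (see [taxa_count_table()]).
#' @return Named integer vector of column sums.
#' @export
sample_depths <- function(counts) colSums(counts)

#' Read a taxa-by-sample count table from TSV
#'
#' Expects a tab-separated file with a header row of sample ids, taxon names
#' in the first column, and integer cells. Malformed cells are reported with
#' their row and column; duplicated taxon or sample ids are an error, never
#' silently merged.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, taxa x samples.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty count table file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  body <- lapply(lines[-1L], function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
  taxa <- vapply(body, `[`, character(1L), 1L)
  n <- length(samples)
  mat <- matrix(0L, nrow = length(taxa), ncol = n, dimnames = list(taxa, samples))
  for (r in seq_along(body)) {
    cells <- body[[r]][-1L]
    if (length(cells) != n)
      stop("row '", taxa[r], "': expected ", n, " cells, found ", length(cells))
    bad <- !grepl("^[0-9]+$", cells)
    if (any(bad))
      stop("non-integer or negative count at row '", taxa[r], "', column '",
           samples[which(bad)[1L]], "': '", cells[which(bad)[1L]], "'")
    mat[r, ] <- as.integer(cells)
  }
  taxa_count_table(mat)
}

#' Write a count table to TSV
#'
#' Writes the canonical on-disk format (UTF-8 TSV, taxa as rows, header row of
#' sample ids) so that [read_count_table()] recovers the input bit-identically.
#' Tab is the reserved delimiter and may not occur in taxon or sample names.
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  counts <- taxa_count_table(counts)
  nm <- c(rownames(counts), colnames(counts))
  if (any(grepl("\t", nm, fixed = TRUE)))
    stop("taxon/sample names must not contain the tab delimiter")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("taxon", colnames(counts)), collapse = "\t"), con)
  if (nrow(counts) > 0L) {
    rows <- vapply(seq_len(nrow(counts)), function(r)
      paste(c(rownames(counts)[r], counts[r, ]), collapse = "\t"), character(1L))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Relative-abundance profile of one sample
#'
#' Divides a sample's counts by its read depth. A zero-depth sample yields the
#' all-zero sentinel profile rather than NaN, mirroring the convention that
#' empty samples are carried but flagged.
#'
#' @param counts Validated count matrix.
#' @param sample_id Column to extract.
#' @return Named numeric vector over the table's taxa, summing to 1 (or all 0).
#' @export
to_profile <- function(counts, sample_id) {
  if (!sample_id %in% colnames(counts)) stop("unknown sample id: ", sample_id)
  x <- counts[, sample_id]
  d <- sum(x)
  p <- if (d > 0) x / d else rep(0, length(x))
  names(p) <- rownames(counts)
  p
}

#' All relative-abundance profiles of a table
#'
#' @param counts Validated count matrix.
#' @return Numeric matrix, taxa x samples; zero-depth columns are all zero.
#' @export
to_profiles <- function(counts) {
  d <- colSums(counts)
  p <- sweep(counts, 2L, ifelse(d > 0, d, 1), "/")
  p[, d == 0] <- 0
  p
}

.fractions <- c("raw", "igg_bound", "igg_unbound")

#' Read and validate a sample metadata table
#'
#' Requires columns `sample_id`, `fraction` (one of `raw`, `igg_bound`,
#' `igg_unbound`), `pair_id` (linking the sorted/unsorted aliquots of one
#' participant) and `group`. Optional columns (`sex`, `age`, `pack_years`,
#' `qpcr_copies`, `flow_events`, and any `cytokine_*`) may be absent wholesale;
#' a pair id may hold at most one sample per fraction.
#'
#' @param path TSV path.
#' @return A validated data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param md A metadata data.frame to validate in place.
#' @export
validate_metadata <- function(md) {
  req <- c("sample_id", "fraction", "pair_id", "group")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  bad <- !md$fraction %in% .fractions
  if (any(bad))
    stop("unknown fraction label(s): ", paste(unique(md$fraction[bad]), collapse = ", "),
         " (expected ", paste(.fractions, collapse = "/"), ")")
  key <- paste(md$pair_id, md$fraction)
  if (anyDuplicated(key))
    stop("broken pairing: pair_id/fraction combination duplicated (",
         key[duplicated(key)][1L], ")")
  if ("age" %in% names(md) && any(md$age < 0, na.rm = TRUE)) stop("age must be >= 0")
  cyt <- grep("^cytokine_", names(md), value = TRUE)
  for (cc in cyt) if (any(md[[cc]] < 0, na.rm = TRUE)) stop("cytokine values must be >= 0: ", cc)
  md
}

#' Write a metadata table to TSV
#'
#' @param md Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
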