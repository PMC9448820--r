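#' Construct a sample-by-protein abundance matrix
#'
#' The universal data currency of the package: a numeric matrix of log2
#' intensities with samples in rows and proteins in columns. Missing
#' (non-detected) entries are encoded as `NA`; the missing mask is therefore
#' `is.na(x)`. Row names are sample identifiers, column names protein
#' identifiers; both must be unique and all observed values finite.
#'
#' @param values numeric matrix of log2 intensities (`NA` = missing).
#' @param sample_ids,protein_ids optional identifier vectors; defaults to the
#'   dimnames of `values`.
#' @return a validated numeric matrix of class `c("abundance_matrix","matrix")`.
#' @export
abundance_matrix <- function(values, sample_ids = rownames(values),
                             protein_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(protein_ids)) protein_ids <- paste0("P", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(protein_ids)) stop("duplicate protein ids")
  if (length(sample_ids) != nrow(values) || length(protein_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  obs <- values[!is.na(values)]
  if (length(obs) && any(!is.finite(obs)))
    stop("observed abundances must be finite")
  dimnames(values) <- list(as.character(sample_ids), as.character(protein_ids))
  class(values) <- c("abundance_matrix", class(matrix()))
  values
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d proteins (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# strip the class so base matrix methods apply cleanly
as_plain_matrix <- function(x) {
  class(x) <- "matrix"
  x
}

#' Read / write abundance matrices as TSV
#'
#' The on-disk dialect: tab-separated, first column `sample_id`, one column
#' per protein, empty cells for missing values.
#'
#' @param x an [abundance_matrix()].
#' @param path file path.
#' @return `read_abundance_tsv` returns an [abundance_matrix()];
#'   `write_abundance_tsv` returns `path` invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as_plain_matrix(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(sample_id = "character"),
                          na.strings = "")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  mode(m) <- "numeric"
  abundance_matrix(m, sample_ids = df$sample_id)
}

#' Write / read a sample annotation table as TSV
#' @param annotation data frame with a `sample_id` column.
#' @param path file path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(sample_id = "character"))
}
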