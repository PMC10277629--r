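#' Write a count matrix
#'
#' TSV layout: first column `gene`, optional second column `gene_type` (from
#' the matrix attribute), then one integer column per sample. MTX layout:
#' MatrixMarket file plus `<path>.rows` / `<path>.cols` index files (one id
#' per line; rows file has two tab-separated columns when gene types are
#' annotated).
#'
#' @param counts genes x samples integer matrix (optionally with a
#'   `gene_type` attribute).
#' @param path output file.
#' @param format "tsv" or "mtx".
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  gt <- attr(counts, "gene_type")
  if (format == "tsv") {
    df <- data.frame(gene = rownames(counts), stringsAsFactors = FALSE)
    if (!is.null(gt)) df$gene_type <- unname(gt[rownames(counts)])
    df <- cbind(df, as.data.frame(counts, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    rows <- if (is.null(gt)) rownames(counts) else
      paste(rownames(counts), unname(gt[rownames(counts)]), sep = "\t")
    writeLines(rows, paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path input file.
#' @param format "tsv" or "mtx".
#' @return integer matrix with gene rownames, sample colnames and (when
#'   present in the file) a `gene_type` attribute.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!"gene" %in% colnames(df)) stop("malformed header: no 'gene' column")
    dup <- df$gene[duplicated(df$gene)]
    if (length(dup)) stop("duplicated gene id(s): ",
                          paste(unique(dup), collapse = ", "))
    gt <- NULL
    if ("gene_type" %in% colnames(df))
      gt <- stats::setNames(df$gene_type, df$gene)
    mat_cols <- setdiff(colnames(df), c("gene", "gene_type"))
    if (anyDuplicated(mat_cols)) stop("duplicated sample id(s)")
    m <- as.matrix(df[, mat_cols, drop = FALSE])
    if (any(m != round(m)) || any(m < 0)) stop("non-integer or negative counts")
    storage.mode(m) <- "integer"
    rownames(m) <- df$gene
    if (!is.null(gt)) attr(m, "gene_type") <- gt
    m
  } else {
    rows_path <- paste0(path, ".rows"); cols_path <- paste0(path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stop("missing MTX index file(s): ", rows_path, " / ", cols_path)
    m <- as.matrix(Matrix::readMM(path))
    rows <- strsplit(readLines(rows_path), "\t", fixed = TRUE)
    ids <- vapply(rows, `[`, character(1), 1)
    if (length(ids) != nrow(m) || length(readLines(cols_path)) != ncol(m))
      stop("MTX index length does not match matrix dimensions")
    if (anyDuplicated(ids)) stop("duplicated gene id(s) in MTX row index")
    if (any(m != round(m)) || any(m < 0)) stop("non-integer or negative counts")
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    colnames(m) <- readLines(cols_path)
    if (all(lengths(rows) == 2))
      attr(m, "gene_type") <- stats::setNames(
        vapply(rows, `[`, character(1), 2), ids)
    m
  }
}

#' Read a GMT gene-set file
#'
#' @param path tab-separated file: set name, description, member genes.
#' @return named list of character vectors (the descriptions are kept as a
#'   `description` attribute).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set descriptions (defaults to the set
#'   names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write/read a signature matrix as TSV
#'
#' First column `gene`, optional `marker_type`, then one column per cell
#' type.
#' @param signature genes x cell-types matrix.
#' @param path file path.
#' @export
write_signature <- function(signature, path) {
  df <- data.frame(gene = rownames(signature), stringsAsFactors = FALSE)
  mt <- attr(signature, "marker_type")
  if (!is.null(mt)) df$marker_type <- unname(mt[rownames(signature)])
  df <- cbind(df, as.data.frame(unclass(signature), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mt <- NULL
  if ("marker_type" %in% colnames(df))
    mt <- stats::setNames(df$marker_type, df$gene)
  m <- as.matrix(df[, setdiff(colnames(df), c("gene", "marker_type")),
                    drop = FALSE])
  rownames(m) <- df$gene
  if (!is.null(mt)) attr(m, "marker_type") <- mt
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
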