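#' Read a UMI count matrix
#'
#' Reads a genes x cells count matrix either from a MatrixMarket triplet
#' (`matrix.mtx` + `genes.tsv` + `barcodes.tsv` in a directory) or from a
#' dense TSV with gene rownames and cell column names. Integer matrices
#' round-trip bit-exactly through [write_counts()].
#'
#' The `genes.tsv` / `barcodes.tsv` side files may carry extra annotation
#' columns beyond the id column; these are returned as tibbles.
#'
#' @param path directory (for `format = "mtx"`) or file (for `"tsv"`).
#' @param format `"mtx"` or `"tsv"`.
#' @return list with `counts` (integer matrix), `genes` (tibble or NULL),
#'   `cells` (tibble or NULL).
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) {
      if (!file.exists(f)) abort(sprintf("missing file: %s", f))
    }
    m <- withCallingHandlers(
      as.matrix(Matrix::readMM(mtx)),
      warning = function(w) abort(sprintf("malformed MTX file: %s",
                                          conditionMessage(w)))
    )
    genes <- readr::read_tsv(gf, show_col_types = FALSE)
    cells <- readr::read_tsv(bf, show_col_types = FALSE)
    if (nrow(genes) != nrow(m) && !(nrow(m) == 0 && nrow(genes) == 0)) {
      abort("genes.tsv row count does not match matrix dimension")
    }
    if (nrow(cells) != ncol(m)) {
      abort("barcodes.tsv row count does not match matrix dimension")
    }
    if (any(m != round(m))) abort("matrix contains non-integer entries")
    gid <- if (ncol(genes) >= 1) as.character(genes[[1]]) else character(0)
    cid <- if (ncol(cells) >= 1) as.character(cells[[1]]) else character(0)
    dimnames(m) <- list(gid, cid)
    storage.mode(m) <- "integer"
    assert_count_matrix(m)
    list(counts = m, genes = genes, cells = cells)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (any(m != round(m))) abort("matrix contains non-integer entries")
    storage.mode(m) <- "integer"
    assert_count_matrix(m)
    list(counts = m, genes = NULL, cells = NULL)
  }
}

#' Write a UMI count matrix
#'
#' Inverse of [read_counts()]: writes either a MatrixMarket triplet
#' directory or a dense TSV.
#'
#' @param counts integer genes x cells matrix with dimnames.
#' @param path output directory (`mtx`) or file (`tsv`).
#' @param format `"mtx"` or `"tsv"`.
#' @param genes,cells optional annotation tibbles written as the side files
#'   (first column must be the ids); defaults to bare id tables.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx", "tsv"),
                         genes = NULL, cells = NULL) {
  format <- match.arg(format)
  assert_count_matrix(counts)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    rn <- rownames(counts) %||% character(0)
    cn <- colnames(counts) %||% character(0)
    if (is.null(genes)) genes <- tibble(gene_id = rn)
    if (is.null(cells)) cells <- tibble(cell_id = cn)
    stopifnot(identical(as.character(genes[[1]]), rn),
              identical(as.character(cells[[1]]), cn))
    readr::write_tsv(genes, file.path(path, "genes.tsv"))
    readr::write_tsv(cells, file.path(path, "barcodes.tsv"))
  } else {
    df <- as_tibble(counts, rownames = "gene_id")
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path a GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("malformed GMT line (need name, desc, >=1 gene)")
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
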