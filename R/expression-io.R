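#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file whose first row holds sample identifiers and
#' whose first column holds gene identifiers; the body must be numeric.
#' The delimiter is auto-detected among tab and comma when not supplied.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Optional field separator; one of `"\t"` or `","`.
#'   When `NULL`, the separator yielding more fields on the header line wins
#'   (ties go to tab).
#' @return A numeric matrix with genes in rows (rownames = gene ids) and
#'   samples in columns (colnames = sample ids).
#' @export
read_expression_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("expression file is empty: ", path)
  if (is.null(delimiter)) {
    n_tab <- length(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
    n_com <- length(strsplit(lines[1L], ",", fixed = TRUE)[[1L]])
    delimiter <- if (n_com > n_tab) "," else "\t"
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading stub over the gene-id column,
  # so body rows must have length(header) or length(header) + 1 fields
  n_body <- lengths(fields[-1L])
  if (length(n_body) == 0L) stop("expression file has no data rows")
  allowed <- c(length(header), length(header) + 1L)
  bad <- which(!n_body %in% allowed | n_body != n_body[1L])
  if (length(bad)) {
    stop("ragged expression file: line ", bad[1L] + 1L, " has ",
         n_body[bad[1L]], " fields, expected ",
         paste(unique(c(allowed, n_body[1L])), collapse = " or "))
  }
  n_samp <- n_body[1L] - 1L
  if (n_samp < 1L) stop("expression file has no sample columns")
  sample_ids <- if (length(header) == n_body[1L]) header[-1L] else header
  if (length(sample_ids) != n_samp)
    stop("header has ", length(sample_ids), " sample ids but body rows have ",
         n_samp, " value fields")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n_samp))
  )
  vals <- if (n_samp == 1L) matrix(vals, nrow = 1L) else vals  # vapply quirk
  vals <- t(matrix(vals, nrow = n_samp))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at gene '", gene_ids[idx[1L]], "' (row ",
         idx[1L] + 1L, "), sample '", sample_ids[idx[2L]], "' (column ",
         idx[2L] + 1L, ")")
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

#' Write an expression matrix as TSV
#'
#' @param matrix Numeric gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(x)
    paste(format(x, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read sample group labels
#'
#' Two-column delimited file mapping sample id to a binary group code.
#' Numeric codes must lie in \{0, 1\}; otherwise the file must contain
#' exactly two string levels, which are mapped to 0/1 (first level met in
#' file order = 0) with the mapping reported via a message.
#'
#' @param path Path to a two-column TSV/CSV file (no header required; a
#'   header line whose second field is not a recognisable code is skipped).
#' @return Named integer vector of 0/1 codes, names = sample ids.
#' @export
read_group_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("label file is empty: ", path)
  sep <- if (grepl(",", lines[1L], fixed = TRUE)) "," else "\t"
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("label file line ", which(lengths(fields) < 2L)[1L],
         " has fewer than two fields")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  raw <- trimws(vapply(fields, `[[`, character(1L), 2L))
  # tolerate a header line
  if (identical(tolower(raw[1L]), "group") ||
      identical(tolower(ids[1L]), "sample_id")) {
    ids <- ids[-1L]; raw <- raw[-1L]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample ids in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- suppressWarnings(as.numeric(raw))
  if (!anyNA(num)) {
    if (!all(num %in% c(0, 1)))
      stop("numeric group codes outside {0, 1}: ",
           paste(unique(num[!num %in% c(0, 1)]), collapse = ", "))
    code <- as.integer(num)
  } else {
    lev <- unique(raw)
    if (length(lev) != 2L)
      stop("expected two group levels, found ", length(lev), ": ",
           paste(lev, collapse = ", "))
    code <- as.integer(raw == lev[2L])
    message("group level mapping: '", lev[1L], "' -> 0, '", lev[2L], "' -> 1")
  }
  if (length(unique(code)) < 2L) stop("both groups must be non-empty")
  stats::setNames(code, ids)
}

#' Log2-normalize an expression matrix
#'
#' Applies `x -> log2(x + 1)`. In `auto` mode the transform is applied only
#' when the matrix maximum exceeds 50, a heuristic for unlogged microarray
#' intensities (log2 data rarely exceed ~20). `force` always transforms and
#' requires all values > -1; `off` is the identity.
#'
#' @param matrix Numeric gene-by-sample matrix.
#' @param mode One of `"auto"`, `"force"`, `"off"`.
#' @return The (possibly transformed) matrix, with attribute
#'   `"log2_applied"` recording the decision.
#' @export
normalize_log2 <- function(matrix, mode = c("auto", "force", "off")) {
  mode <- match.arg(mode)
  apply_tf <- switch(mode,
    auto  = max(matrix) > 50,
    force = TRUE,
    off   = FALSE)
  if (apply_tf) {
    if (any(matrix <= -1))
      stop("log2(x + 1) undefined: matrix contains values <= -1 (min = ",
           min(matrix), ")")
    out <- log2(matrix + 1)
  } else {
    out <- matrix
  }
  attr(out, "log2_applied") <- apply_tf
  out
}

# internal: check a labels vector against a matrix and return it aligned
align_labels <- function(matrix, labels) {
  miss <- setdiff(colnames(matrix), names(labels))
  if (length(miss))
    stop("samples missing from labels: ", paste(miss, collapse = ", "))
  lab <- labels[colnames(matrix)]
  if (length(unique(lab)) < 2L) stop("both groups must be non-empty")
  lab
}
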