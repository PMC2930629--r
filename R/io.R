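#' Read a gene x sample expression TSV
#'
#' Expected layout: a tab-separated header `gene_id<TAB>sample1<TAB>...`,
#' then one row per gene.  Values are parsed as numeric and the table is
#' transposed to the internal samples x genes orientation.  Windows line
#' endings are tolerated.
#'
#' @param path path to the TSV file.
#' @return An [expression_matrix()] (not yet standardized).
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("expression file is empty or header-only: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1L]
  if (length(sample_ids) == 0) stop("no sample columns in ", path)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1L]
    stop("row ", bad + 1L, " of ", path, " has ", nfield[bad],
         " fields; expected ", length(header))
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("non-numeric value at row ", i + 1L, " (gene ", gene_ids[i],
           "), column ", j + 1L, " of ", path)
    }
    vals[i, ] <- v
  }
  expression_matrix(t(vals), sample_ids = sample_ids, gene_ids = gene_ids)
}

#' Write an expression matrix as a gene x sample TSV
#'
#' Inverse of [read_expression_tsv()]; values round-trip at full double
#' precision.
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  m <- t(em$values)                     # genes x samples
  lines <- c(paste(c("gene_id", em$sample_ids), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(em$gene_ids[i],
                       formatC(m[i, ], format = "g", digits = 17)),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-identifier-per-line gene list
#'
#' Blank lines and lines starting with `#` are skipped; duplicates are
#' collapsed (keeping first occurrence) with a warning; input order is
#' preserved.
#'
#' @param path path to the list file.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(ids) == 0)
    stop("gene list ", path, " contains no identifiers")
  if (anyDuplicated(ids)) {
    warning("duplicate identifiers in ", path, " collapsed: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- ids[!duplicated(ids)]
  }
  ids
}
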