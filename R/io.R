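#' Read a gene-set collection in GMT layout
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (gene symbols); the description
#'   column is kept in the `"description"` attribute of each set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    nms[[i]] <- parts[[1]]
    genes <- parts[-(1:2)]
    attr(genes, "description") <- parts[[2]]
    out[[i]] <- genes
  }
  names(out) <- nms
  out
}

#' Write a gene-set collection in GMT layout
#'
#' @param genesets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  lines <- vapply(seq_along(genesets), function(i) {
    desc <- attr(genesets[[i]], "description")
    if (is.null(desc)) desc <- "synthetic"
    paste(c(names(genesets)[[i]], desc, genesets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Deterministic TSV writers shared by the pipeline outputs.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    check.names = FALSE, ...)
}

#' Read a prescription-record table
#'
#' Expects the columns `patient_id`, `visit_date`, `raw_name`, `phase`,
#' `endpoint` (extra columns such as an already-harmonized `drug_id` are kept).
#'
#' @param path Path to a TSV file.
#' @return A data frame of prescription records with `visit_date` as `Date`.
#' @export
read_prescriptions <- function(path) {
  df <- read_tsv(path)
  need <- c("patient_id", "visit_date", "raw_name", "phase", "endpoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("prescription table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$visit_date <- as.Date(df$visit_date)
  df$phase <- as.integer(df$phase)
  df
}

#' Read a drug catalog table
#'
#' Set-valued columns (`atc_codes`, `targets`, `mechanism_genes`,
#' `fingerprint_bits`) are `;`-joined in the file and unpacked into list
#' columns here.
#'
#' @param path Path to a TSV file with columns `drug_id`, `name`,
#'   `atc_codes`, `targets`, `mechanism_genes`, `fingerprint_bits` and
#'   optionally `truth_label`.
#' @return A data frame with list columns for the set-valued fields.
#' @export
read_drug_catalog <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("drug_id", "name", "atc_codes", "targets",
            "mechanism_genes", "fingerprint_bits")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug catalog lacks columns: ",
                         paste(miss, collapse = ", "))
  split_col <- function(x) {
    lapply(x, function(v) {
      if (is.na(v) || !nzchar(v)) character(0)
      else strsplit(v, ";", fixed = TRUE)[[1]]
    })
  }
  df$atc_codes <- split_col(df$atc_codes)
  df$targets <- split_col(df$targets)
  df$mechanism_genes <- split_col(df$mechanism_genes)
  df$fingerprint_bits <- lapply(split_col(df$fingerprint_bits), as.integer)
  df
}

#' Write a drug catalog table
#'
#' @param catalog Catalog data frame as returned by [generate_drug_catalog()]
#'   or [read_drug_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_catalog <- function(catalog, path) {
  join <- function(col) vapply(col, paste, character(1), collapse = ";")
  out <- data.frame(
    drug_id = catalog$drug_id,
    name = catalog$name,
    atc_codes = join(catalog$atc_codes),
    targets = join(catalog$targets),
    mechanism_genes = join(catalog$mechanism_genes),
    fingerprint_bits = join(catalog$fingerprint_bits),
    stringsAsFactors = FALSE
  )
  if (!is.null(catalog$truth_label)) out$truth_label <- catalog$truth_label
  write_tsv(out, path)
}
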