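#' Read a genus-level abundance table
#'
#' Reads a samples-by-taxa count table from either a tab-separated file or a
#' BIOM-style sparse JSON file. TSV files may be oriented taxa-by-samples
#' (the QIIME convention, first column named `#Genus` or `#OTU ID`) or
#' samples-by-taxa (first column `sample_id`); the orientation is detected
#' from the header.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default, from the file extension), `"tsv"` or
#'   `"biom"`.
#' @return A tibble with a `sample_id` column followed by one integer count
#'   column per taxon.
#' @examples
#' tbl <- tibble::tibble(sample_id = c("s1", "s2"), Prevotella = c(3L, 0L),
#'                       Roseburia = c(1L, 5L))
#' f <- tempfile(fileext = ".tsv")
#' write_abundance(tbl, f)
#' read_abundance(f)
#' @export
read_abundance <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  mat <- switch(format,
    tsv  = read_abundance_tsv(path),
    biom = read_abundance_biom(path)
  )
  if (anyDuplicated(colnames(mat))) {
    dup <- unique(colnames(mat)[duplicated(colnames(mat))])
    abort(paste0("duplicated taxa in ", path, ": ", paste(dup, collapse = ", ")))
  }
  if (!all(is_wholenumber(mat))) {
    abort(paste0("non-integer counts in ", path))
  }
  mode(mat) <- "integer"
  matrix_to_tbl(mat)
}

read_abundance_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), comment = "",
                         name_repair = "minimal", progress = FALSE)
  first <- names(raw)[1]
  if (first %in% c("#Genus", "#OTU ID", "#OTU_ID", "taxon")) {
    taxa <- as.character(raw[[1]])
    mat <- t(as.matrix(raw[-1]))          # samples x taxa
    colnames(mat) <- taxa
    mat
  } else if (first == "sample_id") {
    ids <- as.character(raw[[1]])
    mat <- as.matrix(raw[-1])
    rownames(mat) <- ids
    mat
  } else {
    abort(paste0("cannot detect table orientation: first column is `", first,
                 "` (expected `#Genus`, `#OTU ID` or `sample_id`)"))
  }
}

read_abundance_biom <- function(path) {
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  t(m)
}

#' Write an abundance table
#'
#' Writes TSV (taxa rows by sample columns, first column `#Genus`) or
#' BIOM-style sparse JSON.
#'
#' @param tbl Abundance tibble (`sample_id` + taxon count columns).
#' @inheritParams read_abundance
#' @return `path`, invisibly.
#' @export
write_abundance <- function(tbl, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  mat <- abundance_matrix(tbl, counts = TRUE)
  if (format == "tsv") {
    out <- as_tibble(t(mat), .name_repair = "minimal")
    out <- dplyr::bind_cols(tibble(`#Genus` = colnames(mat)), out)
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    b <- biomformat::make_biom(t(mat))  # observations x samples
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read/write per-sample clinical metadata
#'
#' Plain TSV with one row per sample; `sample_id` and `group` are required,
#' clinical scores and covariates are free-form columns.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("metadata must contain `sample_id` and `group` columns")
  }
  meta
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}
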