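#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn inform enquo as_name
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols across all_of everything pull n rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 imap list_rbind
#' @importFrom stats median p.adjust wilcox.test cor.test glm binomial coef
#'   cmdscale rnorm runif rlogis rgamma rmultinom quantile sd shapiro.test
#'   t.test chisq.test fisher.test setNames as.formula qlogis vcov dist
#'   complete.cases IQR
#' @importFrom utils head
NULL

# deterministic 32-bit stream id from a base seed and a sample label, so
# per-sample subsampling never depends on sample order
stream_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# Convert a wide abundance tibble (sample_id + one numeric column per taxon)
# to a samples x taxa matrix, validating the invariants shared by counts and
# relative-abundance tables.
abundance_matrix <- function(tbl, counts = FALSE) {
  if (!is.data.frame(tbl) || !"sample_id" %in% names(tbl)) {
    abort("abundance table must be a data frame with a `sample_id` column")
  }
  ids <- as.character(tbl$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  taxa <- setdiff(names(tbl), "sample_id")
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicated taxa: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  mat <- as.matrix(tbl[taxa])
  if (!is.numeric(mat)) abort("abundance values must be numeric")
  if (any(!is.finite(mat))) abort("abundance values must be finite")
  if (any(mat < 0)) abort("abundance values must be non-negative")
  if (counts && !all(is_wholenumber(mat))) {
    abort("counts must be integer-valued")
  }
  dimnames(mat) <- list(ids, taxa)
  mat
}

matrix_to_tbl <- function(mat) {
  out <- as_tibble(mat, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(mat)), out)
}
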