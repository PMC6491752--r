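#' Collapse an OTU table to genus level
#'
#' Sums counts over taxa sharing a genus. Taxa unclassified at genus rank are
#' pooled per family under the label `"Un <Family>"`; taxa with neither genus
#' nor family rank go to `"Unassigned"`. Lineages use the QIIME convention
#' (`k__...; p__...; ...; f__Family; g__Genus`).
#'
#' @param tbl Abundance tibble (`sample_id` + one count column per OTU/taxon).
#' @param taxonomy A data frame with columns `taxon` and `lineage`, covering
#'   every taxon column of `tbl`.
#' @return Genus-level abundance tibble; per-sample totals are conserved.
#' @export
collapse_to_genus <- function(tbl, taxonomy) {
  mat <- abundance_matrix(tbl, counts = TRUE)
  if (!all(c("taxon", "lineage") %in% names(taxonomy))) {
    abort("taxonomy must have columns `taxon` and `lineage`")
  }
  missing <- setdiff(colnames(mat), taxonomy$taxon)
  if (length(missing)) {
    abort(paste0("taxa without taxonomy: ", paste(missing, collapse = ", ")))
  }
  lin <- setNames(as.character(taxonomy$lineage), taxonomy$taxon)
  labels <- vapply(lin[colnames(mat)], genus_label, character(1))
  collapsed <- t(rowsum(t(mat), group = labels))
  mode(collapsed) <- "integer"
  matrix_to_tbl(collapsed)
}

genus_label <- function(lineage) {
  ranks <- strsplit(lineage, ";")[[1]]
  ranks <- trimws(ranks)
  pick <- function(prefix) {
    hit <- grep(paste0("^", prefix, "__"), ranks, value = TRUE)
    if (!length(hit)) return(NA_character_)
    val <- sub(paste0("^", prefix, "__"), "", hit[1])
    if (!nzchar(val)) NA_character_ else val
  }
  genus <- pick("g")
  family <- pick("f")
  if (!is.na(genus)) genus
  else if (!is.na(family)) paste("Un", family)
  else "Unassigned"
}

#' Drop rare taxa
#'
#' A taxon is retained iff its total count across all samples is at least
#' `min_count_fraction` of the table's grand total count (the semantics of
#' QIIME 1's `filter_otus_from_otu_table.py --min_count_fraction`); the
#' boundary is inclusive. Samples are untouched.
#'
#' @param tbl Abundance tibble of counts.
#' @param min_count_fraction Fraction of the grand total, in `[0, 1)`;
#'   default `0.001` (0.1%).
#' @return Filtered abundance tibble.
#' @export
filter_low_abundance <- function(tbl, min_count_fraction = 0.001) {
  if (!is.numeric(min_count_fraction) || length(min_count_fraction) != 1 ||
      min_count_fraction < 0 || min_count_fraction >= 1) {
    abort("`min_count_fraction` must be a single number in [0, 1)")
  }
  mat <- abundance_matrix(tbl, counts = TRUE)
  totals <- colSums(mat)
  keep <- totals >= min_count_fraction * sum(totals)
  matrix_to_tbl(mat[, keep, drop = FALSE])
}

#' Rarefy counts to an even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads. Samples whose total is below `depth` are dropped with a message.
#' Each sample draws from its own RNG stream derived from `(seed,
#' sample_id)`, so results are independent of sample order.
#'
#' @param tbl Abundance tibble of counts.
#' @param depth Target depth; default 4800 (the SDI pipeline depth; community
#'   diversity analyses conventionally use 8000).
#' @param seed Integer seed.
#' @return Rarefied abundance tibble; every row sums to `depth`.
#' @export
rarefy_counts <- function(tbl, depth = 4800, seed = 1) {
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1) {
    abort("`depth` must be a single integer >= 1")
  }
  depth <- as.integer(depth)
  mat <- abundance_matrix(tbl, counts = TRUE)
  totals <- rowSums(mat)
  drop <- totals < depth
  if (all(drop)) abort("no samples survive rarefaction")
  if (any(drop)) {
    inform(paste0("dropping ", sum(drop), " sample(s) below depth ", depth,
                  ": ", paste(rownames(mat)[drop], collapse = ", ")))
    mat <- mat[!drop, , drop = FALSE]
    totals <- totals[!drop]
  }
  out <- mat
  for (i in seq_len(nrow(mat))) {
    if (totals[i] == depth) next
    counts <- mat[i, ]
    units <- rep.int(seq_along(counts), counts)
    pick <- withr::with_seed(
      stream_seed(seed, rownames(mat)[i]),
      sample(units, depth, replace = FALSE)
    )
    out[i, ] <- tabulate(pick, nbins = length(counts))
  }
  mode(out) <- "integer"
  matrix_to_tbl(out)
}

#' Convert counts to percent relative abundance
#'
#' @param tbl Abundance tibble of counts with positive sample totals.
#' @return Tibble of the same shape with values in percent; each row sums
#'   to 100.
#' @export
to_relative <- function(tbl) {
  mat <- abundance_matrix(tbl)
  totals <- rowSums(mat)
  if (any(totals == 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(rownames(mat)[totals == 0], collapse = ", ")))
  }
  matrix_to_tbl(100 * mat / totals)
}
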