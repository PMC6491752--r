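#' Two-sample Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] returning a one-row tibble.
#' Uses exact enumeration for small untied samples and the midrank,
#' tie-corrected normal approximation otherwise. When every value in both
#' groups is identical the comparison is degenerate and `p_value` is 1.
#'
#' @param x,y Numeric vectors, each with at least 2 observations.
#' @return Tibble with `statistic` (Mann-Whitney U for `x`), `p_value` and
#'   `degenerate`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 observations")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(tibble(statistic = length(x) * length(y) / 2,
                  p_value = 1, degenerate = TRUE))
  }
  ht <- suppressWarnings(wilcox.test(x, y))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement; the
#' mapping is order-preserving with respect to the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Construct a dysbiosis signature
#'
#' A signature is the pair of directional genus sets entering the index: the
#' case-enriched set S and the control-enriched set C. The packaged preset
#' (see [preset_signature()]) has |S| = 7 and |C| = 11.
#'
#' @param stroke_enriched,control_enriched Character vectors of genus names;
#'   disjoint, both non-empty.
#' @param tests Optional tibble of per-genus test results (audit trail).
#' @param threshold FDR threshold used for selection, if any.
#' @param provenance Free-text description of the cohort the signature was
#'   derived from.
#' @return An object of class `sdi_signature`.
#' @export
sdi_signature <- function(stroke_enriched, control_enriched, tests = NULL,
                          threshold = NULL, provenance = NULL) {
  stroke_enriched <- as.character(stroke_enriched)
  control_enriched <- as.character(control_enriched)
  if (!length(stroke_enriched) || !length(control_enriched)) {
    abort("both signature sides must be non-empty")
  }
  if (length(intersect(stroke_enriched, control_enriched))) {
    abort("stroke- and control-enriched sets must be disjoint")
  }
  structure(
    list(stroke_enriched = stroke_enriched,
         control_enriched = control_enriched,
         tests = tests, threshold = threshold, provenance = provenance),
    class = "sdi_signature"
  )
}

#' @export
print.sdi_signature <- function(x, ...) {
  cat("<sdi_signature> ", length(x$stroke_enriched), " stroke-enriched + ",
      length(x$control_enriched), " control-enriched genera\n", sep = "")
  cat("  stroke:  ", paste(x$stroke_enriched, collapse = ", "), "\n", sep = "")
  cat("  control: ", paste(x$control_enriched, collapse = ", "), "\n", sep = "")
  if (!is.null(x$threshold)) cat("  FDR threshold: <", x$threshold, "\n", sep = "")
  if (!is.null(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sdi_signature <- function(x, ...) {
  if (is.null(x$tests)) {
    return(tibble(
      genus = c(x$stroke_enriched, x$control_enriched),
      direction = rep(c("stroke-enriched", "control-enriched"),
                      c(length(x$stroke_enriched), length(x$control_enriched)))
    ))
  }
  x$tests
}

#' Select a differential-abundance signature
#'
#' Per-genus Wilcoxon rank-sum tests between the two groups on percent
#' relative abundances, Benjamini-Hochberg adjustment, and assembly of the
#' genera with `fdr_p < q_threshold` into a directional signature. Direction
#' is the group with the larger mean relative abundance (set
#' `direction_stat = "median"` for the median rule); a significant genus
#' with exactly equal group summaries has no direction and is excluded with
#' a warning. Results for every genus are returned as the audit trail.
#'
#' @param rel_tbl Relative-abundance tibble in percent
#'   (see [to_relative()]).
#' @param metadata Data frame with `sample_id` and `group` covering every
#'   sample of `rel_tbl`; exactly two groups must be present.
#' @param q_threshold Strict FDR threshold; default 0.1.
#' @param case,control Group labels; default `"stroke"` / `"control"`.
#' @param direction_stat `"mean"` (default) or `"median"`.
#' @return An `sdi_signature`; `tidy()` returns the per-genus test table
#'   (`genus`, `statistic`, `p_value`, `fdr_p`, `mean_case`, `mean_control`,
#'   `direction`, `selected`).
#' @export
select_signature <- function(rel_tbl, metadata, q_threshold = 0.1,
                             case = "stroke", control = "control",
                             direction_stat = c("mean", "median")) {
  direction_stat <- match.arg(direction_stat)
  mat <- abundance_matrix(rel_tbl)
  grp <- setNames(as.character(metadata$group), metadata$sample_id)[rownames(mat)]
  if (any(is.na(grp))) abort("metadata does not cover every sample")
  if (!setequal(unique(grp), c(case, control))) {
    abort(paste0("expected exactly the two groups `", case, "` and `",
                 control, "`"))
  }
  stat_fun <- if (direction_stat == "mean") mean else median
  a <- mat[grp == case, , drop = FALSE]
  b <- mat[grp == control, , drop = FALSE]
  tests <- purrr::map(colnames(mat), function(g) {
    rs <- rank_sum_test(a[, g], b[, g])
    tibble(genus = g, statistic = rs$statistic, p_value = rs$p_value,
           mean_case = stat_fun(a[, g]), mean_control = stat_fun(b[, g]))
  }) |> purrr::list_rbind()
  tests$fdr_p <- bh_fdr(tests$p_value)
  tests$direction <- dplyr::case_when(
    tests$mean_case > tests$mean_control ~ "stroke-enriched",
    tests$mean_case < tests$mean_control ~ "control-enriched",
    TRUE ~ NA_character_
  )
  tests$selected <- tests$fdr_p < q_threshold & !is.na(tests$direction)
  undirected <- tests$fdr_p < q_threshold & is.na(tests$direction)
  if (any(undirected)) {
    warn(paste0("significant genera with equal group ", direction_stat,
                "s excluded (direction undefined): ",
                paste(tests$genus[undirected], collapse = ", ")))
  }
  tests <- tests[c("genus", "statistic", "p_value", "fdr_p",
                   "mean_case", "mean_control", "direction", "selected")]
  s <- tests$genus[tests$selected & tests$direction == "stroke-enriched"]
  c_ <- tests$genus[tests$selected & tests$direction == "control-enriched"]
  if (!length(s) || !length(c_)) {
    # unusable signature (one or both sides empty): still return the audit
    # trail so callers can inspect what happened
    return(structure(
      list(stroke_enriched = s, control_enriched = c_, tests = tests,
           threshold = q_threshold,
           provenance = signature_provenance(grp, case, control)),
      class = "sdi_signature"
    ))
  }
  sdi_signature(s, c_, tests = tests, threshold = q_threshold,
                provenance = signature_provenance(grp, case, control))
}

signature_provenance <- function(grp, case, control) {
  paste0(sum(grp == case), " ", case, " vs ", sum(grp == control), " ",
         control, " samples, Wilcoxon rank-sum + BH")
}

#' Serialize a signature to JSON
#'
#' @param signature An `sdi_signature`.
#' @param path Output path.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(stroke_enriched = signature$stroke_enriched,
         control_enriched = signature$control_enriched,
         threshold = signature$threshold,
         provenance = signature$provenance),
    path, auto_unbox = TRUE, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sdi_signature(x$stroke_enriched, x$control_enriched,
                threshold = x$threshold, provenance = x$provenance)
}

#' The packaged 18-genus stroke signature
#'
#' The published dysbiosis signature for acute ischemic stroke: 7
#' stroke-enriched and 11 control-enriched genera selected at FDR < 0.1 from
#' a 104-patient / 90-control training cohort. `"Un <Family>"` labels denote
#' genera unclassified below family rank.
#'
#' @return An `sdi_signature` with 18 genera.
#' @examples
#' sig <- preset_signature()
#' length(sig$stroke_enriched)   # 7
#' length(sig$control_enriched)  # 11
#' @export
preset_signature <- function() {
  read_signature(system.file("extdata", "stroke_signature.json",
                             package = "sdindex", mustWork = TRUE))
}
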