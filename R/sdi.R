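#' Compute the Stroke Dysbiosis Index
#'
#' For each sample,
#' \deqn{SDI = \left(\frac{1}{|S|}\sum_{i \in S} a_i -
#'   \frac{1}{|C|}\sum_{j \in C} a_j\right) \times 100}
#' where \eqn{a} is percent relative abundance, S the stroke-enriched and C
#' the control-enriched genus set of the signature. A signature genus absent
#' from the table contributes 0, so cohorts lacking some signature genera
#' (e.g. a validation cohort scored with a training signature) remain
#' scorable on the same scale. Denominators are always |S| and |C| of the
#' signature in use (7 and 11 for the packaged preset).
#'
#' @param rel_tbl Relative-abundance tibble in percent (see [to_relative()]).
#' @param signature An [sdi_signature()].
#' @return Tibble with `sample_id` and `sdi`.
#' @examples
#' rel <- tibble::tibble(sample_id = "s1", Parabacteroides = 2, Prevotella = 1)
#' sig <- sdi_signature("Parabacteroides", "Prevotella")
#' compute_sdi(rel, sig)  # (2 - 1) * 100 = 100
#' @export
compute_sdi <- function(rel_tbl, signature) {
  if (!inherits(signature, "sdi_signature")) {
    abort("`signature` must be an sdi_signature")
  }
  if (!length(signature$stroke_enriched) || !length(signature$control_enriched)) {
    abort("signature must be non-empty on both sides")
  }
  mat <- abundance_matrix(rel_tbl)
  side_mean <- function(genera) {
    present <- intersect(genera, colnames(mat))
    if (!length(present)) return(rep(0, nrow(mat)))
    unname(rowSums(mat[, present, drop = FALSE])) / length(genera)
  }
  tibble(
    sample_id = rownames(mat),
    sdi = (side_mean(signature$stroke_enriched) -
             side_mean(signature$control_enriched)) * 100
  )
}

#' Stratify patients at the median index
#'
#' Splits scored samples at the median of their SDI values: `SDI-H` for
#' scores at or above the threshold (ties go high, matching the published
#' `SDI >= 17.0` stratum definition), `SDI-L` below. With an even number of
#' distinct scores this yields two equal strata.
#'
#' @param scores Tibble with `sample_id` and `sdi` (typically patients only).
#' @return `scores` with an added `stratum` column (factor, levels `SDI-H`,
#'   `SDI-L`) and the split value in attribute `"threshold"` (also retrieved
#'   by [sdi_threshold()]).
#' @examples
#' s <- tibble::tibble(sample_id = letters[1:4], sdi = c(1, 2, 2, 3))
#' stratify_by_median(s)    # threshold 2; ties go to SDI-H
#' @export
stratify_by_median <- function(scores) {
  if (!is.data.frame(scores) || !all(c("sample_id", "sdi") %in% names(scores))) {
    abort("`scores` must have columns `sample_id` and `sdi`")
  }
  if (nrow(scores) < 2) abort("need at least 2 scores")
  if (length(unique(scores$sdi)) == 1L) abort("degenerate stratification")
  thr <- median(scores$sdi)
  out <- dplyr::mutate(
    scores,
    stratum = factor(ifelse(.data$sdi >= thr, "SDI-H", "SDI-L"),
                     levels = c("SDI-H", "SDI-L"))
  )
  attr(out, "threshold") <- thr
  out
}

#' @rdname stratify_by_median
#' @param x A tibble returned by [stratify_by_median()].
#' @export
sdi_threshold <- function(x) attr(x, "threshold")
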