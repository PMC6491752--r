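#' Unweighted UniFrac distances
#'
#' Presence/absence phylogenetic beta diversity: for each sample pair, the
#' branch length leading exclusively to taxa of one sample divided by the
#' branch length leading to taxa of either sample. Presence means count > 0.
#' Computed at genus level against the supplied genus tree.
#'
#' @param tbl Abundance tibble (counts or relative abundances).
#' @param tree A rooted `phylo` tree whose tip labels include every taxon of
#'   `tbl` (extra tips are allowed and ignored).
#' @return A [stats::dist] object over the samples, values in `[0, 1]`.
#' @export
unifrac_distances <- function(tbl, tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  mat <- abundance_matrix(tbl)
  missing <- setdiff(colnames(mat), tree$tip.label)
  if (length(missing)) {
    abort(paste0("taxa missing from tree: ", paste(missing, collapse = ", ")))
  }
  pruned <- ape::keep.tip(tree, colnames(mat))
  as.dist(picante::unifrac(mat, pruned))
}

#' Principal coordinates analysis
#'
#' Classical scaling: eigendecomposition of the double-centered squared
#' distance (Gower) matrix. Axes are ordered by decreasing eigenvalue;
#' negative eigenvalues (non-Euclidean input) are reported and their axes
#' omitted.
#'
#' @param dist A `dist` object or symmetric matrix.
#' @param k Number of axes to return (at most n - 1).
#' @return An `sdi_pcoa` object: `coordinates` (tibble `sample_id`,
#'   `Axis.1`, ...), `eigenvalues`, `negative_eigenvalues` and
#'   `variance_explained` (fraction of the positive eigenvalue total per
#'   returned axis). `tidy()` returns the coordinates.
#' @export
pcoa_ordination <- function(dist, k = 2) {
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist))) abort("distance matrix must be symmetric")
    dist <- as.dist(dist)
  }
  n <- attr(dist, "Size")
  if (k > n - 1) abort("`k` must be at most n - 1")
  sc <- suppressWarnings(cmdscale(dist, k = k, eig = TRUE))
  eig <- sc$eig
  pts <- sc$points
  if (is.null(pts) || ncol(pts) == 0) {           # fully degenerate input
    pts <- matrix(0, n, k)
    rownames(pts) <- attr(dist, "Labels") %||% as.character(seq_len(n))
  } else if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  colnames(pts) <- paste0("Axis.", seq_len(ncol(pts)))
  pos <- eig[eig > 1e-12]
  ve <- if (length(pos)) head(pos, ncol(pts)) / sum(pos) else rep(0, ncol(pts))
  length(ve) <- ncol(pts); ve[is.na(ve)] <- 0
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble(sample_id = rownames(pts) %||% as.character(seq_len(n))),
        as_tibble(pts)
      ),
      eigenvalues = eig,
      negative_eigenvalues = eig[eig < -1e-12],
      variance_explained = ve
    ),
    class = "sdi_pcoa"
  )
}

#' @export
print.sdi_pcoa <- function(x, ...) {
  cat("<sdi_pcoa> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates) - 1, " axes (",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      " of positive inertia)\n", sep = "")
  if (length(x$negative_eigenvalues)) {
    cat("  ", length(x$negative_eigenvalues), " negative eigenvalue(s)\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.sdi_pcoa <- function(x, ...) x$coordinates

#' PERMANOVA (Adonis) on a distance matrix
#'
#' Partitions the squared-distance variance by a grouping factor and tests
#' the pseudo-F statistic by label permutation (via [vegan::adonis2()]);
#' `p = (#{permuted F >= observed} + 1) / (n_permutations + 1)`.
#'
#' @param dist A `dist` object or symmetric matrix.
#' @param metadata Data frame with `sample_id` and the grouping column,
#'   covering every sample; every group needs at least 2 samples.
#' @param group Name of the grouping column; default `"group"`.
#' @param n_permutations Number of permutations; default 999.
#' @param seed Integer seed for the permutation stream.
#' @return An `sdi_permanova` object; `glance()` gives `pseudo_f`, `r2`,
#'   `p_value`, `n_permutations`, `n`.
#' @export
permanova_test <- function(dist, metadata, group = "group",
                           n_permutations = 999, seed = 1) {
  if (is.matrix(dist)) dist <- as.dist(dist)
  ids <- attr(dist, "Labels")
  grp <- setNames(as.character(metadata[[group]]), metadata$sample_id)[ids]
  if (any(is.na(grp))) abort("metadata does not cover every sample")
  sizes <- table(grp)
  if (length(sizes) < 2) abort("need at least two groups")
  if (any(sizes < 2)) {
    abort(paste0("groups with fewer than 2 samples: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  g <- factor(grp)
  fit <- withr::with_seed(
    as.integer(seed),
    vegan::adonis2(dist ~ g, permutations = n_permutations)
  )
  structure(
    list(pseudo_f = fit$F[1], r2 = fit$R2[1], p_value = fit$`Pr(>F)`[1],
         n_permutations = n_permutations, n = length(ids),
         groups = sizes, table = as.data.frame(fit)),
    class = "sdi_permanova"
  )
}

#' @export
print.sdi_permanova <- function(x, ...) {
  cat(sprintf("<sdi_permanova> F = %.3f, R2 = %.3f, p = %.4g (%d permutations, n = %d)\n",
              x$pseudo_f, x$r2, x$p_value, x$n_permutations, x$n))
  invisible(x)
}

#' @export
glance.sdi_permanova <- function(x, ...) {
  tibble(pseudo_f = x$pseudo_f, r2 = x$r2, p_value = x$p_value,
         n_permutations = x$n_permutations, n = x$n)
}

#' @export
tidy.sdi_permanova <- function(x, ...) {
  out <- as_tibble(x$table, rownames = "term")
  names(out) <- c("term", "df", "sum_of_squares", "r2", "statistic", "p_value")
  out
}

#' Patient-to-reference community distances by stratum
#'
#' Collects all pairwise distances from each patient stratum (SDI-H, SDI-L)
#' to a reference (control) sample set and compares the two distance samples
#' with the Wilcoxon rank-sum test. A stratum more distant from controls has
#' a community composition less like the healthy reference.
#'
#' @param dist A `dist` object or symmetric matrix covering all samples.
#' @param strata Tibble with `sample_id` and `stratum`
#'   (from [stratify_by_median()]).
#' @param reference Character vector of reference sample ids, disjoint from
#'   the strata samples.
#' @return An `sdi_refdist` object; `tidy()` gives the per-pair distances
#'   (`sample_id`, `reference_id`, `stratum`, `distance`), `glance()` the
#'   per-stratum medians and the rank-sum p-value.
#' @export
distances_to_reference <- function(dist, strata, reference) {
  m <- as.matrix(dist)
  if (!all(c("sample_id", "stratum") %in% names(strata))) {
    abort("`strata` must have columns `sample_id` and `stratum`")
  }
  if (length(intersect(strata$sample_id, reference))) {
    abort("strata and reference samples must be disjoint")
  }
  missing <- setdiff(c(strata$sample_id, reference), rownames(m))
  if (length(missing)) {
    abort(paste0("samples missing from distance matrix: ",
                 paste(missing, collapse = ", ")))
  }
  lvls <- unique(as.character(strata$stratum))
  if (any(table(as.character(strata$stratum)) == 0) || length(lvls) < 2) {
    abort("both strata must be non-empty")
  }
  pairs <- tidyr::expand_grid(sample_id = strata$sample_id,
                              reference_id = reference)
  pairs <- dplyr::left_join(pairs, strata, by = "sample_id")
  pairs$distance <- m[cbind(pairs$sample_id, pairs$reference_id)]
  hi <- pairs$distance[pairs$stratum == "SDI-H"]
  lo <- pairs$distance[pairs$stratum == "SDI-L"]
  test <- rank_sum_test(hi, lo)
  structure(list(distances = pairs, test = test), class = "sdi_refdist")
}

#' @export
print.sdi_refdist <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<sdi_refdist> median distance to reference: SDI-H %.3f vs SDI-L %.3f (rank-sum p = %.4g)\n",
              g$median_sdi_h, g$median_sdi_l, g$p_value))
  invisible(x)
}

#' @export
tidy.sdi_refdist <- function(x, ...) x$distances

#' @export
glance.sdi_refdist <- function(x, ...) {
  tibble(
    median_sdi_h = median(x$distances$distance[x$distances$stratum == "SDI-H"]),
    median_sdi_l = median(x$distances$distance[x$distances$stratum == "SDI-L"]),
    statistic = x$test$statistic,
    p_value = x$test$p_value,
    n_pairs = nrow(x$distances)
  )
}
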