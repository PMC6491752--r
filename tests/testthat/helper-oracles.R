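# Independent oracles used across the suite. Each reimplements the quantity
# under test from first principles (enumeration, direct summation, hand
# formulas) without touching the package's code paths.

# Eq.-1 index by explicit per-genus looping over the sample's columns.
brute_sdi <- function(rel_tbl, signature) {
  ids <- rel_tbl$sample_id
  out <- numeric(length(ids))
  for (i in seq_along(ids)) {
    s_sum <- 0
    for (g in signature$stroke_enriched) {
      if (g %in% names(rel_tbl)) s_sum <- s_sum + rel_tbl[[g]][i]
    }
    c_sum <- 0
    for (g in signature$control_enriched) {
      if (g %in% names(rel_tbl)) c_sum <- c_sum + rel_tbl[[g]][i]
    }
    out[i] <- (s_sum / length(signature$stroke_enriched) -
                 c_sum / length(signature$control_enriched)) * 100
  }
  out
}

# Exhaustive two-sided rank-sum p by enumerating every labeling of the
# pooled values (valid with or without ties).
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  u_stat <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(m))
  combos <- utils::combn(n, m)
  mu <- m * (n - m) / 2
  us <- apply(combos, 2, u_stat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Mann-Whitney U (tie-averaged) computed directly from pair comparisons.
brute_u <- function(pos, neg) {
  sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
}

# Unweighted UniFrac by explicit branch-set enumeration on a rooted tree:
# an edge counts toward the union if its descendant tips intersect either
# community, toward the shared part if it intersects both.
oracle_unifrac <- function(tree, present_a, present_b) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  sets <- vector("list", max(tr$edge))
  for (k in seq_len(n_tip)) sets[[k]] <- tr$tip.label[k]
  for (i in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    sets[[pa]] <- c(sets[[pa]], sets[[ch]])
  }
  total <- 0; shared <- 0
  for (i in seq_len(nrow(tr$edge))) {
    tips <- sets[[tr$edge[i, 2]]]
    in_a <- any(tips %in% present_a)
    in_b <- any(tips %in% present_b)
    len <- tr$edge.length[i]
    if (in_a || in_b) {
      total <- total + len
      if (in_a && in_b) shared <- shared + len
    }
  }
  (total - shared) / total
}

# PERMANOVA pseudo-F from the within/between squared-distance decomposition.
brute_pseudo_f <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- unique(labels)
  ss_total <- sum(m[upper.tri(m)]^2) / n
  ss_within <- 0
  for (g in groups) {
    idx <- which(labels == g)
    sub <- m[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  k <- length(groups)
  list(f = (ss_between / (k - 1)) / (ss_within / (n - k)),
       r2 = ss_between / ss_total)
}

# All permutations of 1:n as rows (recursive construction).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Fisher two-sided p for a 2x2 table by hypergeometric enumeration.
enumerate_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small cohort spec used where full study sizes are unnecessary.
small_spec <- function(seed, n_cases = 30, n_controls = 30, n_genera = 40,
                       effect_log2fc = 1,
                       depth_range = c(3000L, 5000L)) {
  cohort_spec(n_cases = n_cases, n_controls = n_controls,
              n_genera = n_genera, effect_log2fc = effect_log2fc,
              sequencing_depth_range = depth_range, seed = seed)
}

# One pass of the downstream selection pipeline, returning the fraction of
# the planted signature recovered with the correct direction.
signature_recovery <- function(cohort, depth = 4800, seed = 1,
                               min_count_fraction = 0.001) {
  rel <- cohort$counts |>
    filter_low_abundance(min_count_fraction) |>
    rarefy_counts(depth, seed = seed) |>
    to_relative()
  sig <- suppressWarnings(select_signature(rel, cohort$clinical))
  planted <- cohort$truth$planted_signature
  (length(intersect(sig$stroke_enriched, planted$stroke_enriched)) +
      length(intersect(sig$control_enriched, planted$control_enriched))) /
    (length(planted$stroke_enriched) + length(planted$control_enriched))
}
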