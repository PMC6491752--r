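test_that("unweighted UniFrac matches hand branch enumeration", {
  # cherry with equal branches: disjoint single-genus samples are maximally far
  cherry <- ape::read.tree(text = "(A:1,B:1):0;")
  tbl <- tibble::tibble(sample_id = c("s1", "s2"), A = c(3L, 0L), B = c(0L, 5L))
  d <- unifrac_distances(tbl, cherry)
  expect_equal(as.matrix(d)["s1", "s2"], 1)

  # identical presence profiles are at distance zero
  same <- tibble::tibble(sample_id = c("s1", "s2"), A = c(3L, 1L), B = c(2L, 9L))
  expect_equal(max(unifrac_distances(same, cherry)), 0)

  # 4-leaf tree ((A:1,B:2):3,(C:4,D:5):6); samples {A,B} and {A,C}.
  # Branch classification: shared = A(1) and the AB stem (3, ancestral to a
  # taxon of both); one-sided = B(2), C(4), CD stem (6); D(5) absent.
  # distance = (2+4+6) / (1+2+3+4+6) = 12/16 = 0.75
  tr4 <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6):0;")
  tbl4 <- tibble::tibble(sample_id = c("s1", "s2"),
                         A = c(1L, 1L), B = c(1L, 0L),
                         C = c(0L, 1L), D = c(0L, 0L))
  expect_equal(as.matrix(unifrac_distances(tbl4, tr4))["s1", "s2"], 0.75)
  expect_equal(oracle_unifrac(tr4, c("A", "B"), c("A", "C")), 0.75)
})

test_that("UniFrac agrees with the oracle on random trees and is a metric", {
  set.seed(23)
  for (rep in 1:3) {
    tr <- simulate_genus_tree(paste0("g", 1:8), seed = rep)
    pres <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8,
                   dimnames = list(paste0("s", 1:5), paste0("g", 1:8)))
    pres[rowSums(pres) == 0, 1] <- 1L
    tbl <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(pres)),
                            tibble::as_tibble(pres))
    d <- as.matrix(unifrac_distances(tbl, tr))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(d[i, j],
                   oracle_unifrac(tr, colnames(pres)[pres[i, ] > 0],
                                  colnames(pres)[pres[j, ] > 0]),
                   tolerance = 1e-10)
    }
    expect_true(all(d >= 0 & d <= 1))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("UniFrac reports taxa missing from the tree", {
  tr <- ape::read.tree(text = "(A:1,B:1):0;")
  tbl <- tibble::tibble(sample_id = "s1", A = 1L, Zeta = 2L)
  expect_error(unifrac_distances(tbl, tr), "Zeta")
})

test_that("PCoA reproduces Euclidean configurations and orders axes", {
  pts <- rbind(c(0, 0), c(3, 0), c(3, 4))  # 3-4-5 right triangle
  rownames(pts) <- paste0("s", 1:3)
  d <- dist(pts)
  ord <- pcoa_ordination(d, k = 2)
  coords <- as.matrix(tidy(ord)[-1])
  expect_equal(as.numeric(dist(coords)), as.numeric(d), tolerance = 1e-9)
  eig <- ord$eigenvalues
  expect_true(all(diff(eig) <= 1e-9))

  zero <- as.dist(matrix(0, 3, 3, dimnames = list(paste0("s", 1:3),
                                                  paste0("s", 1:3))))
  z <- pcoa_ordination(zero, k = 2)
  expect_true(all(abs(as.matrix(tidy(z)[-1])) < 1e-12))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa_ordination(bad), "symmetric")
})

test_that("PERMANOVA statistics equal the decomposition oracle and the exhaustive p", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 1.2), 3, 2))
  rownames(pts) <- paste0("s", 1:6)
  d <- dist(pts)
  meta <- tibble::tibble(sample_id = paste0("s", 1:6),
                         group = rep(c("a", "b"), each = 3))
  res <- permanova_test(d, meta, n_permutations = 4999, seed = 2)
  oracle <- brute_pseudo_f(d, meta$group)
  expect_equal(res$pseudo_f, oracle$f, tolerance = 1e-10)
  expect_equal(res$r2, oracle$r2, tolerance = 1e-10)

  # exhaustive p over all 720 label orderings
  perms <- combinat_perms(6)
  f_obs <- oracle$f
  f_perm <- apply(perms, 1, function(ix) brute_pseudo_f(d, meta$group[ix])$f)
  p_exact <- mean(f_perm >= f_obs - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.02)  # 3 MC SEs at 4999 permutations
})

test_that("PERMANOVA p-values are calibrated under the null and saturate under separation", {
  set.seed(41)
  pts <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  d <- dist(pts)
  ps <- vapply(1:100, function(s) {
    meta <- tibble::tibble(sample_id = paste0("s", 1:12),
                           group = sample(rep(c("a", "b"), each = 6)))
    permanova_test(d, meta, n_permutations = 199, seed = s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  far <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
               matrix(rnorm(12, 50, 0.1), 6, 2))
  rownames(far) <- paste0("s", 1:12)
  meta <- tibble::tibble(sample_id = paste0("s", 1:12),
                         group = rep(c("a", "b"), each = 6))
  res <- permanova_test(dist(far), meta, n_permutations = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)

  # R2 invariant to distance scaling; F invariant to sample reordering
  res2 <- permanova_test(dist(far) * 7, meta, n_permutations = 99, seed = 1)
  expect_equal(res2$r2, res$r2, tolerance = 1e-12)
  ord <- sample(1:12)
  res3 <- permanova_test(as.dist(as.matrix(dist(far))[ord, ord]), meta,
                         n_permutations = 99, seed = 1)
  expect_equal(res3$pseudo_f, res$pseudo_f, tolerance = 1e-8)

  solo <- tibble::tibble(sample_id = paste0("s", 1:12),
                         group = c("a", rep("b", 11)))
  expect_error(permanova_test(dist(far), solo, n_permutations = 9),
               "fewer than 2")
})

test_that("a stratum with more presence-level disruption sits farther from controls", {
  # SDI-H communities flip more taxa relative to the healthy reference than
  # SDI-L communities do, so their UniFrac distances to controls should be
  # stochastically larger
  set.seed(97)
  genera <- paste0("g", 1:20)
  tree <- simulate_genus_tree(genera, seed = 97)
  base <- c(rep(1L, 12), rep(0L, 8))
  flip <- function(n_flip) {
    v <- base
    ix <- sample(20, n_flip)
    v[ix] <- 1L - v[ix]
    if (sum(v) == 0) v[1] <- 1L
    v
  }
  rows <- rbind(
    do.call(rbind, lapply(1:8, function(i) flip(1))),   # controls
    do.call(rbind, lapply(1:8, function(i) flip(2))),   # SDI-L: mild
    do.call(rbind, lapply(1:8, function(i) flip(8)))    # SDI-H: disrupted
  )
  ids <- c(paste0("ctl", 1:8), paste0("lo", 1:8), paste0("hi", 1:8))
  dimnames(rows) <- list(ids, genera)
  tbl <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                          tibble::as_tibble(rows))
  d <- unifrac_distances(tbl, tree)
  strata <- tibble::tibble(
    sample_id = c(paste0("lo", 1:8), paste0("hi", 1:8)),
    stratum = rep(c("SDI-L", "SDI-H"), each = 8))
  res <- distances_to_reference(d, strata, paste0("ctl", 1:8))
  g <- glance(res)
  expect_gt(g$median_sdi_h, g$median_sdi_l)
  expect_lt(g$p_value, 0.05)
})

test_that("distances to the reference stratify and count correctly", {
  m <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  m[upper.tri(m)] <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15)
  m <- m + t(m)
  strata <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                           stratum = c("SDI-H", "SDI-H", "SDI-L", "SDI-L"))
  ref <- c("s5", "s6")
  res <- distances_to_reference(as.dist(m), strata, ref)
  expect_equal(nrow(tidy(res)), 4 * 2)
  expect_equal(sum(tidy(res)$stratum == "SDI-H"), 2 * 2)
  expect_equal(tidy(res)$distance[1], m["s1", "s5"])

  # identical distance profiles in both strata: rank-sum p = 1
  m2 <- matrix(1, 6, 6, dimnames = dimnames(m)); diag(m2) <- 0
  res2 <- distances_to_reference(as.dist(m2), strata, ref)
  expect_equal(glance(res2)$p_value, 1)

  expect_error(distances_to_reference(as.dist(m), strata, c("s4", "s5")),
               "disjoint")
})
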