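#' Specification of a synthetic case-control cohort
#'
#' Defines the statistical structure of a simulated genus-level 16S cohort:
#' a Dirichlet-multinomial count model with a planted directional signature
#' (case samples have stroke-enriched genus concentrations multiplied by
#' `2^effect_log2fc` and control-enriched ones divided by it) and clinical
#' severity/outcome scores linked to each sample's true index value.
#'
#' Defaults mirror the published training cohort: 104 cases, 90 controls,
#' the 18 planted genera of [preset_signature()] among 120 genera, a twofold
#' planted effect, sequencing depths uniform on 8000-15000 (so both the
#' 4800-read index depth and the 8000-read diversity depth are attainable),
#' and clinical links calibrated so the Spearman correlation between the
#' index and the severity score lands in the reported 0.2-0.45 range.
#' Unplanted genus concentrations follow a long-tailed log-normal prior so
#' that a realistic fraction of genera falls below the 0.1% abundance
#' filter.
#'
#' @param n_cases,n_controls Cohort sizes; defaults 104 / 90.
#' @param n_genera Total number of genera (>= number of planted genera);
#'   default 120.
#' @param planted_signature An [sdi_signature()] naming the planted genera
#'   and their directions; default [preset_signature()] (7 + 11 genera).
#' @param effect_log2fc Non-negative log2 fold change applied to planted
#'   genus concentrations in case samples; default 1.
#' @param base_concentration Named positive Dirichlet concentration vector,
#'   one entry per genus; default drawn deterministically from `seed`
#'   (planted genera at intermediate abundance, unplanted log-normal with a
#'   rare tail, total concentration 200).
#' @param sequencing_depth_range Integer `[min, max]` read depths per
#'   sample; default `c(8000, 15000)`.
#' @param clinical_link List with `beta_severity` (NIHSS points per SD of
#'   true index), `beta_outcome` (latent logit slope for the mRS link) and
#'   `noise_sd` (NIHSS noise SD); defaults 2.5 / 0.8 / 6.5.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_cases = 104, n_controls = 90, n_genera = 120,
                        planted_signature = NULL, effect_log2fc = 1,
                        base_concentration = NULL,
                        sequencing_depth_range = c(8000L, 15000L),
                        clinical_link = list(beta_severity = 2.5,
                                             beta_outcome = 0.8,
                                             noise_sd = 6.5),
                        seed = 1L) {
  planted_signature <- planted_signature %||% preset_signature()
  if (!inherits(planted_signature, "sdi_signature")) {
    abort("`planted_signature` must be an sdi_signature")
  }
  planted <- c(planted_signature$stroke_enriched,
               planted_signature$control_enriched)
  if (n_genera < length(planted)) {
    abort("`n_genera` must be at least the number of planted genera")
  }
  if (length(sequencing_depth_range) != 2 ||
      any(sequencing_depth_range < 1) ||
      sequencing_depth_range[1] > sequencing_depth_range[2]) {
    abort("invalid spec: sequencing depth range must be [min, max] with min >= 1")
  }
  if (effect_log2fc < 0) abort("`effect_log2fc` must be non-negative")
  if (is.null(base_concentration)) {
    genera <- c(planted,
                sprintf("Genus%03d", seq_len(n_genera - length(planted))))
    base_concentration <- withr::with_seed(as.integer(seed) + 77L, {
      w <- c(stats::rlnorm(length(planted), meanlog = 0, sdlog = 0.4),
             stats::rlnorm(n_genera - length(planted),
                           meanlog = log(0.25), sdlog = 1.5))
      setNames(200 * w / sum(w), genera)
    })
  } else {
    genera <- names(base_concentration)
    if (is.null(genera) || length(genera) != n_genera) {
      abort("`base_concentration` must be named, one entry per genus")
    }
  }
  if (any(base_concentration <= 0)) abort("all concentrations must be > 0")
  if (!all(planted %in% genera)) {
    abort("planted genera must be a subset of the genus names")
  }
  stopifnot(is.list(clinical_link),
            all(c("beta_severity", "beta_outcome", "noise_sd") %in%
                  names(clinical_link)))
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_genera = as.integer(n_genera),
         planted_signature = planted_signature,
         effect_log2fc = effect_log2fc,
         base_concentration = base_concentration,
         sequencing_depth_range = as.integer(sequencing_depth_range),
         clinical_link = clinical_link, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_cases, " cases / ", x$n_controls, " controls, ",
      x$n_genera, " genera (",
      length(x$planted_signature$stroke_enriched), "+",
      length(x$planted_signature$control_enriched),
      " planted), effect log2FC = ", x$effect_log2fc,
      ", depths ", x$sequencing_depth_range[1], "-",
      x$sequencing_depth_range[2], ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a case-control cohort
#'
#' Draws per-sample genus counts from a Dirichlet-multinomial model with the
#' planted effects of the spec, computes each sample's true index value from
#' the realized relative abundances and the planted signature, and generates
#' linked clinical records: NIHSS on admission as a monotone noisy function
#' of the true index (rounded, clipped to 0-42), NIHSS at discharge as a
#' damped copy, and mRS at discharge through proportional-odds thresholds on
#' a latent score. Covariates follow the marginal patterns of a
#' stroke/control baseline table but are conditionally independent of
#' outcome given group. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An `sdi_cohort`: list with `counts` (abundance tibble),
#'   `clinical` (metadata tibble) and `truth` (`true_sdi` tibble plus the
#'   planted signature).
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec")
  withr::with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_cases + spec$n_controls
  genera <- names(spec$base_concentration)
  sig <- spec$planted_signature
  group <- rep(c("stroke", "control"), c(spec$n_cases, spec$n_controls))
  ids <- sprintf("%s%03d", ifelse(group == "stroke", "P", "C"),
                 c(seq_len(spec$n_cases), seq_len(spec$n_controls)))

  alpha_case <- spec$base_concentration
  alpha_case[sig$stroke_enriched] <-
    alpha_case[sig$stroke_enriched] * 2^spec$effect_log2fc
  alpha_case[sig$control_enriched] <-
    alpha_case[sig$control_enriched] / 2^spec$effect_log2fc

  depths <- sample(seq(spec$sequencing_depth_range[1],
                       spec$sequencing_depth_range[2]), n, replace = TRUE)
  counts <- matrix(0L, n, length(genera), dimnames = list(ids, genera))
  for (i in seq_len(n)) {
    alpha <- if (group[i] == "stroke") alpha_case else spec$base_concentration
    p <- rgamma(length(alpha), shape = alpha)
    p <- p / sum(p)
    counts[i, ] <- as.integer(rmultinom(1, depths[i], p))
  }

  rel <- 100 * counts / rowSums(counts)
  true_sdi <- (rowSums(rel[, sig$stroke_enriched, drop = FALSE]) /
                 length(sig$stroke_enriched) -
               rowSums(rel[, sig$control_enriched, drop = FALSE]) /
                 length(sig$control_enriched)) * 100

  clinical <- simulate_clinical(ids, group, true_sdi, spec$clinical_link)

  structure(
    list(counts = matrix_to_tbl(counts),
         clinical = clinical,
         truth = list(true_sdi = tibble(sample_id = ids, true_sdi = true_sdi),
                      planted_signature = sig)),
    class = "sdi_cohort"
  )
}

simulate_clinical <- function(ids, group, true_sdi, link) {
  n <- length(ids)
  case <- group == "stroke"
  z <- rep(0, n)
  z[case] <- as.numeric(scale(true_sdi[case]))

  nihss_in <- rep(NA_integer_, n)
  nihss_in[case] <- as.integer(round(pmin(pmax(
    4 + link$beta_severity * z[case] + rnorm(sum(case), 0, link$noise_sd),
    0), 42)))
  nihss_out <- rep(NA_integer_, n)
  nihss_out[case] <- as.integer(round(pmin(pmax(
    0.7 * nihss_in[case] + rnorm(sum(case), 0, 1.5), 0), 42)))

  # proportional-odds mRS: latent logistic score shifted by the true index;
  # cutpoints put ~25% of baseline patients above mRS 2
  cutpoints <- c(-1.5, -0.3, 1.1, 2.2, 3.5)
  latent <- link$beta_outcome * z[case] + rlogis(sum(case))
  mrs_out <- rep(NA_integer_, n)
  mrs_out[case] <- as.integer(findInterval(latent, cutpoints))

  rb <- function(p_case, p_ctrl) {
    as.integer(runif(n) < ifelse(case, p_case, p_ctrl))
  }
  rn <- function(m_case, m_ctrl, s) {
    round(rnorm(n, ifelse(case, m_case, m_ctrl), s), 2)
  }
  tibble(
    sample_id = ids, group = group,
    nihss_in = nihss_in, nihss_out = nihss_out, mrs_out = mrs_out,
    age = as.integer(pmin(pmax(round(rnorm(n, ifelse(case, 59, 57), 10)),
                               18), 80)),
    sex = ifelse(runif(n) < ifelse(case, 0.75, 0.81), "male", "female"),
    hypertension = rb(0.79, 0.28), diabetes = rb(0.44, 0.05),
    cad = rb(0.04, 0.01), smoking = rb(0.40, 0.30), alcohol = rb(0.20, 0.15),
    wbc = pmax(rn(7.9, 6.6, 1.8), 2), glucose = pmax(rn(6.0, 4.9, 1.5), 3),
    cr = pmax(rn(77, 73.5, 18), 30), ua = pmax(rn(357, 387, 80), 100),
    tg = pmax(rn(1.4, 1.4, 0.6), 0.3), tc = pmax(rn(4.6, 5.05, 1.0), 2),
    hdl = pmax(rn(0.91, 1.14, 0.25), 0.4),
    ldl = pmax(rn(2.98, 3.26, 0.8), 1),
    hba1c = pmax(rn(6.5, 5.5, 1.0), 4)
  )
}

#' @export
print.sdi_cohort <- function(x, ...) {
  g <- table(x$clinical$group)
  cat("<sdi_cohort> ", nrow(x$counts), " samples (",
      paste(paste0(g, " ", names(g)), collapse = ", "), "), ",
      ncol(x$counts) - 1, " genera\n", sep = "")
  invisible(x)
}

#' Simulate a random genus tree
#'
#' Random rooted bifurcating tree over the given genus names with positive
#' branch lengths (uniform on (0, 1)); supports genus-level UniFrac when no
#' reference phylogeny is available. With n leaves the tree has n - 1
#' internal nodes; the Newick serialization round-trips.
#'
#' @param genus_names Unique character vector, length >= 2.
#' @param seed Integer seed; the topology and branch lengths are
#'   deterministic given it.
#' @return An [ape] `phylo` object.
#' @export
simulate_genus_tree <- function(genus_names, seed = 1) {
  if (length(genus_names) < 2) abort("need at least 2 genus names")
  if (anyDuplicated(genus_names)) {
    abort(paste0("duplicate genus names: ",
                 paste(unique(genus_names[duplicated(genus_names)]),
                       collapse = ", ")))
  }
  withr::with_seed(as.integer(seed), {
    tr <- ape::rtree(length(genus_names), rooted = TRUE,
                     tip.label = genus_names)
    tr$edge.length <- pmax(tr$edge.length, 1e-3)
    tr
  })
}
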