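# Tissue-breadth scoring with the tau statistic, breadth classification,
# and the top-decile intensity enrichment test.

#' Tissue-specificity tau statistic
#'
#' tau = sum_i (1 - x_i / x_max) / (N - 1) over N tissues: 0 for uniform
#' expression, 1 for single-tissue expression.
#'
#' @param profile non-negative per-tissue expression vector (N >= 2,
#'   max > 0).
#' @return tau in \[0, 1\].
#' @examples
#' tau(c(8, 4, 2, 2))  # 2/3
#' @export
tau <- function(profile) {
  if (length(profile) < 2L) stop2("tau needs at least 2 tissues")
  if (anyNA(profile)) stop2("missing values in profile")
  if (any(profile < 0)) stop2("negative expression value")
  mx <- max(profile)
  if (mx == 0) stop2("undefined tau: all-zero profile")
  sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Classify expression breadth from tau
#'
#' @param tau_value tau in \[0, 1\] (vectorized).
#' @param low housekeeping cutoff: tau < `low` (default 0.15).
#' @param high narrow cutoff: tau > `high` (default 0.85; both strict).
#' @return `"housekeeping"`, `"intermediate"` or `"narrow"`.
#' @export
breadth_classify <- function(tau_value, low = 0.15, high = 0.85) {
  stopifnot(0 <= low, low < high, high <= 1)
  if (anyNA(tau_value) || any(tau_value < 0) || any(tau_value > 1))
    stop2("tau must lie in [0, 1]")
  ifelse(tau_value < low, "housekeeping",
         ifelse(tau_value > high, "narrow", "intermediate"))
}

#' Per-gene tau table from an atlas
#'
#' Builds per-tissue profiles (sexes combined by the mean of the sex means,
#' probes collapsed by the per-tissue maximum, log2 values floored at 0) and
#' scores every gene.
#'
#' @param atlas an `expression_atlas`.
#' @param detection optional `detection_table`; when supplied, a gene's
#'   profile uses only tissues where the gene is consensus-detected in at
#'   least one sex (genes detected in < 2 tissues are dropped with a tally).
#' @param low,high breadth cutoffs as in [breadth_classify()].
#' @return data.frame `gene`, `tau`, `breadth`, `peak_tissue`; attribute
#'   `n_dropped` counts genes without a scoreable profile.
#' @export
tau_table <- function(atlas, detection = NULL, low = 0.15, high = 0.85) {
  prof <- combine_sexes(tissue_sex_means(atlas))
  prof <- collapse_probes(prof, atlas$probes)
  prof[prof < 0] <- 0
  det_gene <- NULL
  if (!is.null(detection)) {
    gene <- atlas$probes$gene[match(detection$probe, atlas$probes$probe)]
    agg <- stats::aggregate(
      detected ~ g + tissue,
      data = data.frame(detected = detection$detected, g = gene,
                        tissue = detection$tissue), FUN = any)
    det_gene <- agg[agg$detected, ]
  }
  res <- lapply(rownames(prof), function(g) {
    x <- prof[g, ]
    if (!is.null(det_gene)) {
      keep <- colnames(prof) %in% det_gene$tissue[det_gene$g == g]
      x <- x[keep]
    }
    if (length(x) < 2L || max(x) == 0) return(NULL)
    data.frame(gene = g, tau = tau(x),
               peak_tissue = names(x)[which.max(x)],
               stringsAsFactors = FALSE)
  })
  drop_n <- sum(vapply(res, is.null, logical(1)))
  out <- do.call(rbind, res)
  out$breadth <- breadth_classify(out$tau, low, high)
  out <- out[, c("gene", "tau", "breadth", "peak_tissue")]
  attr(out, "n_dropped") <- drop_n
  rownames(out) <- NULL
  out
}

#' Top-decile intensity enrichment of a gene set
#'
#' Tests whether members of `gene_set` are over-represented in the top 10%
#' of an intensity ranking: df-1 chi-squared on the observed vs expected
#' in/out-of-decile split of the set (no continuity correction).
#'
#' @param gene_set character vector of genes, all present in `ranking`.
#' @param ranking character vector of all genes ordered by decreasing
#'   intensity in one tissue (length >= 10).
#' @param decile fraction defining the top bin (default 0.10).
#' @return a [chi_square_result()].
#' @export
top_decile_enrichment <- function(gene_set, ranking, decile = 0.10) {
  if (length(gene_set) == 0L) stop2("empty gene set")
  if (length(ranking) < 10L) stop2("ranking needs >= 10 genes")
  if (anyDuplicated(ranking)) stop2("duplicated genes in ranking")
  missing <- setdiff(gene_set, ranking)
  if (length(missing))
    stop2("gene(s) in set but not in ranking: ",
          paste(utils::head(missing, 5L), collapse = ", "))
  n_top <- max(1L, floor(decile * length(ranking)))
  p_top <- n_top / length(ranking)
  obs_in <- sum(gene_set %in% ranking[seq_len(n_top)])
  obs <- c(top = obs_in, rest = length(gene_set) - obs_in)
  ct <- stats::chisq.test(obs, p = c(p_top, 1 - p_top))
  chi_square_result(ct$statistic, ct$parameter, ct$p.value,
                    observed = obs, expected = c(ct$expected),
                    method = sprintf("top-%d%% intensity enrichment",
                                     round(100 * decile)))
}
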