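# Gene-wise differential expression between two sample groups with
# empirical-Bayes variance moderation: male-vs-female sex bias per tissue,
# and gonad-vs-carcass enrichment within one sex.
#
# The per-gene model is the two-group linear model on log2 intensities; the
# residual variances s^2 (df d) are shrunk towards a scaled inverse-chi-square
# prior (s0^2, d0) fit by method of moments, giving posterior variances
# s~^2 = (d0*s0^2 + d*s^2)/(d0 + d) and a moderated t with d0 + d df.

# Method-of-moments fit of the variance prior: marginally s^2/s0^2 ~ F(d, d0),
# so CV^2(s^2) = 2(d + d0 - 2)/(d(d0 - 4)). Solve for d0 from the sample CV;
# non-informative samples give d0 = Inf (complete shrinkage to the mean).
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) return(list(d0 = 0, s0 = NA_real_))
  m1 <- mean(s2)
  cv2 <- stats::var(s2) / m1^2
  denom <- cv2 * d - 2
  if (denom <= 0) return(list(d0 = Inf, s0 = m1))
  d0 <- (4 * cv2 * d + 2 * d - 4) / denom  # always > 4 when denom > 0
  s0 <- m1 * (d0 - 2) / d0
  if (!is.finite(s0) || s0 <= 0) return(list(d0 = 0, s0 = NA_real_))
  list(d0 = d0, s0 = s0)
}

# Moderated two-group comparison: x1, x2 are gene x replicate matrices on
# the log2 scale; effect = rowMeans(x1) - rowMeans(x2).
moderated_two_group <- function(x1, x2, prior_df = NULL) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop2("each group needs at least 2 replicates")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  d <- n1 + n2 - 2L
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- rss / d
  if (is.null(prior_df)) {
    pr <- fit_variance_prior(s2, d)
  } else if (prior_df == 0) {
    pr <- list(d0 = 0, s0 = NA_real_)
  } else {
    pr <- list(d0 = prior_df, s0 = mean(s2[s2 > 0]))
  }
  d0 <- pr$d0
  s2_post <- if (d0 == 0) s2
  else if (is.infinite(d0)) rep(pr$s0, length(s2))
  else (d0 * pr$s0 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  eff <- m1 - m2
  t <- eff / se
  df_t <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(t), df = df_t)
  flag <- !is.finite(t)
  p[flag] <- NA_real_
  list(effect = eff, t = t, p = p, s2 = s2, s2_post = s2_post,
       df = d, prior_df = d0, prior_var = pr$s0, flagged = flag)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' q_i = min over j with p_(j) >= p_(i) of p_(j) * n / rank(j), capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NAs allowed and
#'   propagated).
#' @return q-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) stop2("empty p-value vector")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0) || any(p_values[ok] > 1))
    stop2("p_values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Sex-biased expression within one tissue
#'
#' Fits the gene-wise moderated two-group model female vs male on log2
#' intensities and classifies genes: `female_biased` if the log2
#' female-minus-male effect M >= `fold_threshold_log2` with
#' q < `q_threshold`; `male_biased` symmetrically; otherwise `unbiased`.
#' The fold rule is applied to the model's M estimate.
#'
#' @param atlas an `expression_atlas`.
#' @param tissue tissue to test (needs >= 2 replicates per sex).
#' @param fold_threshold_log2 minimum |M| (default 1 = 2-fold).
#' @param q_threshold BH q cutoff (default 0.05).
#' @param probes optional probe subset (e.g. consensus-detected in >= 1 sex);
#'   detection filtering is the caller's responsibility.
#' @param prior_df override for the moderation prior df (0 = ordinary
#'   two-sample t; `NULL` = method-of-moments estimate).
#' @return data.frame with columns `probe`, `gene`, `tissue`, `m_value`,
#'   `t`, `p_value`, `q_value`, `class`, `flagged`.
#' @export
fit_sex_bias <- function(atlas, tissue, fold_threshold_log2 = 1,
                         q_threshold = 0.05, probes = NULL, prior_df = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  iF <- sample_index(atlas, tissue, "female")
  iM <- sample_index(atlas, tissue, "male")
  if (length(iF) < 2L || length(iM) < 2L)
    stop2("tissue '", tissue, "' needs >= 2 replicates per sex")
  v <- atlas$values
  if (!is.null(probes)) v <- v[rownames(v) %in% probes, , drop = FALSE]
  fit <- moderated_two_group(v[, iF, drop = FALSE], v[, iM, drop = FALSE],
                             prior_df = prior_df)
  q <- bh_fdr(fit$p)
  cls <- rep("unbiased", nrow(v))
  sig <- !is.na(q) & q < q_threshold & abs(fit$effect) >= fold_threshold_log2
  cls[sig & fit$effect > 0] <- "female_biased"
  cls[sig & fit$effect < 0] <- "male_biased"
  data.frame(probe = rownames(v),
             gene = atlas$probes$gene[match(rownames(v), atlas$probes$probe)],
             tissue = tissue, m_value = unname(fit$effect),
             t = unname(fit$t), p_value = unname(fit$p), q_value = q,
             class = cls, flagged = unname(fit$flagged),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gonad-vs-carcass enrichment within one sex
#'
#' Same moderated model contrasting the gonad against the carcass within one
#' sex; a gene is enriched iff M = log2(gonad) - log2(carcass) strictly
#' exceeds `m_threshold` (default 2) with q < `q_threshold`.
#'
#' @param atlas an `expression_atlas`.
#' @param gonad_tissue,carcass_tissue tissue labels.
#' @param sex `"male"` or `"female"`.
#' @param m_threshold log2-ratio threshold (strict inequality).
#' @param q_threshold BH q cutoff.
#' @param probes optional probe subset.
#' @param prior_df moderation override as in [fit_sex_bias()].
#' @return data.frame with `probe`, `gene`, `m_value`, `p_value`, `q_value`,
#'   `enriched`.
#' @export
gonad_enrichment <- function(atlas, gonad_tissue = "gonad",
                             carcass_tissue = "carcass", sex,
                             m_threshold = 2, q_threshold = 0.05,
                             probes = NULL, prior_df = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  iG <- sample_index(atlas, gonad_tissue, sex)
  iC <- sample_index(atlas, carcass_tissue, sex)
  if (length(iG) < 2L || length(iC) < 2L)
    stop2("both tissues need >= 2 replicates for sex '", sex, "'")
  v <- atlas$values
  if (!is.null(probes)) v <- v[rownames(v) %in% probes, , drop = FALSE]
  fit <- moderated_two_group(v[, iG, drop = FALSE], v[, iC, drop = FALSE],
                             prior_df = prior_df)
  q <- bh_fdr(fit$p)
  data.frame(probe = rownames(v),
             gene = atlas$probes$gene[match(rownames(v), atlas$probes$probe)],
             m_value = unname(fit$effect), p_value = unname(fit$p),
             q_value = q,
             enriched = !is.na(q) & q < q_threshold & fit$effect > m_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary of sexual dimorphism across tissues
#'
#' Per-tissue counts of female- and male-biased genes, the female:male ratio,
#' a df-1 chi-squared test of deviation from 1:1, and the overall fraction of
#' genes dimorphic in at least one tissue (each gene counted once).
#'
#' @param records row-bound output of [fit_sex_bias()] over tissues.
#' @return list with `per_tissue` (data.frame: tissue, n_female, n_male,
#'   ratio, chi2, p_value) and `overall_fraction`.
#' @export
dimorphism_summary <- function(records) {
  if (nrow(records) == 0L) stop2("no records")
  tissues <- unique(records$tissue)
  per <- do.call(rbind, lapply(tissues, function(tt) {
    r <- records[records$tissue == tt, ]
    nf <- sum(r$class == "female_biased")
    nm <- sum(r$class == "male_biased")
    if (nf + nm > 0) {
      e <- (nf + nm) / 2
      chi2 <- (nf - e)^2 / e + (nm - e)^2 / e
      p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    } else {
      chi2 <- 0; p <- 1
    }
    data.frame(tissue = tt, n_female = nf, n_male = nm,
               ratio = if (nm > 0) nf / nm else NA_real_,
               chi2 = chi2, p_value = p, stringsAsFactors = FALSE)
  }))
  biased <- unique(records$gene[records$class != "unbiased"])
  list(per_tissue = per,
       overall_fraction = length(biased) / length(unique(records$gene)))
}
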