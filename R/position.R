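# Chromosome-arm distribution tests: is a gene set distributed over the
# arms {X, 2R, 2L, 3R, 3L} as the background predicts, and on which arms
# does it deviate?

#' Chromosome-arm distribution test for a gene set
#'
#' Goodness-of-fit chi-squared of the gene set's arm counts against the
#' background arm proportions; standardized residuals (O - E)/sqrt(E) give
#' the direction of departure per arm (X depletion shows as a negative X
#' residual). Genes with arm `"unknown"` (or absent from the background) are
#' excluded and tallied. When any expected count falls below 1, the
#' chi-squared tail is replaced by a seeded Monte-Carlo multinomial p-value.
#'
#' @param gene_set character vector of gene ids.
#' @param background named character vector gene -> arm defining the null
#'   proportions (at least 2 arms represented).
#' @param arms arm labels considered (default X, 2R, 2L, 3R, 3L).
#' @param mc_B Monte-Carlo draws for the small-expected fallback.
#' @param seed seed for the fallback.
#' @return a [chi_square_result()] with attribute `n_dropped`.
#' @export
arm_distribution <- function(gene_set, background,
                             arms = c("X", "2R", "2L", "3R", "3L"),
                             mc_B = 10000L, seed = 1729L) {
  if (length(gene_set) == 0L) stop2("empty gene set")
  bg <- background[background %in% arms]
  if (length(unique(bg)) < 2L)
    stop2("background must cover at least 2 arms")
  prop <- as.numeric(table(factor(bg, levels = arms))) / length(bg)
  names(prop) <- arms
  set_arm <- background[match(gene_set, names(background))]
  keep <- !is.na(set_arm) & set_arm %in% arms
  n_dropped <- sum(!keep)
  set_arm <- set_arm[keep]
  if (length(set_arm) == 0L) stop2("no gene in the set has a known arm")
  obs <- as.numeric(table(factor(set_arm, levels = arms)))
  names(obs) <- arms
  used <- prop > 0
  expected <- length(set_arm) * prop[used] / sum(prop[used])
  observed <- obs[used]
  if (any(expected < 1)) {
    warning("expected count < 1; using Monte-Carlo multinomial p-value",
            call. = FALSE)
    ct <- with_seed(seed,
      stats::chisq.test(observed, p = prop[used] / sum(prop[used]),
                        simulate.p.value = TRUE, B = mc_B))
    df <- NA_integer_
  } else {
    # small-count accuracy is governed by the expected < 1 fallback above
    ct <- suppressWarnings(
      stats::chisq.test(observed, p = prop[used] / sum(prop[used])))
    df <- unname(ct$parameter)
  }
  out <- chi_square_result(ct$statistic, df, ct$p.value,
                           observed = observed, expected = expected,
                           method = "chromosome-arm distribution test")
  attr(out, "n_dropped") <- n_dropped
  out
}
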