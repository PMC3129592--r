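test_that("site counting matches known codon values and conserves 3 per codon", {
  s <- count_sites("TTTATGTAA")  # TTT + ATG, terminal stop excluded
  expect_equal(s$syn_sites, 1 / 3)      # TTT: only TTT->TTC synonymous
  expect_equal(s$nonsyn_sites, 8 / 3 + 3)  # ATG: no synonymous change
  expect_equal(s$n_codons, 2)
  expect_error(count_sites("TTTTAAATG"), "internal stop")
  expect_error(count_sites("TTTANG"), "ambiguous|invalid")
  expect_error(count_sites("TTTT"), "multiple of 3")
})

test_that("site counts agree with brute-force enumeration for all 61 sense codons", {
  for (cod in setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))) {
    oracle <- oracle_codon_sites(cod)
    got <- count_sites(paste0(cod, "TAA"))
    expect_equal(got$syn_sites, unname(oracle["syn"]), tolerance = 1e-12)
    expect_equal(got$syn_sites + got$nonsyn_sites, 3, tolerance = 1e-12)
  }
})

test_that("SNP classification matches the translation oracle", {
  expect_equal(classify_snp("TTTAAA", 3, "T", "C"), "synonymous")   # TTC = Phe
  expect_equal(classify_snp("ATGAAA", 3, "G", "A"), "nonsynonymous") # ATA = Ile
  expect_equal(classify_snp("TACAAA", 3, "C", "A"), "nonsynonymous") # TAA = stop
  expect_error(classify_snp("TTTAAA", 9, "T", "C"), "outside")
  expect_error(classify_snp("TTTAAA", 1, "A", "C"), "REF mismatch")
  set.seed(77)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (i in 1:1000) {
    cod <- sample(sense, 1)
    p <- sample(3, 1)
    ref <- substring(cod, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mut <- cod; substring(mut, p, p) <- alt
    aa_ref <- oracle_translate(cod); aa_alt <- oracle_translate(mut)
    want <- if (aa_alt == aa_ref) "synonymous" else "nonsynonymous"
    expect_equal(classify_snp(paste0(cod, "AAA"), p, ref, alt), want)
  }
})

test_that("pooled A/S arithmetic is exact", {
  # printed-rate worked example: A = 0.0033, S = 0.0068 -> 0.49 at 2 dp
  expect_equal(round(as_ratio_from_rates(0.0033, 0.0068), 2), 0.49)
  # one gene, hand-computable counts: 100 syn sites needs a synthetic gene;
  # use the count-free arithmetic route
  expect_equal(as_ratio_from_rates(5 / 200, 10 / 100), 0.25)
  # zero nonsynonymous SNPs -> A = 0, ratio 0
  cds <- c(g1 = "TTTTTCTTTTTCTTTTTCTAA")
  snps <- data.frame(gene = "g1", pos = 3, ref = "T", alt = "C")
  est <- as_ratio(cds, snps)
  expect_equal(est$A, 0)
  expect_equal(est$ratio, 0)
  # no synonymous SNPs -> undefined, flagged not numeric
  snps2 <- data.frame(gene = "g1", pos = 1, ref = "T", alt = "A")
  est2 <- as_ratio(cds, snps2)
  expect_true(est2$undefined)
  expect_true(is.na(est2$ratio))
})

test_that("gene bootstrap is deterministic, degenerate-safe and validated", {
  ss <- simulate_snps(sim_snp_config(n_genes_per_regime = 40,
                                     regimes = c(neutral = 1), seed = 6))
  b1 <- bootstrap_as(ss$cds, ss$snps, B = 200, seed = 42)
  b2 <- bootstrap_as(ss$cds, ss$snps, B = 200, seed = 42)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_true(b1$ci_low <= b1$ratio && b1$ratio <= b1$ci_high)
  expect_error(bootstrap_as(ss$cds, ss$snps, B = 50), "at least 100")
  # identical genes: no resampling variance
  cds <- rep(c(x = "TTTATGAAATAA"), 5)
  names(cds) <- paste0("g", 1:5)
  snps <- data.frame(gene = names(cds), pos = 3, ref = "T", alt = "C")
  snps <- rbind(snps, data.frame(gene = names(cds), pos = 4, ref = "A",
                                 alt = "C"))
  b <- bootstrap_as(cds, snps, B = 100, seed = 1)
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$ci_low, b$ratio)
})

test_that("bootstrap CI width shrinks with gene count", {
  widths <- vapply(c(50, 200, 800), function(n) {
    ss <- simulate_snps(sim_snp_config(n_genes_per_regime = n,
                                       regimes = c(neutral = 1), seed = 99))
    b <- bootstrap_as(ss$cds, ss$snps, B = 300, seed = 5)
    b$ci_high - b$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("snp_density is SNPs per kilobase", {
  expect_equal(snp_density(5, 1000), 5)
  expect_equal(snp_density(0, 500), 0)
  expect_equal(round(snp_density(316043, 43956000), 2), 7.19)
  expect_error(snp_density(5, 0), "positive")
})

test_that("A/S contrast reproduces the 2x2 chi-squared formula", {
  r <- as_contrast(c(30, 10), c(100, 100))
  m <- rbind(c(30, 10), c(100, 100))
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(r$statistic, sum((m - E)^2 / E), tolerance = 1e-10)
  expect_equal(round(r$statistic, 3), 8.392)
  expect_equal(r$df, 1)
  # proportionally identical sets: no signal
  expect_equal(as_contrast(c(30, 15), c(60, 30))$statistic, 0)
  expect_error(as_contrast(c(30, 10), c(0, 0)), "at least 1 SNP")
})
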