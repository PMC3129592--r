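test_that("bh_fdr implements the step-up rule and validates input", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "empty")
  # permutation equivariance
  set.seed(2); p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # monotone step-up never drops below the raw p
  expect_true(all(bh_fdr(p) >= p))
})

test_that("identical male/female values are unbiased with m = 0", {
  vals <- matrix(6, 4, 4, dimnames = list(
    letters[1:4], c("head:female", "head:male", "gonad:female", "gonad:male")))
  vals[, ] <- rnorm(16, 8)
  vals[, "head:male"] <- vals[, "head:female"]  # sexes identical in head
  a <- toy_atlas(vals)
  r <- fit_sex_bias(a, "head")
  expect_equal(r$m_value, rep(0, 4))
  expect_true(all(r$class == "unbiased"))
})

test_that("the fold rule vetoes significant sub-threshold effects", {
  set.seed(7)
  # 200 null genes + one gene with a reproducible 0.8-log2 shift
  ng <- 201
  vals <- matrix(rnorm(ng * 4, 8, 0.5), ng, 4,
                 dimnames = list(sprintf("g%03d", 1:ng),
                                 c("head:female", "head:male",
                                   "gonad:female", "gonad:male")))
  a <- toy_atlas(vals)
  v <- a$values
  iF <- which(a$samples$tissue == "head" & a$samples$sex == "female")
  iM <- which(a$samples$tissue == "head" & a$samples$sex == "male")
  v["p.g001", iF] <- 9.0 + c(-.01, .01, -.01, .01)
  v["p.g001", iM] <- 8.2 + c(-.01, .01, -.01, .01)
  a$values <- v
  r <- fit_sex_bias(a, "head")
  g1 <- r[r$gene == "g001", ]
  expect_lt(g1$q_value, 1e-4)
  expect_equal(g1$class, "unbiased")   # |m| = 0.8 < 1
})

test_that("with prior_df = 0 the moderated t equals the ordinary t", {
  sim <- simulate_atlas(sim_atlas_config(n_genes = 40, seed = 21))
  r <- fit_sex_bias(sim$atlas, "midgut", prior_df = 0)
  v <- sim$atlas$values
  iF <- which(sim$atlas$samples$tissue == "midgut" &
                sim$atlas$samples$sex == "female")
  iM <- which(sim$atlas$samples$tissue == "midgut" &
                sim$atlas$samples$sex == "male")
  t_ref <- apply(v, 1, function(x)
    stats::t.test(x[iF], x[iM], var.equal = TRUE)$statistic)
  expect_equal(r$t, unname(t_ref), tolerance = 1e-10)
})

test_that("moderated fit agrees with limma on simulated data", {
  skip_if_not_installed("limma")
  sim <- simulate_atlas(sim_atlas_config(n_genes = 500, frac_narrow = 0,
                                         seed = 33))
  a <- sim$atlas
  idx <- which(a$samples$tissue == "midgut")
  v <- a$values[, idx]
  design <- cbind(1, as.integer(a$samples$sex[idx] == "female"))
  fit <- limma::eBayes(limma::lmFit(v, design))
  q_limma <- bh_fdr(fit$p.value[, 2])
  r <- fit_sex_bias(a, "midgut")
  expect_equal(r$m_value, unname(fit$coefficients[, 2]), tolerance = 1e-8)
  # same significance decisions at q < 0.05 with |m| >= 1 for > 95% of genes
  cls_limma <- q_limma < 0.05 & abs(fit$coefficients[, 2]) >= 1
  expect_gt(mean(cls_limma == (r$class != "unbiased")), 0.95)
})

test_that("gonad enrichment uses a strict M threshold", {
  set.seed(9)
  vals <- matrix(rnorm(40, 8, 0.3), 10, 4,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 c("carcass:female", "carcass:male",
                                   "gonad:female", "gonad:male")))
  vals["g01", "gonad:female"] <- vals["g01", "carcass:female"] + 2  # M = 2 exactly
  vals["g02", "gonad:female"] <- vals["g02", "carcass:female"] + 3
  a <- toy_atlas(vals, tissues = c("carcass", "gonad"))
  # make replicates vary so the test is defined
  a$values <- a$values + rnorm(length(a$values), 0, 0.05)
  r <- gonad_enrichment(a, "gonad", "carcass", "female")
  # enrichment requires M strictly above the threshold
  expect_true(all(r$m_value[r$enriched] > 2))
  expect_true(r$enriched[r$gene == "g02"])
  expect_false(r$enriched[r$gene == "g03"])
})

test_that("dimorphism summary counts, ratio and chi-squared are correct", {
  rec <- data.frame(
    gene = sprintf("g%03d", 1:120),
    tissue = "head",
    class = c(rep("female_biased", 60), rep("male_biased", 40),
              rep("unbiased", 20)))
  s <- dimorphism_summary(rec)
  expect_equal(s$per_tissue$ratio, 1.5)
  expect_equal(s$per_tissue$chi2, 4.0)
  expect_lt(s$per_tissue$p_value, 0.05)
  expect_equal(s$overall_fraction, 100 / 120)
  # a gene dimorphic in two tissues counts once overall
  rec2 <- rbind(rec, data.frame(gene = "g001", tissue = "gonad",
                                class = "female_biased"))
  expect_equal(dimorphism_summary(rec2)$overall_fraction, 100 / 120)
  # balanced counts give chi2 = 0
  rec$class <- rep(c("female_biased", "male_biased"), 60)
  expect_equal(dimorphism_summary(rec)$per_tissue$chi2, 0)
})
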