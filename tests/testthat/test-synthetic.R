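test_that("zero-noise atlas is deterministic and effects are exact", {
  cfg <- sim_atlas_config(n_genes = 60, noise_sd = 0, seed = 5)
  sim <- simulate_atlas(cfg)
  a <- sim$atlas; tr <- sim$truth
  # replicates identical within (tissue, sex)
  grp <- paste(a$samples$tissue, a$samples$sex)
  for (g in unique(grp)) {
    cols <- a$values[, grp == g, drop = FALSE]
    expect_equal(apply(cols, 1, stats::sd), rep(0, nrow(cols)),
                 ignore_attr = TRUE)
  }
  # planted sex effect equals the female-minus-male mean difference exactly
  dims <- tr[tr$class == "dimorphic", ]
  for (i in seq_len(nrow(dims))) {
    p <- paste0("p.", dims$gene[i])
    mf <- mean(a$values[p, grp == paste(dims$dim_tissue[i], "female")])
    mm <- mean(a$values[p, grp == paste(dims$dim_tissue[i], "male")])
    eff <- if (dims$dim_sex[i] == "female") mf - mm else mm - mf
    expect_equal(eff, dims$dim_effect[i])
  }
})

test_that("atlas generator is seed-reproducible and validates fractions", {
  s1 <- simulate_atlas(sim_atlas_config(n_genes = 30, seed = 9))
  s2 <- simulate_atlas(sim_atlas_config(n_genes = 30, seed = 9))
  expect_identical(s1$atlas$values, s2$atlas$values)
  expect_identical(s1$signal$pm, s2$signal$pm)
  expect_identical(s1$truth, s2$truth)
  expect_error(sim_atlas_config(frac_dimorphic = 0.6, frac_narrow = 0.3,
                                frac_housekeeping = 0.2), "exceed")
  expect_error(sim_atlas_config(n_replicates = 1), "n_replicates")
})

test_that("silent probe sets have near-zero median discrimination score", {
  sim <- simulate_atlas(sim_atlas_config(n_genes = 1000, frac_dimorphic = 0,
                                         frac_narrow = 1, frac_housekeeping = 0,
                                         seed = 31))
  pm <- sim$signal$pm; mm <- sim$signal$mm
  tr <- sim$truth
  # pick, per narrow gene, a sample where it is silent
  keys <- paste(sim$signal$samples$tissue, sim$signal$samples$sex)
  meds <- vapply(seq_len(nrow(tr)), function(i) {
    s <- which(keys != paste(tr$spec_tissue[i], tr$spec_sex[i]))[1]
    R <- (pm[i, , s] - mm[i, , s]) / (pm[i, , s] + mm[i, , s])
    median(R)
  }, numeric(1))
  expect_lt(abs(median(meds)), 0.05)
})

test_that("ortholog generator plants conserved clusters at the target correlation", {
  so <- simulate_orthologs(sim_ortholog_config(seed = 13))
  ra <- relative_abundance(so$mat_a)
  for (k in 1:3) {
    g <- so$truth$gene_a[which(so$truth$cluster_id == k)]
    R <- stats::cor(t(ra[g, ]))
    expect_gt(mean(R[upper.tri(R)]), 0.85)
    expect_lt(mean(R[upper.tri(R)]), 0.95)
  }
  expect_error(sim_ortholog_config(cluster_size = 1), "cluster size")
})

test_that("zero diverged fraction preserves the peak tissue in both species", {
  so <- simulate_orthologs(sim_ortholog_config(diverged_frac = 0, seed = 17))
  pk_a <- colnames(so$mat_a)[apply(so$mat_a, 1, which.max)]
  pk_b <- colnames(so$mat_b)[apply(so$mat_b, 1, which.max)]
  expect_identical(pk_a, pk_b)
  expect_identical(pk_a, so$truth$peak_tissue)
})

test_that("planted family memberships give the planted origin labels", {
  so <- simulate_orthologs(sim_ortholog_config(seed = 23))
  ft <- attr(so$truth, "family_truth")
  by_fam <- split(so$families$species, so$families$family_id)
  origins <- vapply(by_fam[ft$family_id], family_origin, character(1))
  expect_identical(unname(origins), ft$origin)
  copies <- vapply(by_fam[ft$family_id], classify_family_copies, character(1))
  expect_identical(unname(copies), ft$copies)
  # every family planted with a Ce member is labelled Metazoa
  has_ce <- vapply(by_fam[ft$family_id], function(s) "Ce" %in% s, logical(1))
  expect_true(all(ft$origin[has_ce] == "Metazoa"))
})

test_that("simulated CDS are valid coding sequences", {
  ss <- simulate_snps(sim_snp_config(n_genes_per_regime = 20,
                                     regimes = c(neutral = 1), seed = 2))
  expect_true(all(nchar(ss$cds) %% 3 == 0))
  for (cds in ss$cds[1:10]) {
    n <- nchar(cds)
    cods <- substring(cds, seq(1, n - 3, 3), seq(3, n - 3, 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
    expect_true(substring(cds, n - 2, n) %in% c("TAA", "TAG", "TGA"))
  }
  expect_error(sim_snp_config(mu_s = 0), "mu_s")
  # SNP truth classes match the classifier
  ann <- annotate_snps(ss$snps, ss$cds)
  expect_identical(ann$snp_class, ss$snps$snp_class_true)
})
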