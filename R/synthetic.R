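# Synthetic-data generators with planted ground truth: a tissue x sex x
# replicate expression atlas with PM/MM probe signals, two-species ortholog
# matrices with planted conserved co-expression clusters, and CDS + SNP sets
# with planted selection regimes. Identical seeds give identical output.

ARM_PROPS <- c(X = 0.10, "2R" = 0.25, "2L" = 0.22, "3R" = 0.23, "3L" = 0.20)

#' Configuration for the simulated expression atlas
#'
#' @param n_genes number of simulated genes.
#' @param tissues tissue panel (default [atlas_tissues()]); `gonad` is
#'   sex-resolved implicitly (ovary in females, testis in males).
#' @param n_replicates biological replicates per (tissue, sex) (default 4).
#' @param noise_sd log2-scale Gaussian noise SD (default 0.25).
#' @param probe_pairs PM/MM pairs per probe set (default 11).
#' @param probes_per_gene probes per gene (default 1).
#' @param frac_dimorphic,frac_narrow,frac_housekeeping planted class
#'   fractions; the remainder are broad genes with an intermediate tissue
#'   preference. Must sum to <= 1.
#' @param effect_size planted log2 sex-bias effect (default 2).
#' @param baseline_mean,baseline_sd per-gene lognormal baseline on the log2
#'   scale (defaults 6 and 1.5, truncated below at 2 so every expressed gene
#'   clears the detection floor).
#' @param silent_log2 log2 value of not-expressed cells (default 0, the
#'   detection floor, so single-tissue genes score tau = 1 at zero noise).
#' @param seed RNG seed.
#' @return validated list of class `sim_atlas_config`.
#' @export
sim_atlas_config <- function(n_genes = 500L, tissues = atlas_tissues(),
                             n_replicates = 4L, noise_sd = 0.25,
                             probe_pairs = 11L, probes_per_gene = 1L,
                             frac_dimorphic = 0.15, frac_narrow = 0.15,
                             frac_housekeeping = 0.2, effect_size = 2,
                             baseline_mean = 6, baseline_sd = 1.5,
                             silent_log2 = 0, seed = 1729L) {
  if (frac_dimorphic + frac_narrow + frac_housekeeping > 1)
    stop2("class fractions exceed 1")
  if (n_replicates < 2L) stop2("n_replicates must be >= 2")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (length(tissues) < 2L) stop2("need at least 2 tissues")
  structure(as.list(environment()), class = "sim_atlas_config")
}

#' Simulate a tissue/sex expression atlas with planted truth
#'
#' Log2 intensities are a per-gene baseline plus planted tissue/sex effects
#' plus Normal(0, noise_sd) noise. Per probe pair, PM = background +
#' linear-scale signal and MM = background, both with multiplicative
#' (log-normal) noise, so expressed cells have PM systematically above MM
#' and silent cells have PM ~ MM.
#'
#' Planted classes: `dimorphic` genes carry a +`effect_size` log2 effect for
#' one sex in one tissue; `narrow` genes are expressed in exactly one
#' (tissue, sex) cell; `housekeeping` genes are flat across all cells;
#' remaining `broad` genes get a +3 log2 preference in one tissue.
#'
#' @param cfg a [sim_atlas_config()].
#' @return list with `atlas` (an [expression_atlas()]), `signal` (a
#'   `probe_signal_set`: arrays `pm`, `mm` of dim probe x pair x sample plus
#'   `samples`), and `truth` (data.frame: gene, class, dim_tissue, dim_sex,
#'   dim_effect, spec_tissue, spec_sex, tau_class, arm).
#' @export
simulate_atlas <- function(cfg = sim_atlas_config()) {
  stopifnot(inherits(cfg, "sim_atlas_config"))
  with_seed(cfg$seed, {
    ng <- cfg$n_genes
    genes <- sprintf("AGAP%05d", seq_len(ng))
    arms <- sample(names(ARM_PROPS), ng, replace = TRUE, prob = ARM_PROPS)
    tiss <- cfg$tissues; sexes <- c("female", "male")

    n_dim <- round(cfg$frac_dimorphic * ng)
    n_nar <- round(cfg$frac_narrow * ng)
    n_hk <- round(cfg$frac_housekeeping * ng)
    cls <- rep("broad", ng)
    idx <- sample.int(ng)
    cls[idx[seq_len(n_dim)]] <- "dimorphic"
    cls[idx[n_dim + seq_len(n_nar)]] <- "narrow"
    cls[idx[n_dim + n_nar + seq_len(n_hk)]] <- "housekeeping"

    baseline <- pmax(stats::rnorm(ng, cfg$baseline_mean, cfg$baseline_sd), 2)
    truth <- data.frame(gene = genes, class = cls,
                        dim_tissue = NA_character_, dim_sex = NA_character_,
                        dim_effect = NA_real_, spec_tissue = NA_character_,
                        spec_sex = NA_character_, tau_class = NA_character_,
                        arm = arms, stringsAsFactors = FALSE)

    # mean log2 intensity and expression status per gene x tissue x sex
    mu <- array(rep(baseline, length(tiss) * 2L),
                dim = c(ng, length(tiss), 2L),
                dimnames = list(genes, tiss, sexes))
    expressed <- array(TRUE, dim = dim(mu), dimnames = dimnames(mu))

    for (i in which(cls == "dimorphic")) {
      tt <- sample(tiss, 1L); sx <- sample(sexes, 1L)
      mu[i, tt, sx] <- mu[i, tt, sx] + cfg$effect_size
      truth$dim_tissue[i] <- tt; truth$dim_sex[i] <- sx
      truth$dim_effect[i] <- cfg$effect_size
    }
    for (i in which(cls == "narrow")) {
      tt <- sample(tiss, 1L); sx <- sample(sexes, 1L)
      mu[i, , ] <- cfg$silent_log2
      expressed[i, , ] <- FALSE
      mu[i, tt, sx] <- baseline[i] + 3
      expressed[i, tt, sx] <- TRUE
      truth$spec_tissue[i] <- tt; truth$spec_sex[i] <- sx
      truth$tau_class[i] <- "narrow"
    }
    truth$tau_class[cls == "housekeeping"] <- "housekeeping"
    for (i in which(cls == "broad")) {
      tt <- sample(tiss, 1L)
      mu[i, tt, ] <- mu[i, tt, ] + 3
    }

    samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                           sex = sexes, tissue = tiss,
                           stringsAsFactors = FALSE)[, c("tissue", "sex",
                                                         "replicate")]
    samples$key <- with(samples, paste(tissue, sex, replicate, sep = ":"))

    ppg <- cfg$probes_per_gene
    probes <- if (ppg == 1L) paste0("p.", genes)
      else paste0("p.", rep(genes, each = ppg), ".", seq_len(ppg))
    probe_gene <- rep(genes, each = ppg)
    np <- length(probes); ns <- nrow(samples)

    cell_mu <- vapply(seq_len(ns), function(s)
      mu[probe_gene, samples$tissue[s], samples$sex[s]], numeric(np))
    cell_expr <- vapply(seq_len(ns), function(s)
      expressed[probe_gene, samples$tissue[s], samples$sex[s]], logical(np))
    values <- cell_mu + stats::rnorm(np * ns, 0, cfg$noise_sd)
    dimnames(values) <- list(probes, samples$key)

    bg <- 2^6
    npair <- cfg$probe_pairs
    signal_lin <- ifelse(cell_expr, 2^cell_mu, 0)
    pm <- array(rep(bg + signal_lin, each = npair) *
                  2^stats::rnorm(np * npair * ns, 0, cfg$noise_sd),
                dim = c(npair, np, ns))
    mm <- array(bg * 2^stats::rnorm(np * npair * ns, 0, cfg$noise_sd),
                dim = c(npair, np, ns))
    pm <- aperm(pm, c(2L, 1L, 3L)); mm <- aperm(mm, c(2L, 1L, 3L))
    dimnames(pm) <- dimnames(mm) <- list(probes, NULL, samples$key)

    atlas <- expression_atlas(
      values,
      data.frame(probe = probes, gene = probe_gene, stringsAsFactors = FALSE),
      data.frame(gene = genes, arm = arms, stringsAsFactors = FALSE))
    signal <- structure(list(pm = pm, mm = mm, samples = samples),
                        class = "probe_signal_set")
    list(atlas = atlas, signal = signal, truth = truth)
  })
}

#' Configuration for the two-species ortholog simulation
#'
#' @param n_clusters planted conserved co-expression clusters.
#' @param cluster_size genes per cluster (>= 2).
#' @param n_background one-to-one pairs outside any cluster.
#' @param tissues shared tissue panel (default: the atlas panel minus the
#'   accessory gland, which the comparison species lacks).
#' @param within_r target within-cluster Pearson correlation (default 0.9).
#' @param diverged_frac fraction of orthologue pairs whose two profiles are
#'   independent (default 0.1).
#' @param frac_expanded fraction of extra families planted with 2-4 Ag
#'   copies.
#' @param n_expanded_families extra (non one-to-one) families to plant.
#' @param origin_probs probabilities of the planted oldest ancestor, in the
#'   order Diptera, Coleoptera, Hymenoptera, Metazoa.
#' @param seed RNG seed.
#' @return validated list of class `sim_ortholog_config`.
#' @export
sim_ortholog_config <- function(n_clusters = 3L, cluster_size = 60L,
                                n_background = 200L,
                                tissues = setdiff(atlas_tissues(),
                                                  "accessory gland"),
                                within_r = 0.9, diverged_frac = 0.1,
                                frac_expanded = 0.15,
                                n_expanded_families = 50L,
                                origin_probs = c(0.30, 0.15, 0.15, 0.40),
                                seed = 1729L) {
  if (cluster_size < 2L) stop2("cluster size below 2")
  if (within_r <= 0 || within_r >= 1) stop2("within_r must be in (0, 1)")
  if (diverged_frac < 0 || diverged_frac > 1)
    stop2("diverged_frac must be in [0, 1]")
  stopifnot(length(origin_probs) == 4L, all(origin_probs >= 0))
  structure(as.list(environment()), class = "sim_ortholog_config")
}

# A tissue profile with a planted peak: base jitter plus a tall peak.
peak_profile <- function(tissues, peak) {
  x <- 1 + stats::runif(length(tissues), 0, 1)
  x[match(peak, tissues)] <- x[match(peak, tissues)] + 8
  names(x) <- tissues
  x
}

# Archetype + noise calibrated so E[cor(gene_i, gene_j)] ~ r; the planted
# peak tissue is enforced exactly by swapping if noise displaced it.
profile_from_archetype <- function(arch, r, peak) {
  sd_e <- stats::sd(arch) * sqrt(1 / r - 1)
  x <- pmax(arch + stats::rnorm(length(arch), 0, sd_e), 0.01)
  pk <- match(peak, names(arch))
  if (which.max(x) != pk) {
    j <- which.max(x)
    x[c(pk, j)] <- x[c(j, pk)]
  }
  x
}

#' Simulate two-species ortholog expression matrices with planted clusters
#'
#' Generates linear-scale gene x tissue matrices for two species (Ag, Dm)
#' over one-to-one orthologue pairs. Genes in a planted cluster share a
#' cluster archetype (same peak tissue in both species); a `diverged_frac`
#' fraction of pairs get independent profiles in the second species.
#' A family table adds planted outgroup memberships (origin labels) and
#' planted Ag expansions.
#'
#' @param cfg a [sim_ortholog_config()].
#' @return list with `mat_a`, `mat_b` (gene x tissue, linear scale),
#'   `pairs` (`gene_a`, `gene_b`), `families` (family_id, species, gene,
#'   relation), and `truth` (pair_id, gene_a, gene_b, cluster_id, diverged,
#'   peak_tissue, plus per-family `origin`/`copies` in attribute
#'   `family_truth`).
#' @export
simulate_orthologs <- function(cfg = sim_ortholog_config()) {
  stopifnot(inherits(cfg, "sim_ortholog_config"))
  with_seed(cfg$seed, {
    tiss <- cfg$tissues
    n_pairs <- cfg$n_clusters * cfg$cluster_size + cfg$n_background
    ga <- sprintf("AGAP%05d", seq_len(n_pairs))
    gb <- sprintf("FBgn%05d", seq_len(n_pairs))
    cluster_id <- rep(NA_integer_, n_pairs)
    if (cfg$n_clusters > 0L)
      cluster_id[seq_len(cfg$n_clusters * cfg$cluster_size)] <-
        rep(seq_len(cfg$n_clusters), each = cfg$cluster_size)
    diverged <- stats::runif(n_pairs) < cfg$diverged_frac

    cl_peaks <- sample(tiss, cfg$n_clusters,
                       replace = cfg$n_clusters > length(tiss))
    archetypes <- lapply(cl_peaks, function(p) peak_profile(tiss, p))

    mat_a <- matrix(0, n_pairs, length(tiss), dimnames = list(ga, tiss))
    mat_b <- matrix(0, n_pairs, length(tiss), dimnames = list(gb, tiss))
    peak <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      if (!is.na(cluster_id[i])) {
        arch <- archetypes[[cluster_id[i]]]
        pk <- cl_peaks[cluster_id[i]]
      } else {
        # background pairs: near-flat per-pair archetype (broadly expressed
        # genes); no dominant tissue, so correlation with any peaked cluster
        # profile stays near zero
        arch <- stats::runif(length(tiss), 1.5, 2.5)
        names(arch) <- tiss
        pk <- tiss[which.max(arch)]
      }
      peak[i] <- pk
      mat_a[i, ] <- profile_from_archetype(arch, cfg$within_r, pk)
      if (diverged[i]) {
        pk_b <- sample(tiss, 1L)
        mat_b[i, ] <- profile_from_archetype(peak_profile(tiss, pk_b),
                                             cfg$within_r, pk_b)
      } else {
        mat_b[i, ] <- profile_from_archetype(arch, cfg$within_r, pk)
      }
    }

    origins <- c("Diptera", "Coleoptera", "Hymenoptera", "Metazoa")
    fam_rows <- list(); fam_truth <- list()
    add_family <- function(fid, ag_genes, dm_genes, relation, origin) {
      sp <- c(rep("Ag", length(ag_genes)), rep("Dm", length(dm_genes)))
      gn <- c(ag_genes, dm_genes)
      if (origin == "Metazoa") {
        sp <- c(sp, "Ce"); gn <- c(gn, paste0("Ce_", fid))
        if (stats::runif(1) < 0.7) { sp <- c(sp, "Am"); gn <- c(gn, paste0("Am_", fid)) }
        if (stats::runif(1) < 0.7) { sp <- c(sp, "Tc"); gn <- c(gn, paste0("Tc_", fid)) }
      } else if (origin == "Hymenoptera") {
        sp <- c(sp, "Am"); gn <- c(gn, paste0("Am_", fid))
        if (stats::runif(1) < 0.7) { sp <- c(sp, "Tc"); gn <- c(gn, paste0("Tc_", fid)) }
      } else if (origin == "Coleoptera") {
        sp <- c(sp, "Tc"); gn <- c(gn, paste0("Tc_", fid))
      }
      fam_rows[[length(fam_rows) + 1L]] <<-
        data.frame(family_id = fid, species = sp, gene = gn,
                   relation = relation, stringsAsFactors = FALSE)
      fam_truth[[length(fam_truth) + 1L]] <<-
        data.frame(family_id = fid, origin = origin,
                   copies = if (sum(sp == "Ag") == 1L) "single_copy"
                            else "expanded",
                   stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_pairs))
      add_family(sprintf("FAM%05d", i), ga[i], gb[i], "one-to-one",
                 sample(origins, 1L, prob = cfg$origin_probs))
    for (j in seq_len(cfg$n_expanded_families)) {
      fid <- sprintf("FAM%05d", n_pairs + j)
      k <- sample(2:4, 1L)
      add_family(fid, sprintf("AGAP9%04d.%d", j, seq_len(k)),
                 sprintf("FBgn9%04d", j), "one-to-many",
                 sample(origins, 1L, prob = cfg$origin_probs))
    }
    families <- do.call(rbind, fam_rows)

    truth <- data.frame(pair_id = seq_len(n_pairs), gene_a = ga, gene_b = gb,
                        cluster_id = cluster_id, diverged = diverged,
                        peak_tissue = peak, stringsAsFactors = FALSE)
    attr(truth, "family_truth") <- do.call(rbind, fam_truth)
    list(mat_a = mat_a, mat_b = mat_b,
         pairs = data.frame(gene_a = ga, gene_b = gb,
                            stringsAsFactors = FALSE),
         families = families, truth = truth)
  })
}

#' Configuration for the CDS + SNP simulation
#'
#' @param n_genes_per_regime genes per selection regime.
#' @param regimes named target A/S ratios (default neutral 1.0, purifying
#'   0.5, positive 2.0).
#' @param mu_s synonymous SNP rate per synonymous site (default 0.007).
#' @param codon_range CDS length range in codons (uniform; default 100-500,
#'   excluding the appended terminal stop).
#' @param seed RNG seed.
#' @return validated list of class `sim_snp_config`.
#' @export
sim_snp_config <- function(n_genes_per_regime = 500L,
                           regimes = c(neutral = 1.0, purifying = 0.5,
                                       positive = 2.0),
                           mu_s = 0.007, codon_range = c(100L, 500L),
                           seed = 1729L) {
  if (mu_s <= 0) stop2("mu_s must be positive")
  stopifnot(length(codon_range) == 2L, codon_range[1L] >= 2L,
            codon_range[1L] <= codon_range[2L], all(regimes > 0),
            !is.null(names(regimes)))
  structure(as.list(environment()), class = "sim_snp_config")
}

# Stacked 64 x 9 change tables indexed by codon code for fast per-gene
# sampling: row block (code-1)*9 + 1:9 lists the codon's nine mutants.
.change_stack <- local({
  ord <- order(match(CODON_CHANGES$codon, names(GENETIC_CODE_STD)))
  cc <- CODON_CHANGES[ord, ]
  list(codons = names(GENETIC_CODE_STD), syn = cc$synonymous,
       pos = cc$pos_in_codon, alt = cc$alt)
})

#' Simulate coding sequences and SNPs under planted selection regimes
#'
#' CDS are random sense codons (terminal stop appended, no internal stop).
#' Each possible single-base change carries mu_s/3 placement probability if
#' synonymous and (mu_s x target A/S)/3 if non-synonymous, so the expected
#' per-site rates are S = mu_s and A = mu_s x target, and the planted A/S
#' equals the regime target in expectation.
#'
#' @param cfg a [sim_snp_config()].
#' @return list with `cds` (named character vector, terminal stop included),
#'   `snps` (gene, pos, ref, alt, region, truth class `snp_class_true`),
#'   `truth` (gene, regime, target_as, arm).
#' @export
simulate_snps <- function(cfg = sim_snp_config()) {
  stopifnot(inherits(cfg, "sim_snp_config"))
  with_seed(cfg$seed, {
    st <- .change_stack
    regs <- cfg$regimes
    n_total <- length(regs) * cfg$n_genes_per_regime
    genes <- sprintf("AGAP%05d", seq_len(n_total))
    regime <- rep(names(regs), each = cfg$n_genes_per_regime)
    target <- regs[regime]
    arms <- sample(names(ARM_PROPS), n_total, replace = TRUE,
                   prob = ARM_PROPS)
    cds <- character(n_total)
    snp_list <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      ncod <- sample(cfg$codon_range[1L]:cfg$codon_range[2L], 1L)
      codes <- sample(match(SENSE_CODONS, st$codons), ncod, replace = TRUE)
      cods <- st$codons[codes]
      cds[i] <- paste0(paste(cods, collapse = ""),
                       sample(STOP_CODONS, 1L))
      rows <- rep((codes - 1L) * 9L, each = 9L) + seq_len(9L)
      p <- ifelse(st$syn[rows], cfg$mu_s / 3,
                  cfg$mu_s * target[i] / 3)
      hit <- which(stats::runif(length(rows)) < p)
      if (length(hit)) {
        codon_j <- (hit - 1L) %/% 9L + 1L
        pos <- 3L * (codon_j - 1L) + st$pos[rows[hit]]
        snp_list[[i]] <- data.frame(
          gene = genes[i], pos = pos,
          ref = substring(cds[i], pos, pos),
          alt = st$alt[rows[hit]], region = "coding",
          snp_class_true = ifelse(st$syn[rows[hit]], "synonymous",
                                  "nonsynonymous"),
          stringsAsFactors = FALSE)
      }
    }
    names(cds) <- genes
    snps <- do.call(rbind, snp_list[!vapply(snp_list, is.null, logical(1))])
    rownames(snps) <- NULL
    list(cds = cds, snps = snps,
         truth = data.frame(gene = genes, regime = regime,
                            target_as = unname(target), arm = arms,
                            stringsAsFactors = FALSE))
  })
}
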