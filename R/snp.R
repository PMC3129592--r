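# SNP-based selection estimation: Nei-Gojobori synonymous/non-synonymous
# site counting, SNP effect classification, pooled A/S estimates with gene
# bootstrap confidence intervals, SNP densities, and 2x2 A/S contrasts.
#
# A = non-synonymous SNPs per non-synonymous site, S = synonymous SNPs per
# synonymous site; A/S is the polymorphism analogue of dN/dS (< 1 purifying,
# > 1 positive selection).

BASES <- c("A", "C", "G", "T")

# Standard genetic code, codon -> amino acid ("*" = stop).
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]

# All nine single-base changes of every codon, with their synonymy under the
# unweighted Nei-Gojobori scheme (change to a stop codon = non-synonymous).
codon_change_table <- function() {
  rows <- lapply(names(GENETIC_CODE_STD), function(cod) {
    aa <- GENETIC_CODE_STD[[cod]]
    ch <- strsplit(cod, "")[[1L]]
    out <- vector("list", 9L)
    k <- 0L
    for (p in 1:3) for (b in setdiff(BASES, ch[p])) {
      mut <- ch; mut[p] <- b
      mcod <- paste(mut, collapse = "")
      maa <- GENETIC_CODE_STD[[mcod]]
      k <- k + 1L
      out[[k]] <- data.frame(codon = cod, pos_in_codon = p, alt = b,
                             alt_codon = mcod,
                             synonymous = (maa == aa && maa != "*"),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}
CODON_CHANGES <- codon_change_table()

# Synonymous sites per codon: each of the 3 positions contributes
# (synonymous changes at that position)/3 of a synonymous site, so every
# position contributes exactly one site in total.
CODON_SYN_SITES <- vapply(split(CODON_CHANGES$synonymous, CODON_CHANGES$codon),
                          function(s) sum(s) / 3, numeric(1))

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n < 6L || n %% 3L != 0L)
    stop2("CDS length must be a multiple of 3 and at least 6")
  if (grepl("[^ACGT]", cds))
    stop2("ambiguous or invalid base in CDS")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Count synonymous and non-synonymous sites in a coding sequence
#'
#' Unweighted Nei-Gojobori (1986) counting: for each codon position the
#' synonymous site fraction is the number of the three single-base changes
#' that preserve the amino acid, divided by three; changes creating a stop
#' codon count as non-synonymous. A terminal stop codon, if present, is
#' excluded from counting; an internal stop is an error. Each counted codon
#' contributes exactly 3 sites in total.
#'
#' @param cds DNA string (A/C/G/T), length a multiple of 3.
#' @return list with `syn_sites`, `nonsyn_sites`, `n_codons`.
#' @examples
#' count_sites("TTTATG")  # TTT: 1/3 syn; ATG: 0 syn
#' @export
count_sites <- function(cds) {
  cods <- split_codons(toupper(cds))
  n <- length(cods)
  if (cods[n] %in% STOP_CODONS) cods <- cods[-n]
  if (any(cods %in% STOP_CODONS))
    stop2("internal stop codon at codon ",
          which(cods %in% STOP_CODONS)[1L])
  syn <- sum(CODON_SYN_SITES[cods])
  list(syn_sites = syn, nonsyn_sites = 3 * length(cods) - syn,
       n_codons = length(cods))
}

#' Classify a coding SNP as synonymous or non-synonymous
#'
#' A SNP is synonymous iff the mutated codon translates to the same amino
#' acid; mutations creating a stop codon are non-synonymous.
#'
#' @param cds the gene's coding sequence.
#' @param pos 1-based position within the CDS.
#' @param ref reference base; must equal the CDS base at `pos`.
#' @param alt alternate base.
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_snp <- function(cds, pos, ref, alt) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (pos < 1L || pos > n) stop2("position ", pos, " outside [1, ", n, "]")
  if (substring(cds, pos, pos) != toupper(ref))
    stop2("REF mismatch at position ", pos)
  if (toupper(ref) == toupper(alt)) stop2("ref and alt are identical")
  ci <- (pos - 1L) %/% 3L
  cod <- substring(cds, 3L * ci + 1L, 3L * ci + 3L)
  aa <- GENETIC_CODE_STD[[cod]]
  if (is.null(aa)) stop2("invalid codon ", cod)
  if (aa == "*") stop2("SNP falls in a stop codon")
  p <- pos - 3L * ci
  mut <- strsplit(cod, "")[[1L]]
  mut[p] <- toupper(alt)
  maa <- GENETIC_CODE_STD[[paste(mut, collapse = "")]]
  if (maa == aa) "synonymous" else "nonsynonymous"
}

#' Annotate a SNP table with synonymous/non-synonymous classes
#'
#' @param snps data.frame with columns `gene`, `pos`, `ref`, `alt`.
#' @param cds named character vector of coding sequences.
#' @return `snps` with an added `snp_class` column.
#' @export
annotate_snps <- function(snps, cds) {
  stopifnot(all(snps$gene %in% names(cds)))
  snps$snp_class <- vapply(seq_len(nrow(snps)), function(i)
    classify_snp(cds[[snps$gene[i]]], snps$pos[i], snps$ref[i], snps$alt[i]),
    character(1))
  snps
}

# Per-gene syn/nonsyn SNP and site counts; the unit table the estimators
# and the gene bootstrap share.
per_gene_counts <- function(cds, snps) {
  if (!all(snps$gene %in% names(cds)))
    stop2("SNP gene(s) not in the gene set")
  if (is.null(snps$snp_class)) snps <- annotate_snps(snps, cds)
  sites <- lapply(cds, count_sites)
  data.frame(
    gene = names(cds),
    syn_sites = vapply(sites, `[[`, numeric(1), "syn_sites"),
    nonsyn_sites = vapply(sites, `[[`, numeric(1), "nonsyn_sites"),
    syn_snps = as.numeric(table(factor(snps$gene[snps$snp_class == "synonymous"],
                                       levels = names(cds)))),
    nonsyn_snps = as.numeric(table(factor(snps$gene[snps$snp_class == "nonsynonymous"],
                                          levels = names(cds)))),
    row.names = NULL, stringsAsFactors = FALSE)
}

as_from_counts <- function(n_nonsyn, nonsyn_sites, n_syn, syn_sites) {
  A <- n_nonsyn / nonsyn_sites
  S <- if (syn_sites > 0) n_syn / syn_sites else NA_real_
  structure(
    list(A = A, S = S,
         ratio = if (!is.na(S) && S > 0) A / S else NA_real_,
         undefined = is.na(S) || S == 0,
         n_syn_snps = n_syn, n_nonsyn_snps = n_nonsyn,
         syn_sites = syn_sites, nonsyn_sites = nonsyn_sites),
    class = "as_estimate")
}

#' Pooled A/S point estimate for a gene set
#'
#' A = total non-synonymous SNPs / total non-synonymous sites; S likewise for
#' synonymous; ratio = A/S. Counts are pooled over genes (not averaged over
#' per-gene ratios), and sites are counted over all genes in the set, not
#' only SNP-bearing codons. With zero synonymous SNPs or sites the ratio is
#' flagged undefined.
#'
#' @param cds named character vector of coding sequences (the gene set).
#' @param snps data.frame of coding SNPs (`gene`, `pos`, `ref`, `alt`,
#'   optionally pre-annotated `snp_class`).
#' @return an `as_estimate` object with `A`, `S`, `ratio` and the counts.
#' @seealso [as_ratio_from_rates()] for the pure arithmetic on per-site rates.
#' @export
as_ratio <- function(cds, snps) {
  g <- per_gene_counts(cds, snps)
  est <- as_from_counts(sum(g$nonsyn_snps), sum(g$nonsyn_sites),
                        sum(g$syn_snps), sum(g$syn_sites))
  est$n_genes <- nrow(g)
  est
}

#' A/S ratio from per-site rates
#'
#' The arithmetic core: given the per-site non-synonymous rate A and
#' synonymous rate S, returns A/S.
#'
#' @param A non-synonymous SNPs per non-synonymous site.
#' @param S synonymous SNPs per synonymous site.
#' @return A/S, or `NA` if `S` is zero.
#' @examples
#' as_ratio_from_rates(0.0033, 0.0068)  # ~0.49
#' @export
as_ratio_from_rates <- function(A, S) {
  stopifnot(A >= 0, S >= 0)
  if (S == 0) return(NA_real_)
  A / S
}

#' @export
print.as_estimate <- function(x, ...) {
  cat(sprintf("A = %.4g (%d SNPs / %.1f sites), S = %.4g (%d SNPs / %.1f sites)\n",
              x$A, x$n_nonsyn_snps, x$nonsyn_sites,
              x$S, x$n_syn_snps, x$syn_sites))
  if (isTRUE(x$undefined)) cat("A/S ratio undefined (no synonymous signal)\n")
  else cat(sprintf("A/S = %.3f", x$ratio),
           if (!is.null(x$ci_low))
             sprintf(" [95%% CI %.3f, %.3f; B = %d]", x$ci_low, x$ci_high, x$B)
           else "", "\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence interval for the pooled A/S ratio
#'
#' Genes are resampled with replacement `B` times; each resample carries its
#' SNPs and its sites, and the pooled ratio is recomputed. The 95% CI is the
#' 2.5/97.5 percentile over replicates where the ratio is defined; the
#' fraction of undefined replicates is reported.
#'
#' @param cds named character vector of coding sequences.
#' @param snps coding SNP data.frame as for [as_ratio()].
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed; fixed seeds give identical CIs.
#' @param conf confidence level (default 0.95).
#' @return an `as_estimate` with `ci_low`, `ci_high`, `B`, `seed`,
#'   `frac_undefined`.
#' @export
bootstrap_as <- function(cds, snps, B = 10000L, seed = 1729L, conf = 0.95) {
  if (B < 100L) stop2("B must be at least 100")
  if (length(cds) < 2L) stop2("need at least 2 genes to bootstrap")
  g <- per_gene_counts(cds, snps)
  est <- as_from_counts(sum(g$nonsyn_snps), sum(g$nonsyn_sites),
                        sum(g$syn_snps), sum(g$syn_sites))
  est$n_genes <- nrow(g)
  n <- nrow(g)
  ratios <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ss <- sum(g$syn_snps[idx]); sst <- sum(g$syn_sites[idx])
      if (ss == 0 || sst == 0) return(NA_real_)
      (sum(g$nonsyn_snps[idx]) / sum(g$nonsyn_sites[idx])) / (ss / sst)
    }, numeric(1))
  })
  ok <- !is.na(ratios)
  if (!any(ok)) stop2("A/S undefined in every bootstrap replicate")
  a <- (1 - conf) / 2
  ci <- stats::quantile(ratios[ok], c(a, 1 - a), names = FALSE)
  est$ci_low <- ci[1L]; est$ci_high <- ci[2L]
  est$B <- as.integer(B); est$seed <- seed
  est$frac_undefined <- mean(!ok)
  est
}

#' SNP density per 1,000 nucleotides
#'
#' @param n_snps SNP count.
#' @param n_nucleotides surveyed sequence length in nucleotides (> 0).
#' @return SNPs per 1,000 nt.
#' @export
snp_density <- function(n_snps, n_nucleotides) {
  stopifnot(n_snps >= 0)
  if (n_nucleotides <= 0) stop2("n_nucleotides must be positive")
  1000 * n_snps / n_nucleotides
}

# syn/nonsyn counts from either an annotated SNP data.frame or a
# length-2 numeric c(syn, nonsyn).
syn_nonsyn_counts <- function(x) {
  if (is.data.frame(x)) {
    if (is.null(x$snp_class)) stop2("SNP table must carry snp_class")
    c(syn = sum(x$snp_class == "synonymous"),
      nonsyn = sum(x$snp_class == "nonsynonymous"))
  } else {
    stopifnot(is.numeric(x), length(x) == 2L)
    c(syn = x[[1L]], nonsyn = x[[2L]])
  }
}

#' Chi-squared contrast of A/S composition between two SNP sets
#'
#' 2x2 chi-squared test (no continuity correction) on the counts
#' {synonymous, non-synonymous} x {set1, set2}; used e.g. to contrast
#' X-linked against autosomal genes.
#'
#' @param set1,set2 annotated SNP data.frames (with `snp_class`), or numeric
#'   length-2 vectors `c(syn, nonsyn)`.
#' @return a [chi_square_result()].
#' @export
as_contrast <- function(set1, set2) {
  c1 <- syn_nonsyn_counts(set1); c2 <- syn_nonsyn_counts(set2)
  if (sum(c1) == 0 || sum(c2) == 0) stop2("each set needs at least 1 SNP")
  m <- rbind(set1 = c1, set2 = c2)
  if (any(colSums(m) == 0)) stop2("a syn/nonsyn margin is zero")
  ct <- stats::chisq.test(m, correct = FALSE)
  chi_square_result(ct$statistic, ct$parameter, ct$p.value,
                    observed = c(m), expected = c(ct$expected),
                    method = "2x2 chi-squared contrast of syn/nonsyn SNP counts")
}
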