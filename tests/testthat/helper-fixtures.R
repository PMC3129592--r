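# Shared fixtures built in code.

# A tiny atlas: `n` genes, one probe each, two tissues, 4 replicates per sex.
toy_atlas <- function(values_by_group, tissues = c("head", "gonad"),
                      n_rep = 4L) {
  genes <- rownames(values_by_group)
  keys <- as.vector(outer(
    paste(rep(tissues, each = 2L), c("female", "male"), sep = ":"),
    seq_len(n_rep), paste, sep = ":"))
  m <- matrix(0, nrow(values_by_group), length(keys),
              dimnames = list(paste0("p.", genes), keys))
  for (k in keys) {
    grp <- sub(":[0-9]+$", "", k)
    m[, k] <- values_by_group[, grp]
  }
  expression_atlas(m, data.frame(probe = paste0("p.", genes), gene = genes))
}

# Independent translation oracle built on Biostrings' genetic code.
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Brute-force site counts for one codon: enumerate all 9 single-base
# mutants and classify each by translation.
oracle_codon_sites <- function(codon) {
  aa <- oracle_translate(codon)
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
    mut <- ch; mut[p] <- b
    maa <- oracle_translate(paste(mut, collapse = ""))
    if (maa == aa && maa != "*") syn <- syn + 1 / 3
  }
  c(syn = syn, nonsyn = 3 - syn)
}
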