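# Readers and writers for the external formats the pipeline touches:
# expression/annotation TSV, CDS FASTA, CDS-space VCF, ortholog map TSV,
# Newick dendrograms, and the YAML run configuration.

#' Read a probe-by-sample expression TSV plus annotation
#'
#' The expression file has a `probe` column followed by one column per sample,
#' headers encoded `"tissue:sex:replicate"`. The annotation file has columns
#' `probe`, `gene` and optionally `arm`. Probes mapped to more than one gene
#' are rejected; probes absent from the annotation are reported with their
#' line numbers.
#'
#' @param path expression TSV path.
#' @param annotation_path annotation TSV path.
#' @return an [expression_atlas()].
#' @export
read_expression_tsv <- function(path, annotation_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1L] != "probe") stop2("first column must be 'probe'")
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) || anyNA(vals[[j]]))
      stop2("non-numeric or missing cell in column '", names(vals)[j],
            "', data row(s) ",
            paste(utils::head(union(bad, which(is.na(vals[[j]]))), 5L),
                  collapse = ", "))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- raw$probe
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(ann)))
    stop2("annotation must have columns 'probe' and 'gene'")
  missing <- which(!rownames(m) %in% ann$probe)
  if (length(missing))
    stop2("probe(s) absent from annotation at data line(s) ",
          paste(utils::head(missing, 10L), collapse = ", "), ": ",
          paste(utils::head(rownames(m)[missing], 10L), collapse = ", "))
  genes <- NULL
  if ("arm" %in% names(ann))
    genes <- unique(ann[, c("gene", "arm")])
  expression_atlas(m, ann[, c("probe", "gene")], genes)
}

#' Write an expression atlas (and its annotation) to TSV
#'
#' Values are written at full double precision so that a write/read round
#' trip reproduces the matrix exactly.
#'
#' @param atlas an `expression_atlas`.
#' @param path expression TSV destination.
#' @param annotation_path annotation TSV destination (probe, gene, arm).
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(atlas, path, annotation_path = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  m <- atlas$values
  txt <- apply(m, 2L, function(col) formatC(col, digits = 17, format = "g"))
  df <- data.frame(probe = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("probe", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- atlas$probes
    if (!is.null(atlas$genes))
      ann <- merge(ann, atlas$genes, by = "gene", all.x = TRUE,
                   sort = FALSE)[, c("probe", "gene", "arm")]
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file of CDS, one record per gene.
#' @return named character vector of upper-case DNA strings.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write coding sequences to FASTA
#' @param cds named character vector of DNA strings.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_cds_fasta <- function(cds, path) {
  stopifnot(!is.null(names(cds)), all(nzchar(names(cds))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' Read SNPs from a CDS-space VCF
#'
#' The VCF's CHROM column holds gene identifiers and POS is the 1-based
#' position within that gene's coding sequence (forward strand). Only
#' single-nucleotide REF/ALT records are kept; indels are skipped with a
#' warning tally. Multi-allelic rows are split into one record per ALT.
#'
#' @param path VCF path.
#' @param cds named character vector of coding sequences (gene -> CDS), used
#'   to validate positions and reference bases.
#' @return data.frame with columns `gene`, `pos`, `ref`, `alt`, `region`,
#'   with attribute `n_indels_skipped`.
#' @export
read_snps_vcf <- function(path, cds) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  gene <- fx[, "CHROM"]
  pos <- as.integer(fx[, "POS"])
  ref <- toupper(fx[, "REF"])
  alt_field <- toupper(fx[, "ALT"])
  alts <- strsplit(alt_field, ",", fixed = TRUE)
  n <- lengths(alts)
  gene <- rep(gene, n); pos <- rep(pos, n); ref <- rep(ref, n)
  alt <- unlist(alts, use.names = FALSE)
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  n_indel <- sum(!is_snv)
  if (n_indel)
    warning(n_indel, " indel record(s) skipped", call. = FALSE)
  gene <- gene[is_snv]; pos <- pos[is_snv]; ref <- ref[is_snv]; alt <- alt[is_snv]
  unknown <- setdiff(unique(gene), names(cds))
  if (length(unknown))
    stop2("SNP gene(s) absent from CDS set: ",
          paste(utils::head(unknown, 10L), collapse = ", "))
  len <- nchar(cds)[gene]
  bad <- which(pos < 1L | pos > len)
  if (length(bad))
    stop2("POS outside [1, CDS length] for record(s): ",
          paste(utils::head(paste0(gene[bad], ":", pos[bad]), 10L),
                collapse = ", "))
  cds_base <- substring(cds[gene], pos, pos)
  bad <- which(cds_base != ref)
  if (length(bad))
    stop2("REF mismatch with CDS for record(s): ",
          paste(utils::head(paste0(gene[bad], ":", pos[bad], " ", ref[bad],
                                   "!=", cds_base[bad]), 10L), collapse = ", "))
  out <- data.frame(gene = gene, pos = pos, ref = ref, alt = alt,
                    region = "coding", stringsAsFactors = FALSE)
  attr(out, "n_indels_skipped") <- n_indel
  out
}

#' Write SNPs to a CDS-space VCF
#'
#' Records sharing (gene, pos, ref) are merged into one multi-allelic row.
#'
#' @param snps data.frame with columns `gene`, `pos`, `ref`, `alt`.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_snps_vcf <- function(snps, path) {
  stopifnot(all(c("gene", "pos", "ref", "alt") %in% names(snps)))
  key <- paste(snps$gene, snps$pos, snps$ref, sep = "\r")
  alt <- vapply(split(snps$alt, key), paste, "", collapse = ",")
  first <- !duplicated(key)
  df <- snps[first, c("gene", "pos", "ref")]
  df$alt <- alt[key[first]]
  df <- df[order(df$gene, df$pos), ]
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=CS,Number=0,Type=Flag,Description=\"CDS-space SNP\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                     df$gene, df$pos, df$ref, df$alt))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog/family map TSV
#'
#' Columns: `family_id`, `species` (Ag, Dm, Tc, Am, Ce), `gene`, `relation`
#' (one-to-one, one-to-many, many-to-many).
#'
#' @param path TSV path.
#' @return data.frame of family memberships.
#' @export
read_ortholog_map_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "species", "gene", "relation")
  if (!all(need %in% names(x)))
    stop2("ortholog map must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(x$species), c("Ag", "Dm", "Tc", "Am", "Ce"))
  if (length(bad))
    stop2("unknown species code(s): ", paste(bad, collapse = ", "))
  x
}

#' Write a tree to Newick
#'
#' Accepts an `hclust` object, an ape `phylo`, or the result of
#' [bootstrap_support()]. Bootstrap supports, when present, are rendered as
#' internal-node labels scaled to percent.
#'
#' @param tree tree object; all leaves must be labelled.
#' @param path destination file.
#' @return invisibly, the Newick string written.
#' @export
write_newick <- function(tree, path) {
  support <- NULL
  if (inherits(tree, "supported_tree")) {
    support <- tree$support
    tree <- tree$tree
  }
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) stop2("tree must be hclust, phylo or supported_tree")
  if (length(tree$tip.label) == 0L) stop2("empty tree")
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop2("unlabelled leaf")
  if (!is.null(support)) {
    lab <- as.character(round(100 * support))
    lab[is.na(support)] <- ""
    tree$node.label <- lab
  }
  s <- ape::write.tree(tree)
  writeLines(s, path)
  invisible(s)
}

#' Read a run configuration file
#'
#' A single YAML key-value file holding thresholds, the tissue list, seeds
#' and bootstrap sizes. Values given in `overrides` replace file values.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list of values taking precedence over the file.
#' @return named list of configuration values.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    tissues = atlas_tissues(),
    alpha1 = 0.04, alpha2 = 0.06, tau_det = 0.015, min_present = 3L,
    fold_threshold_log2 = 1, q_threshold = 0.05, m_threshold = 2,
    tau_low = 0.15, tau_high = 0.85, tau_detection_filter = FALSE,
    min_similarity = 0.8, min_size = 50L,
    bootstrap_B = 10000L, seed = 1729L)
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  cfg
}
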