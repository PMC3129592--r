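# Cross-species expression conservation: relative-abundance (RA) profiles,
# co-expression cluster extraction, hypergeometric cluster overlap between
# species, bootstrap-supported tissue dendrograms, and gene-family origin /
# copy-number classification.

#' Collapse probe-level rows to gene level by the per-column maximum
#'
#' Where a gene is represented by multiple probes, the maximum intensity
#' recorded in each tissue (column) is used for subsequent analysis.
#'
#' @param mat probe x column numeric matrix (e.g. per-tissue means).
#' @param probe_annotation data.frame mapping `probe` to `gene`.
#' @return gene x column matrix; attribute `n_unannotated` tallies dropped
#'   probes.
#' @export
collapse_probes <- function(mat, probe_annotation) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  gene <- probe_annotation$gene[match(rownames(mat), probe_annotation$probe)]
  drop <- is.na(gene)
  m <- mat[!drop, , drop = FALSE]
  gene <- gene[!drop]
  ug <- unique(gene)
  out <- do.call(rbind, lapply(split(seq_along(gene), gene)[ug], function(i)
    apply(m[i, , drop = FALSE], 2L, max)))
  rownames(out) <- ug
  attr(out, "n_unannotated") <- sum(drop)
  out
}

#' Combine male and female sample means per tissue
#'
#' Per tissue, the mean of the male mean and the female mean, with equal
#' weight regardless of replicate counts; tissues measured in a single sex
#' keep that sex's mean.
#'
#' @param mat matrix whose columns are named `"tissue:sex"` (e.g. from
#'   [tissue_sex_means()]).
#' @return matrix with one column per tissue.
#' @export
combine_sexes <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  parts <- strsplit(colnames(mat), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop2("column names must be 'tissue:sex'")
  tissue <- vapply(parts, `[[`, "", 1L)
  ut <- unique(tissue)
  out <- vapply(ut, function(tt) {
    cols <- which(tissue == tt)
    if (length(cols) == 0L) stop2("tissue without any sex: ", tt)
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat),
                                       dimnames = list(rownames(mat), ut))
  colnames(out) <- ut
  out
}

#' Relative-abundance (RA) profiles
#'
#' Represents each gene as a vector of relative expression abundance across
#' tissues (row proportions on the linear scale), removing absolute-intensity
#' scale so cross-platform comparisons do not over-estimate divergence.
#'
#' @param mat gene x tissue matrix.
#' @param scale `"linear"` (values must be >= 0) or `"log2"` (values are
#'   unlogged first).
#' @param normalization `"total"` (rows sum to 1, the default definition)
#'   or `"max"` (rows divided by their maximum; sensitivity alternative).
#' @return gene x tissue matrix; with `"total"` rows sum to 1. All-zero
#'   rows are excluded and listed in attribute `dropped`.
#' @export
relative_abundance <- function(mat, scale = c("linear", "log2"),
                               normalization = c("total", "max")) {
  scale <- match.arg(scale)
  normalization <- match.arg(normalization)
  stopifnot(is.matrix(mat))
  x <- if (scale == "log2") 2^mat else mat
  if (scale == "linear" && any(x < 0)) stop2("negative linear value")
  rs <- rowSums(x)
  dropped <- rownames(x)[rs == 0]
  x <- x[rs > 0, , drop = FALSE]
  out <- if (normalization == "total") x / rowSums(x)
         else x / apply(x, 1L, max)
  attr(out, "dropped") <- dropped
  out
}

# Mean pairwise correlation inside each merge node of an average-linkage
# tree, computed incrementally from the correlation matrix.
node_mean_cor <- function(hc, R) {
  n <- nrow(R)
  n_nodes <- nrow(hc$merge)
  members <- vector("list", n_nodes)
  sum_off <- numeric(n_nodes)   # sum of off-diagonal correlations (ordered pairs)
  size <- integer(n_nodes)
  meanc <- numeric(n_nodes)
  for (k in seq_len(n_nodes)) {
    a <- hc$merge[k, 1L]; b <- hc$merge[k, 2L]
    ma <- if (a < 0) -a else members[[a]]
    mb <- if (b < 0) -b else members[[b]]
    sa <- if (a < 0) 0 else sum_off[a]
    sb <- if (b < 0) 0 else sum_off[b]
    cross <- sum(R[ma, mb])
    members[[k]] <- c(ma, mb)
    size[k] <- length(members[[k]])
    sum_off[k] <- sa + sb + 2 * cross
    meanc[k] <- sum_off[k] / (size[k] * (size[k] - 1L))
  }
  list(members = members, size = size, mean_cor = meanc)
}

#' Extract co-expression clusters from RA profiles
#'
#' Agglomerative average-linkage clustering on the Pearson-correlation
#' distance d = 1 - r; the tree is cut by emitting the maximal subtrees
#' whose mean pairwise correlation exceeds `min_similarity`, and of those,
#' clusters with strictly more than `min_size` genes are reported.
#' Constant-profile genes (Pearson undefined) are excluded with a tally.
#'
#' @param ra gene x tissue RA matrix (>= 3 tissues).
#' @param min_similarity mean pairwise correlation threshold (default 0.8,
#'   strict).
#' @param min_size minimum cluster size (default 50, strict).
#' @return list of class `gene_cluster_set`: `clusters` (list of gene-id
#'   vectors), `similarity`, `profiles` (mean RA per cluster),
#'   `unclustered`, `n_constant_dropped`.
#' @export
gene_coexpression_clusters <- function(ra, min_similarity = 0.8,
                                       min_size = 50L) {
  stopifnot(is.matrix(ra), !is.null(rownames(ra)))
  if (ncol(ra) < 3L) stop2("need >= 3 tissues for Pearson profiles")
  sds <- apply(ra, 1L, stats::sd)
  n_const <- sum(sds == 0)
  x <- ra[sds > 0, , drop = FALSE]
  if (nrow(x) < 2L) stop2("all gene profiles are constant")
  R <- stats::cor(t(x))
  hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
  nm <- node_mean_cor(hc, R)
  qualifies <- nm$mean_cor > min_similarity
  # parent of each internal node
  parent <- rep(NA_integer_, nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) for (ab in hc$merge[k, ])
    if (ab > 0) parent[ab] <- k
  maximal <- which(qualifies &
                     (is.na(parent) | !qualifies[ifelse(is.na(parent), 1L, parent)]))
  keep <- maximal[nm$size[maximal] > min_size]
  clusters <- lapply(keep, function(k) rownames(x)[nm$members[[k]]])
  ord <- order(vapply(clusters, length, integer(1)), decreasing = TRUE)
  clusters <- clusters[ord]
  similarity <- nm$mean_cor[keep][ord]
  profiles <- do.call(rbind, lapply(clusters, function(g)
    colMeans(x[g, , drop = FALSE])))
  assigned <- unlist(clusters, use.names = FALSE)
  structure(list(clusters = clusters, similarity = similarity,
                 profiles = profiles,
                 unclustered = setdiff(rownames(ra), assigned),
                 n_constant_dropped = n_const,
                 universe = rownames(x)),
            class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("gene_cluster_set: %d cluster(s), %d unclustered gene(s)\n",
              length(x$clusters), length(x$unclustered)))
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d genes, mean pairwise r = %.3f\n",
                i, length(x$clusters[[i]]), x$similarity[i]))
  invisible(x)
}

#' Hypergeometric overlap of cluster sets across species
#'
#' Maps both species' clusters through one-to-one orthologue pairs and tests
#' every cluster pair for orthologue overlap with the hypergeometric
#' upper-tail probability, BH-corrected over all pairs; bands at q < 0.05
#' (`"p<0.05"`) and q < 0.01 (`"p<0.01"`), else `"ns"`.
#'
#' @param setA,setB `gene_cluster_set`s for the two species.
#' @param pairs data.frame of one-to-one pairs with columns `gene_a`,
#'   `gene_b`.
#' @param universe_a,universe_b gene universes in each species defining which
#'   pairs enter the test (default: the genes used in each clustering).
#' @return data.frame of class `overlap_result`: `cluster_a`, `cluster_b`,
#'   `size_a`, `size_b`, `overlap`, `universe`, `p_value`, `q_value`, `band`.
#' @export
cluster_overlap <- function(setA, setB, pairs,
                            universe_a = NULL, universe_b = NULL) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  if (is.null(universe_a)) universe_a <- setA$universe
  if (is.null(universe_b)) universe_b <- setB$universe
  keep <- pairs$gene_a %in% universe_a & pairs$gene_b %in% universe_b
  pairs <- pairs[keep, ]
  N <- nrow(pairs)
  if (N == 0L) stop2("empty orthologue universe")
  grid <- expand.grid(a = seq_along(setA$clusters),
                      b = seq_along(setB$clusters))
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ca <- setA$clusters[[grid$a[i]]]
    cb <- setB$clusters[[grid$b[i]]]
    in_a <- pairs$gene_a %in% ca
    in_b <- pairs$gene_b %in% cb
    m <- sum(in_a); n <- sum(in_b); k <- sum(in_a & in_b)
    p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    data.frame(cluster_a = grid$a[i], cluster_b = grid$b[i],
               size_a = m, size_b = n, overlap = k, universe = N,
               p_value = p)
  }))
  res$q_value <- bh_fdr(res$p_value)
  res$band <- ifelse(res$q_value < 0.01, "p<0.01",
                     ifelse(res$q_value < 0.05, "p<0.05", "ns"))
  class(res) <- c("overlap_result", "data.frame")
  res
}

#' Hierarchical dendrogram of tissues (or samples)
#'
#' Agglomerative clustering of the item rows with Euclidean distance and
#' average linkage; rows are pre-sorted by label so ties break
#' deterministically.
#'
#' @param mat items x features numeric matrix with unique row labels.
#' @param distance `"euclidean"` (passed to [stats::dist()]).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return an `hclust` object.
#' @export
tissue_dendrogram <- function(mat, distance = "euclidean",
                              linkage = "average") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (nrow(mat) < 2L) stop2("need at least 2 items")
  if (anyDuplicated(rownames(mat))) stop2("duplicate item labels")
  if (anyNA(mat)) stop2("missing features")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  stats::hclust(stats::dist(mat, method = distance), method = linkage)
}

#' Bootstrap branch support for a tissue dendrogram
#'
#' Feature columns (genes) are resampled with replacement `B` times and the
#' tree rebuilt; the support of each internal branch is the fraction of
#' replicate trees containing the same leaf bipartition (topology only).
#'
#' @param mat items x features matrix (>= 3 items, >= 2 features).
#' @param B bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param distance,linkage as in [tissue_dendrogram()].
#' @return object of class `supported_tree`: list with `tree` (ape `phylo`),
#'   `support` (per internal node, in \[0, 1\], root `NA`), `B`, `seed`.
#' @export
bootstrap_support <- function(mat, B = 10000L, seed = 1729L,
                              distance = "euclidean", linkage = "average") {
  if (B < 100L) stop2("B must be at least 100")
  if (nrow(mat) < 3L) stop2("need at least 3 items")
  if (ncol(mat) < 2L) stop2("need at least 2 features")
  base <- ape::as.phylo(tissue_dendrogram(mat, distance, linkage))
  counts <- with_seed(seed, {
    trees <- lapply(seq_len(B), function(b) {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      ape::as.phylo(tissue_dendrogram(mat[, idx, drop = FALSE],
                                      distance, linkage))
    })
    ape::prop.clades(base, trees, rooted = TRUE)
  })
  support <- counts / B
  support[1L] <- NA_real_  # root: trivially present in every replicate
  structure(list(tree = base, support = support, B = as.integer(B),
                 seed = seed),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("dendrogram over %d items; %d internal branches, B = %d\n",
              length(x$tree$tip.label), length(x$support), x$B))
  cat("supports:", paste(ifelse(is.na(x$support), "NA",
                                sprintf("%.2f", x$support)),
                         collapse = " "), "\n")
  invisible(x)
}

SPECIES_CODES <- c("Ag", "Dm", "Tc", "Am", "Ce")

#' Phylogenetic origin of a gene family
#'
#' The oldest common ancestor implied by the family's species memberships:
#' Metazoa if a C. elegans (Ce) member is present; else Hymenoptera if a
#' honeybee (Am) member; else Coleoptera if a beetle (Tc) member; else
#' Diptera.
#'
#' @param species character vector of species codes present in the family
#'   (`Ag`, `Dm`, `Tc`, `Am`, `Ce`).
#' @return one of `"Diptera"`, `"Coleoptera"`, `"Hymenoptera"`, `"Metazoa"`.
#' @export
family_origin <- function(species) {
  bad <- setdiff(species, SPECIES_CODES)
  if (length(bad)) stop2("unknown species code(s): ", paste(bad, collapse = ", "))
  if (!any(species %in% c("Ag", "Dm")))
    stop2("family has neither an Ag nor a Dm member")
  if ("Ce" %in% species) "Metazoa"
  else if ("Am" %in% species) "Hymenoptera"
  else if ("Tc" %in% species) "Coleoptera"
  else "Diptera"
}

#' Single-copy vs expanded classification of a family
#'
#' @param species species code per family member.
#' @return `"single_copy"` iff exactly one Ag member, else `"expanded"`.
#' @export
classify_family_copies <- function(species) {
  n_ag <- sum(species == "Ag")
  if (n_ag == 0L) stop2("family has no Ag member")
  if (n_ag == 1L) "single_copy" else "expanded"
}

#' Narrow-expression family report
#'
#' Two tables over a family map: (A) expanded families whose Ag members have
#' tau = 1, counted by the member's peak tissue; (B) single-copy one-to-one
#' families where both orthologues are narrow (tau > `narrow_cut`) and share
#' the same peak tissue, cross-tabulated by family origin.
#'
#' @param families data.frame `family_id`, `species`, `gene` (ortholog map).
#' @param tau_a,tau_b [tau_table()]-style data.frames (`gene`, `tau`,
#'   `peak_tissue`) for Ag and Dm.
#' @param narrow_cut tau threshold for table B (default 0.85, strict).
#' @return list with `expanded` (data.frame family_id, gene, peak_tissue)
#'   and `single_copy` (data.frame family_id, gene_a, gene_b, peak_tissue,
#'   origin).
#' @export
narrow_family_report <- function(families, tau_a, tau_b, narrow_cut = 0.85) {
  fam_split <- split(families, families$family_id)
  exp_rows <- list(); sc_rows <- list()
  for (f in fam_split) {
    sp <- f$species
    copies <- classify_family_copies(sp)
    if (copies == "expanded") {
      ag <- f$gene[sp == "Ag"]
      t_ag <- tau_a[match(ag, tau_a$gene), ]
      hit <- which(!is.na(t_ag$tau) & t_ag$tau == 1)
      if (length(hit))
        exp_rows[[length(exp_rows) + 1L]] <-
          data.frame(family_id = f$family_id[1L], gene = ag[hit],
                     peak_tissue = t_ag$peak_tissue[hit],
                     stringsAsFactors = FALSE)
    } else if (sum(sp == "Dm") == 1L) {
      ga <- f$gene[sp == "Ag"]; gb <- f$gene[sp == "Dm"]
      ta <- tau_a[match(ga, tau_a$gene), ]
      tb <- tau_b[match(gb, tau_b$gene), ]
      if (!is.na(ta$tau) && !is.na(tb$tau) &&
          ta$tau > narrow_cut && tb$tau > narrow_cut &&
          ta$peak_tissue == tb$peak_tissue)
        sc_rows[[length(sc_rows) + 1L]] <-
          data.frame(family_id = f$family_id[1L], gene_a = ga, gene_b = gb,
                     peak_tissue = ta$peak_tissue,
                     origin = family_origin(sp), stringsAsFactors = FALSE)
    }
  }
  list(expanded = if (length(exp_rows)) do.call(rbind, exp_rows)
         else data.frame(family_id = character(), gene = character(),
                         peak_tissue = character()),
       single_copy = if (length(sc_rows)) do.call(rbind, sc_rows)
         else data.frame(family_id = character(), gene_a = character(),
                         gene_b = character(), peak_tissue = character(),
                         origin = character()))
}
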