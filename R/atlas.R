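# The expression_atlas container and sample-key handling.

VALID_SEXES <- c("male", "female", "combined")

#' Default tissue panel
#'
#' The dissected adult tissues of the atlas. `gonad` is sex-resolved
#' implicitly: it denotes the ovary in female samples and the testis in male
#' samples, so the panel does not double up germline tissues.
#' @return character vector of tissue labels.
#' @export
atlas_tissues <- function() {
  c("head", "midgut", "salivary gland", "Malpighian tubules",
    "carcass", "gonad", "accessory gland")
}

#' Parse sample keys of the form "tissue:sex:replicate"
#'
#' @param keys character vector, e.g. `"head:male:1"`.
#' @return data.frame with columns `tissue`, `sex`, `replicate`, `key`.
#' @examples
#' parse_sample_keys("head:male:1")
#' @export
parse_sample_keys <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop2("unparseable sample key(s) at column(s) ", paste(bad, collapse = ", "),
          ": ", paste(keys[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  rep_num <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(rep_num) | rep_num < 1 | rep_num != round(rep_num))
  if (length(bad))
    stop2("replicate must be a positive integer in sample key(s): ",
          paste(keys[bad], collapse = ", "))
  bad <- which(!m[, 2L] %in% VALID_SEXES)
  if (length(bad))
    stop2("sex must be one of ", paste(VALID_SEXES, collapse = "/"),
          " in sample key(s): ", paste(keys[bad], collapse = ", "))
  out <- data.frame(tissue = m[, 1L], sex = m[, 2L],
                    replicate = as.integer(rep_num),
                    key = keys, stringsAsFactors = FALSE)
  if (anyDuplicated(out$key))
    stop2("duplicate sample key(s): ",
          paste(unique(out$key[duplicated(out$key)]), collapse = ", "))
  out
}

#' Construct an expression atlas
#'
#' Bundles a probe-by-sample matrix of log2 intensities with its sample keys
#' and probe/gene annotation. Every probe must map to exactly one gene; every
#' cell must be finite.
#'
#' @param values numeric matrix, probes in rows, samples in columns; column
#'   names are sample keys `"tissue:sex:replicate"`.
#' @param probe_annotation data.frame with columns `probe`, `gene`.
#' @param gene_annotation data.frame with columns `gene`, `arm`; arms in
#'   `{X, 2R, 2L, 3R, 3L, unknown}`. Optional.
#' @return object of class `expression_atlas` with elements `values`,
#'   `samples`, `probes`, `genes`.
#' @export
expression_atlas <- function(values, probe_annotation, gene_annotation = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("values must have probe rownames and sample-key colnames")
  if (anyNA(values) || any(!is.finite(values)))
    stop2("expression matrix contains missing or non-finite cells")
  samples <- parse_sample_keys(colnames(values))
  if (anyDuplicated(rownames(values)))
    stop2("duplicated probe identifiers")
  pa <- probe_annotation
  stopifnot(all(c("probe", "gene") %in% names(pa)))
  dup <- unique(pa$probe[duplicated(pa$probe)])
  if (length(dup))
    stop2("probe(s) mapped to more than one gene rejected: ",
          paste(utils::head(dup, 10L), collapse = ", "))
  missing <- setdiff(rownames(values), pa$probe)
  if (length(missing))
    stop2("probe(s) absent from annotation: ",
          paste(utils::head(missing, 10L), collapse = ", "))
  pa <- pa[match(rownames(values), pa$probe), c("probe", "gene")]
  rownames(pa) <- NULL
  if (!is.null(gene_annotation)) {
    stopifnot(all(c("gene", "arm") %in% names(gene_annotation)))
    ok <- gene_annotation$arm %in% c("X", "2R", "2L", "3R", "3L", "unknown")
    if (!all(ok))
      stop2("unknown chromosome arm label(s): ",
            paste(unique(gene_annotation$arm[!ok]), collapse = ", "))
  }
  structure(list(values = values, samples = samples, probes = pa,
                 genes = gene_annotation),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas: %d probes x %d samples (%d genes, %d tissues)\n",
              nrow(x$values), ncol(x$values), length(unique(x$probes$gene)),
              length(unique(x$samples$tissue))))
  invisible(x)
}

#' Per-(tissue, sex) mean intensities
#'
#' Averages replicates within each (tissue, sex) sample group.
#'
#' @param atlas an `expression_atlas`.
#' @return probe x group matrix; columns named `"tissue:sex"`.
#' @export
tissue_sex_means <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  grp <- paste(atlas$samples$tissue, atlas$samples$sex, sep = ":")
  ug <- unique(grp)
  out <- vapply(ug, function(g)
    rowMeans(atlas$values[, grp == g, drop = FALSE]),
    numeric(nrow(atlas$values)))
  colnames(out) <- ug
  out
}

# Column indices of the samples for one (tissue, sex).
sample_index <- function(atlas, tissue, sex) {
  which(atlas$samples$tissue == tissue & atlas$samples$sex == sex)
}
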