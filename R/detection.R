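# Present/absent detection calls from paired perfect-match (PM) and
# mismatch (MM) probe signals, replicate consensus, expressed fractions,
# and single-(tissue, sex) specific detection.
#
# Per probe pair the discrimination score is R_i = (PM_i - MM_i)/(PM_i + MM_i);
# the call tests H0: median R = tau_det against H1: median R > tau_det with a
# one-sided Wilcoxon signed-rank statistic (the classic Affymetrix P/M/A
# parameterization; tau_det = 0.015, alpha1 = 0.04, alpha2 = 0.06).

# One-sided signed-rank p-value P(W >= w) for differences d, exact (discrete
# null over ranks 1..n) up to 25 informative pairs, normal approximation with
# tie correction and continuity correction beyond. Zeros are dropped; ties in
# |d| take midranks.
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    stats::psignrank(ceiling(w) - 1L, n, lower.tail = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    stats::pnorm((w - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
  }
}

#' Present/marginal/absent call for one probe set
#'
#' @param pm,mm positive PM and MM intensities, one entry per probe pair
#'   (at least 6 pairs).
#' @param tau_det small positive shift tested against the median
#'   discrimination score (default 0.015).
#' @param alpha1,alpha2 p-value cutoffs: present if p < alpha1, marginal if
#'   alpha1 <= p < alpha2, else absent.
#' @return list with `call` (`"present"`, `"marginal"` or `"absent"`) and
#'   `p_value`.
#' @examples
#' detect_probe(pm = rep(3, 11), mm = rep(1, 11))  # present, p = 2^-11
#' @export
detect_probe <- function(pm, mm, tau_det = 0.015, alpha1 = 0.04,
                         alpha2 = 0.06) {
  if (length(pm) != length(mm)) stop2("pm and mm must have equal length")
  if (length(pm) < 6L) stop2("insufficient probe pairs (need >= 6)")
  if (any(pm <= 0) || any(mm <= 0)) stop2("PM and MM must be positive")
  if (!(alpha1 < alpha2)) stop2("alpha1 must be < alpha2")
  if (tau_det < 0) stop2("tau_det must be >= 0")
  if (any(pm + mm == 0)) stop2("PM + MM must be positive")
  R <- (pm - mm) / (pm + mm)
  p <- signed_rank_p(R - tau_det)
  call <- if (p < alpha1) "present" else if (p < alpha2) "marginal" else "absent"
  list(call = call, p_value = p)
}

#' Replicate consensus for presence
#'
#' A probe is called detected in a (tissue, sex) cell iff at least
#' `min_present` of its replicate-level calls are `"present"`; marginal calls
#' do not count.
#'
#' @param calls character vector of replicate calls
#'   (`"present"`/`"marginal"`/`"absent"`).
#' @param min_present required number of present calls (default 3). More
#'   replicates than `min_present` must be supplied (a 3-of-3 vote cannot
#'   satisfy 3-of-4 semantics).
#' @return logical scalar.
#' @export
consensus_present <- function(calls, min_present = 3L) {
  stopifnot(all(calls %in% c("present", "marginal", "absent")))
  if (length(calls) <= min_present)
    stop2("need more replicates than min_present (got ", length(calls),
          " with min_present = ", min_present, ")")
  sum(calls == "present") >= min_present
}

#' Detection calls for a simulated or loaded PM/MM signal set
#'
#' Applies [detect_probe()] to every probe x sample cell of a
#' `probe_signal_set` (see [simulate_atlas()]) and collapses replicates to a
#' per-(probe, tissue, sex) consensus.
#'
#' @param signal a `probe_signal_set`: list with 3-d arrays `pm`, `mm` of
#'   dimension probe x pair x sample and a `samples` data.frame.
#' @param tau_det,alpha1,alpha2 as in [detect_probe()].
#' @param min_present as in [consensus_present()].
#' @return a `detection_table`: data.frame with columns `probe`, `tissue`,
#'   `sex`, `n_present`, `n_replicates`, `detected`.
#' @export
detection_table <- function(signal, tau_det = 0.015, alpha1 = 0.04,
                            alpha2 = 0.06, min_present = 3L) {
  stopifnot(inherits(signal, "probe_signal_set"))
  pm <- signal$pm; mm <- signal$mm
  np <- dim(pm)[1L]; ns <- dim(pm)[3L]
  present <- matrix(FALSE, np, ns)
  for (s in seq_len(ns)) {
    R <- (pm[, , s] - mm[, , s]) / (pm[, , s] + mm[, , s])
    pv <- apply(R - tau_det, 1L, signed_rank_p)
    present[, s] <- pv < alpha1
  }
  grp <- paste(signal$samples$tissue, signal$samples$sex, sep = "\r")
  ug <- unique(grp)
  res <- lapply(ug, function(g) {
    idx <- which(grp == g)
    if (length(idx) <= min_present)
      stop2("tissue/sex group with <= min_present replicates")
    npres <- rowSums(present[, idx, drop = FALSE])
    data.frame(probe = dimnames(pm)[[1L]],
               tissue = signal$samples$tissue[idx[1L]],
               sex = signal$samples$sex[idx[1L]],
               n_present = npres, n_replicates = length(idx),
               detected = npres >= min_present,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("detection_table", "data.frame")
  attr(out, "min_present") <- min_present
  out
}

#' Fraction of probes detected in one (tissue, sex) sample group
#'
#' @param table a `detection_table`.
#' @param tissue,sex the sample group.
#' @return fraction in \[0, 1\] of probes with consensus detection.
#' @export
expressed_fraction <- function(table, tissue, sex) {
  sel <- table$tissue == tissue & table$sex == sex
  if (!any(sel)) stop2("no entries for (", tissue, ", ", sex, ")")
  mean(table$detected[sel])
}

#' Genes detected in exactly one (tissue, sex) cell
#'
#' Probe-level consensus calls are first collapsed to gene level by logical
#' OR over a gene's probes; genes whose detection is true in exactly one
#' (tissue, sex) cell and false in all others are reported.
#'
#' @param table a `detection_table` covering at least 2 tissues.
#' @param probe_annotation data.frame mapping `probe` to `gene`.
#' @return data.frame with columns `gene`, `tissue`, `sex`.
#' @export
tissue_specific_detected <- function(table, probe_annotation) {
  if (length(unique(table$tissue)) < 2L)
    stop2("detection table must cover at least 2 tissues")
  gene <- probe_annotation$gene[match(table$probe, probe_annotation$probe)]
  if (anyNA(gene)) stop2("unannotated probe(s) in detection table")
  cell <- paste(table$tissue, table$sex, sep = "\r")
  agg <- stats::aggregate(detected ~ g + cell,
                          data = data.frame(detected = table$detected,
                                            g = gene, cell = cell),
                          FUN = any)
  hits <- agg[agg$detected, ]
  n_cells <- table(hits$g)
  uni <- names(n_cells)[n_cells == 1L]
  hits <- hits[hits$g %in% uni, ]
  parts <- strsplit(hits$cell, "\r", fixed = TRUE)
  out <- data.frame(gene = hits$g,
                    tissue = vapply(parts, `[[`, "", 1L),
                    sex = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}
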