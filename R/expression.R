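## Stringent microarray differential-expression screen.
##
## The screen mirrors a triplicate WT vs MeCP2-deficient (KO) array
## design: a detection-call prefilter per direction, quantile
## normalization + log2, an unpaired t test per probe (raw P < 0.005 or
## BH FDR 0.05 modes), a linear fold-change gate, and an any-probe
## collapse from probes to genes.

valid_calls <- c("present", "marginal", "absent")

#' Detection-call prefilter
#'
#' Keeps probes called present or marginally present in at least
#' `min_detected` samples of the target group. A full screen builds two
#' lists: the KO-filtered list feeds the up-in-KO candidates and the
#' WT-filtered list the down-in-KO candidates (a transcript must be
#' detectable in the genotype where it is claimed higher).
#'
#' @param calls Character matrix probes x samples with values
#'   `present`, `marginal` or `absent`.
#' @param groups Factor/character of group labels (`WT`/`KO`) aligned
#'   with `colnames(calls)`.
#' @param target_group Group whose samples are inspected.
#' @param min_detected Minimum detected samples (default 2 of 3).
#' @return Character vector of passing probe ids.
#' @export
detection_prefilter <- function(calls, groups, target_group,
                                min_detected = 2) {
  stopifnot(is.matrix(calls))
  bad <- setdiff(unique(as.vector(calls)), valid_calls)
  if (length(bad))
    stop("invalid detection call(s): ", paste(bad, collapse = ", "))
  sel <- groups == target_group
  if (!any(sel)) stop("no samples in group ", target_group)
  if (min_detected > sum(sel))
    stop("min_detected (", min_detected, ") exceeds group size (",
         sum(sel), ")")
  detected <- calls[, sel, drop = FALSE] %in% c("present", "marginal")
  detected <- matrix(detected, nrow = nrow(calls))
  rownames(calls)[rowSums(detected) >= min_detected]
}

#' Fallback detection calls for matrices without MAS5-style calls
#'
#' A probe is called `present` in a sample iff its intensity exceeds
#' the given background quantile of that sample's intensities.
#'
#' @param mat Intensity matrix probes x samples.
#' @param background_quantile Per-sample background quantile
#'   (default 0.25).
#' @return Character matrix of calls (`present`/`absent`).
#' @export
threshold_detection_calls <- function(mat, background_quantile = 0.25) {
  thr <- apply(mat, 2, quantile, probs = background_quantile)
  calls <- ifelse(sweep(mat, 2, thr, ">"), "present", "absent")
  dimnames(calls) <- dimnames(mat)
  calls
}

#' Quantile-normalize and log2-transform an expression matrix
#'
#' `quantile_log2` applies across-sample quantile normalization
#' (identical intensity distributions per sample) followed by log2;
#' `passthrough` returns the matrix unchanged for data already on the
#' log2 scale. With a single probe, quantile normalization is
#' degenerate and is treated as the identity before the log2.
#'
#' @param mat Numeric matrix probes x samples (raw intensities for
#'   `quantile_log2`, log2 values for `passthrough`).
#' @param method `"quantile_log2"` or `"passthrough"`.
#' @return log2-scale matrix.
#' @export
normalize_log2 <- function(mat, method = c("quantile_log2", "passthrough")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mat), !anyNA(mat))
  if (method == "passthrough") return(mat)
  if (any(mat <= 0))
    stop("quantile_log2 requires positive raw intensities")
  out <- if (nrow(mat) > 1) limma::normalizeQuantiles(mat) else mat
  log2(out)
}

## Vectorized per-row unpaired t test on a log2 matrix.
## Equal-variance (classic Student) by default; Welch optional.
row_t_test <- function(mat, sel1, sel2, var_equal = TRUE) {
  n1 <- sum(sel1); n2 <- sum(sel2)
  m1 <- rowMeans(mat[, sel1, drop = FALSE])
  m2 <- rowMeans(mat[, sel2, drop = FALSE])
  v1 <- apply(mat[, sel1, drop = FALSE], 1, var)
  v2 <- apply(mat[, sel2, drop = FALSE], 1, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  testable <- se > 0
  t_stat <- ifelse(testable, (m2 - m1) / se, NA_real_)
  p <- ifelse(testable, 2 * pt(-abs(t_stat), df), NA_real_)
  list(mean1 = m1, mean2 = m2, t = t_stat, p = p, testable = testable)
}

#' Differential expression screen between WT and KO
#'
#' Per probe: two-sided unpaired t test on log2 values
#' (equal-variance by default), linear fold change
#' `2^|mean_KO - mean_WT|` with direction `up_in_KO` or `down_in_KO`.
#' Significance modes: `rawp` (stringent raw `P < p_cutoff`, default
#' 0.005) or `fdr` (BH q <= `fdr_cutoff`, default 0.05, adjusted within
#' each direction-specific prefiltered list). A probe passes when the
#' mode criterion holds, its fold change exceeds `fc_cutoff`, and its
#' direction is consistent with the prefiltered list it came from
#' (up-candidates from the KO-detected list, down-candidates from the
#' WT-detected list). Probes with zero variance in both groups are
#' untestable and excluded with a warning.
#'
#' @param log2_mat log2 expression matrix probes x samples.
#' @param groups Group labels (`WT`/`KO`) aligned with columns.
#' @param mode `"rawp"` or `"fdr"`.
#' @param p_cutoff Raw-P threshold for `rawp` mode (default 0.005).
#' @param fdr_cutoff BH threshold for `fdr` mode (default 0.05).
#' @param fc_cutoff Linear fold-change gate, exceeded strictly
#'   (default 1.2; 1.5 for the stricter screen).
#' @param ko_detected,wt_detected Probe ids surviving
#'   [detection_prefilter()] for KO and WT; default all probes.
#' @param var_equal Classic equal-variance t (default) or Welch.
#' @return data.frame, one row per probe in either prefiltered list:
#'   means, `log2_fc` (KO - WT), `fold_change`, `direction`, `t`, `p`,
#'   `q` (from the direction-matching list; `NA` if the probe is absent
#'   from that list), `testable`, `passes`.
#' @export
differential_expression <- function(log2_mat, groups,
                                    mode = c("rawp", "fdr"),
                                    p_cutoff = 0.005, fdr_cutoff = 0.05,
                                    fc_cutoff = 1.2,
                                    ko_detected = rownames(log2_mat),
                                    wt_detected = rownames(log2_mat),
                                    var_equal = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(log2_mat), !is.null(rownames(log2_mat)))
  groups <- as.character(groups)
  if (!all(sort(unique(groups)) == c("KO", "WT")))
    stop("groups must contain exactly the labels WT and KO")
  sel_wt <- groups == "WT"; sel_ko <- groups == "KO"
  if (sum(sel_wt) < 2 || sum(sel_ko) < 2)
    stop("need at least 2 samples per group")

  probes <- union(ko_detected, wt_detected)
  probes <- rownames(log2_mat)[rownames(log2_mat) %in% probes]
  if (!length(probes)) stop("no probes survive the prefilter")
  tt <- row_t_test(log2_mat[probes, , drop = FALSE], sel_wt, sel_ko,
                   var_equal = var_equal)
  log2_fc <- tt$mean2 - tt$mean1  # KO - WT
  res <- data.frame(
    probe_id = probes,
    mean_log2_wt = tt$mean1, mean_log2_ko = tt$mean2,
    log2_fc = log2_fc,
    fold_change = 2^abs(log2_fc),
    direction = ifelse(log2_fc >= 0, "up_in_KO", "down_in_KO"),
    t = tt$t, p = tt$p, q = NA_real_,
    testable = tt$testable,
    stringsAsFactors = FALSE)
  if (any(!res$testable))
    warning(sum(!res$testable),
            " probe(s) with zero variance in both groups are untestable ",
            "and never pass")

  in_ko_list <- res$probe_id %in% ko_detected
  in_wt_list <- res$probe_id %in% wt_detected
  # BH within each direction-specific prefiltered list
  q_ko <- q_wt <- rep(NA_real_, nrow(res))
  q_ko[in_ko_list] <- p.adjust(res$p[in_ko_list], method = "BH")
  q_wt[in_wt_list] <- p.adjust(res$p[in_wt_list], method = "BH")
  res$q <- ifelse(res$direction == "up_in_KO", q_ko, q_wt)

  sig <- if (mode == "rawp") !is.na(res$p) & res$p < p_cutoff
         else !is.na(res$q) & res$q <= fdr_cutoff
  dir_ok <- (res$direction == "up_in_KO" & in_ko_list) |
            (res$direction == "down_in_KO" & in_wt_list)
  res$passes <- res$testable & sig & res$fold_change > fc_cutoff & dir_ok
  rownames(res) <- NULL
  attr(res, "mode") <- mode
  attr(res, "fc_cutoff") <- fc_cutoff
  res
}

#' Collapse probe-level results to genes
#'
#' A gene is differentially expressed iff at least one of its probes
#' passes; its direction, fold and statistics come from the
#' smallest-p passing probe. Genes whose passing probes disagree in
#' direction are flagged `discordant` but retained with the
#' representative probe's direction. Passing probes missing from the
#' map are reported separately as unannotated.
#'
#' @param de_result Probe table from [differential_expression()].
#' @param probe_map data.frame with `probe_id`, `gene_id` (many probes
#'   to one gene).
#' @return list with `genes` (data.frame `gene_id`, `direction`,
#'   `fold_change`, `log2_fc`, `p`, `q`, `probe_id`, `n_probes_passing`,
#'   `discordant`) and `unannotated` (character).
#' @export
collapse_probes_to_genes <- function(de_result, probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  pass <- de_result[de_result$passes, , drop = FALSE]
  m <- match(pass$probe_id, probe_map$probe_id)
  unannotated <- pass$probe_id[is.na(m)]
  pass <- pass[!is.na(m), , drop = FALSE]
  pass$gene_id <- probe_map$gene_id[m[!is.na(m)]]
  if (nrow(pass) == 0)
    return(list(genes = data.frame(gene_id = character(),
                                   direction = character(),
                                   fold_change = numeric(),
                                   log2_fc = numeric(), p = numeric(),
                                   q = numeric(), probe_id = character(),
                                   n_probes_passing = integer(),
                                   discordant = logical(),
                                   stringsAsFactors = FALSE),
                unannotated = unannotated))
  genes <- do.call(rbind, lapply(split(pass, pass$gene_id), function(d) {
    best <- d[order(d$p, d$probe_id, method = "radix")[1], ]
    data.frame(gene_id = best$gene_id, direction = best$direction,
               fold_change = best$fold_change, log2_fc = best$log2_fc,
               p = best$p, q = best$q, probe_id = best$probe_id,
               n_probes_passing = nrow(d),
               discordant = length(unique(d$direction)) > 1,
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$p, genes$gene_id, method = "radix"), ]
  rownames(genes) <- NULL
  list(genes = genes, unannotated = unannotated)
}
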