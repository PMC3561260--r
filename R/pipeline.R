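## End-to-end convenience wrapper: window quantification -> DE screen
## -> target intersection.

#' Run the integrated target screen
#'
#' Quantifies ChIP vs input binding over the gene windows, runs the
#' detection-prefiltered differential-expression screen, collapses
#' probes to genes, and intersects the DE gene list with the per-window
#' top-decile binding lists.
#'
#' @param chip,input [read_library()] objects.
#' @param windows Window table from [derive_windows()].
#' @param log2_mat,groups,calls,probe_map Expression screen inputs (see
#'   [differential_expression()]); `calls` may be `NULL`, in which case
#'   no prefilter is applied.
#' @param mode,p_cutoff,fdr_cutoff,fc_cutoff DE screen settings.
#' @param fraction Top fraction per window.
#' @param fragment_extension_bp,assignment Read-counting settings.
#' @return list `quantification`, `de_probes`, `de_genes`,
#'   `unannotated`, `targets` (a `target_set`), `direction_summary`.
#' @export
run_screen <- function(chip, input, windows, log2_mat, groups,
                       calls = NULL, probe_map,
                       mode = "rawp", p_cutoff = 0.005,
                       fdr_cutoff = 0.05, fc_cutoff = 1.2,
                       fraction = 0.10, fragment_extension_bp = 200,
                       assignment = "midpoint") {
  quant <- quantify_windows(chip, input, windows,
                            fragment_extension_bp = fragment_extension_bp,
                            assignment = assignment, fraction = fraction)
  if (!is.null(calls)) {
    ko_list <- detection_prefilter(calls, groups, "KO")
    wt_list <- detection_prefilter(calls, groups, "WT")
  } else {
    ko_list <- wt_list <- rownames(log2_mat)
  }
  de <- differential_expression(log2_mat, groups, mode = mode,
                                p_cutoff = p_cutoff,
                                fdr_cutoff = fdr_cutoff,
                                fc_cutoff = fc_cutoff,
                                ko_detected = ko_list,
                                wt_detected = wt_list)
  coll <- collapse_probes_to_genes(de, probe_map)
  targets <- intersect_targets(coll$genes, quant)
  list(quantification = quant, de_probes = de, de_genes = coll$genes,
       unannotated = coll$unannotated, targets = targets,
       direction_summary = direction_by_region_summary(targets))
}
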