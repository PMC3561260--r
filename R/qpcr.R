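## Comparative-Ct (delta-delta Ct) relative quantification and
## standard-curve quantitation for qPCR validation.
##
## The comparative Ct method assumes perfect doubling per cycle
## (amplification efficiency 2): DCt = Ct_target - Ct_reference within
## a sample, DDCt = DCt - mean(DCt of the calibrator group), and
## relative expression = 2^(-DDCt).

#' Delta-delta Ct relative quantification
#'
#' Ct tables carry one row per technical replicate with the target and
#' reference (default Gapdh) Ct measured in the same sample. Technical
#' replicates are averaged to one DCt per sample before calibration
#' unless `average_technical = FALSE`.
#'
#' @param ct data.frame with `sample_id`, `genotype` (`WT`/`KO`),
#'   `gene`, `ct_target`, `ct_reference` and optionally `replicate`.
#' @param calibrator Genotype used as calibrator (default `"WT"`).
#' @param average_technical Average technical replicates per sample
#'   (default TRUE).
#' @return data.frame `sample_id`, `genotype`, `gene`, `dct`, `ddct`,
#'   `fold` (one row per sample, or per technical replicate).
#' @export
delta_delta_ct <- function(ct, calibrator = "WT", average_technical = TRUE) {
  need <- c("sample_id", "genotype", "gene", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  bad <- !is.finite(ct$ct_target) | !is.finite(ct$ct_reference) |
    ct$ct_target <= 0 | ct$ct_reference <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) rejected: missing or nonpositive Ct")
    ct <- ct[!bad, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(ct, ct$gene), function(d) {
    d$dct <- d$ct_target - d$ct_reference
    if (average_technical) {
      agg <- stats::aggregate(dct ~ sample_id + genotype + gene, data = d,
                              FUN = mean)
      d <- agg
    }
    cal <- d$dct[d$genotype == calibrator]
    if (!length(cal))
      stop("no calibrator (", calibrator, ") samples for gene ",
           d$gene[1])
    d$ddct <- d$dct - mean(cal)
    d$fold <- 2^(-d$ddct)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Replicate concordance in the style of a validation table
#'
#' For each gene and each biological replicate pair (one WT and one KO
#' culture, identified by a `pair` column), the technical-replicate
#' DCt values of the two genotypes are compared with one-tailed
#' unpaired t tests at `alpha`. A pair counts as "increased in KO"
#' when the KO DCt is significantly lower (fewer cycles = more
#' transcript), "reduced" when significantly higher, otherwise "no
#' change". Concordance is the count of pairs changed in the direction
#' the microarray predicted.
#'
#' @param ct Ct table as in [delta_delta_ct()] plus a `pair` column.
#' @param microarray_direction Named character vector per gene,
#'   `"up_in_KO"` or `"down_in_KO"`.
#' @param alpha One-tailed significance level (default 0.05).
#' @return data.frame per gene: `gene`, `microarray_direction`,
#'   `increased`, `reduced`, `no_change`, `concordant`.
#' @export
replicate_concordance <- function(ct, microarray_direction, alpha = 0.05) {
  stopifnot("pair" %in% names(ct))
  out <- do.call(rbind, lapply(split(ct, ct$gene), function(d) {
    gene <- d$gene[1]
    dct <- d$ct_target - d$ct_reference
    inc <- red <- noc <- 0L
    for (pr in sort(unique(d$pair))) {
      wt <- dct[d$pair == pr & d$genotype == "WT"]
      ko <- dct[d$pair == pr & d$genotype == "KO"]
      if (length(wt) < 2 || length(ko) < 2) {
        warning("gene ", gene, " pair ", pr,
                ": <2 technical replicates, counted as no change")
        noc <- noc + 1L
        next
      }
      p_inc <- t.test(ko, wt, alternative = "less")$p.value
      p_red <- t.test(ko, wt, alternative = "greater")$p.value
      if (p_inc < alpha) inc <- inc + 1L
      else if (p_red < alpha) red <- red + 1L
      else noc <- noc + 1L
    }
    dir <- microarray_direction[[gene]]
    data.frame(gene = gene, microarray_direction = dir,
               increased = inc, reduced = red, no_change = noc,
               concordant = if (identical(dir, "up_in_KO")) inc else red,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `ct = slope * log10(quantity) + intercept` over
#' dilution points; the efficiency diagnostic is
#' `10^(-1/slope) - 1` (1 = perfect doubling per cycle).
#'
#' @param quantity_pg DNA quantities in picograms (>= 3 distinct
#'   values).
#' @param ct Measured Ct per point.
#' @return list `slope`, `intercept`, `efficiency`, `range`
#'   (quantity range), class `standard_curve`.
#' @export
fit_standard_curve <- function(quantity_pg, ct) {
  stopifnot(length(quantity_pg) == length(ct))
  lq <- log10(quantity_pg)
  if (length(unique(lq)) < 3)
    stop("need at least 3 distinct quantities for a standard curve")
  fit <- lm(ct ~ lq)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope >= 0) stop("standard curve slope must be negative")
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1,
                 range = range(quantity_pg)),
            class = "standard_curve")
}

#' Quantify unknowns against a standard curve
#'
#' Inverts the fitted line: `quantity = 10^((ct - intercept) / slope)`.
#' Unknowns whose estimate falls outside the curve's quantity range are
#' flagged as extrapolated, not rejected.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param unknown_ct Ct value(s) to quantify.
#' @return data.frame `ct`, `quantity_pg`, `extrapolated`.
#' @export
standard_curve_quantify <- function(curve, unknown_ct) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- 10^((unknown_ct - curve$intercept) / curve$slope)
  data.frame(ct = unknown_ct, quantity_pg = q,
             extrapolated = q < curve$range[1] | q > curve$range[2])
}
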