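## Intersect the gene-level DE list with per-window top-decile binding
## lists. The paper-style readout is three per-window target lists, a
## unique union, and the genes bound in more than one window.

#' Intersect differential expression with top-decile binding
#'
#' @param de_genes Gene-level DE table ([collapse_probes_to_genes()]
#'   `$genes`): needs `gene_id`, `direction`, `fold_change`, `p`.
#' @param quantification Window quantification from
#'   [quantify_windows()] (uses `top`, `score`, `rank`).
#' @return A `target_set`: list with `per_window` (data.frame `window`,
#'   `gene_id`, `score`, `rank`, `direction`, `fold_change`, `p`,
#'   ordered by descending score within window), `union` (unique gene
#'   ids), `duplicates` (genes in >= 2 window lists), and `venn`
#'   (per-window |DE|, |top|, |intersection|).
#' @export
intersect_targets <- function(de_genes, quantification) {
  if (nrow(de_genes) == 0)
    warning("empty differential-expression gene list")
  wins <- intersect(c("tss", "body", "tes"), unique(quantification$window))
  per <- lapply(wins, function(w) {
    q <- quantification[quantification$window == w & quantification$top, ,
                        drop = FALSE]
    if (nrow(q) == 0) warning("empty top-decile list for window ", w)
    hit <- q[q$gene_id %in% de_genes$gene_id, , drop = FALSE]
    hit <- hit[order(-hit$score, hit$gene_id, method = "radix"), ,
               drop = FALSE]
    m <- match(hit$gene_id, de_genes$gene_id)
    data.frame(window = rep(w, nrow(hit)), gene_id = hit$gene_id,
               score = hit$score,
               rank = hit$rank, direction = de_genes$direction[m],
               fold_change = de_genes$fold_change[m], p = de_genes$p[m],
               stringsAsFactors = FALSE)
  })
  per_window <- do.call(rbind, per)
  rownames(per_window) <- NULL
  tab <- table(as.character(per_window$gene_id))
  dups <- as.character(names(tab)[tab >= 2])
  venn <- data.frame(
    window = wins,
    n_de = nrow(de_genes),
    n_top = vapply(wins, function(w)
      sum(quantification$window == w & quantification$top), integer(1)),
    n_intersection = vapply(per, nrow, integer(1)),
    stringsAsFactors = FALSE)
  rownames(venn) <- NULL
  structure(list(per_window = per_window,
                 union = sort(unique(per_window$gene_id), method = "radix"),
                 duplicates = sort(dups, method = "radix"),
                 venn = venn),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("MeCP2 target set:", length(x$union), "unique gene(s)\n")
  for (i in seq_len(nrow(x$venn)))
    cat(sprintf("  %-5s top %d  x  DE %d  ->  %d target(s)\n",
                x$venn$window[i], x$venn$n_top[i], x$venn$n_de[i],
                x$venn$n_intersection[i]))
  if (length(x$duplicates))
    cat("  bound in >1 window:", paste(x$duplicates, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate DE direction by binding window
#'
#' Counts up-in-KO vs down-in-KO target genes per window — e.g. TES
#' binding coinciding almost exclusively with upregulation in KO is the
#' signature of repression at the transcription end site.
#'
#' @param targets A [intersect_targets()] result.
#' @return data.frame `window`, `up_in_KO`, `down_in_KO`.
#' @export
direction_by_region_summary <- function(targets) {
  stopifnot(inherits(targets, "target_set"))
  wins <- targets$venn$window
  pw <- targets$per_window
  data.frame(
    window = wins,
    up_in_KO = vapply(wins, function(w)
      sum(pw$window == w & pw$direction == "up_in_KO"), integer(1)),
    down_in_KO = vapply(wins, function(w)
      sum(pw$window == w & pw$direction == "down_in_KO"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
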