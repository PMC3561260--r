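## Synthetic study generator with planted truth.
##
## Emulates the study design end to end: a compact gene annotation, a
## ChIP library with diffuse (non-peaky) enrichment planted in chosen
## gene windows over uniform background, a matching uniform input
## library, a triplicate WT vs KO expression matrix with a small set of
## modest planted effects, and Ct tables consistent with planted fold
## changes. Every generator is deterministic given (seed, parameters);
## a master seed derives per-component substreams so modules can be
## regenerated independently.

derive_subseeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a compact genome annotation
#'
#' Places non-overlapping genes with random lengths, spacings and
#' strands along `n_chroms` chromosomes (round-robin); chromosome sizes
#' are taken large enough to hold the packed genes plus a margin unless
#' `chrom_length` is fixed, in which case infeasible packing is an
#' error.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes.
#' @param gene_length_range,spacing_range bp ranges for gene length and
#'   intergenic spacing.
#' @param margin_bp Clearance at chromosome ends so default +/-2 kb
#'   windows are not clipped.
#' @param chrom_length Optional fixed chromosome length.
#' @param seed Integer seed.
#' @return list `genes` (gene-model data.frame) and `chrom_sizes`.
#' @export
simulate_genome <- function(n_genes = 1000, n_chroms = 5,
                            gene_length_range = c(2000, 8000),
                            spacing_range = c(4000, 8000),
                            margin_bp = 3000, chrom_length = NULL,
                            seed = 1) {
  stopifnot(n_genes >= 0, n_chroms >= 1, all(gene_length_range > 0),
            all(spacing_range > 0))
  set.seed(seed)
  if (n_genes == 0)
    return(list(genes = data.frame(gene_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), strand = character(),
                                   stringsAsFactors = FALSE),
                chrom_sizes = setNames(rep(2 * margin_bp, n_chroms),
                                       paste0("chr", seq_len(n_chroms)))))
  chrom <- paste0("chr", rep_len(seq_len(n_chroms), n_genes))
  len <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
  gap <- round(runif(n_genes, spacing_range[1], spacing_range[2]))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  start <- end <- numeric(n_genes)
  sizes <- setNames(rep(2 * margin_bp, n_chroms),
                    paste0("chr", seq_len(n_chroms)))
  cursor <- setNames(rep(margin_bp, n_chroms), names(sizes))
  for (i in seq_len(n_genes)) {
    ch <- chrom[i]
    start[i] <- cursor[ch] + gap[i]
    end[i] <- start[i] + len[i]
    cursor[ch] <- end[i]
    sizes[ch] <- end[i] + margin_bp
  }
  if (!is.null(chrom_length)) {
    if (any(sizes > chrom_length))
      stop("infeasible packing: genes exceed chrom_length on ",
           paste(names(sizes)[sizes > chrom_length], collapse = ", "))
    sizes[] <- chrom_length
  }
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = chrom, start = start, end = end, strand = strand,
    stringsAsFactors = FALSE)
  validate_gene_models(genes)
  list(genes = genes, chrom_sizes = sizes)
}

#' Plant enrichment and expression truth over a gene roster
#'
#' Chooses which genes carry ChIP enrichment in which window (fold
#' `enrichment_fold`; 1 = background) and which genes carry a planted
#' expression effect. `n_de_enriched` DE genes are drawn from the
#' enriched set (these are the recoverable joint targets) and
#' `n_de_background` from the rest; signs alternate up/down in KO
#' unless `all_up = TRUE`.
#'
#' @param genes Gene-model data.frame.
#' @param n_enriched Named counts per window, e.g.
#'   `c(tss = 50, body = 0, tes = 0)`.
#' @param enrichment_fold Planted fold (>= 1) for enriched windows.
#' @param n_de_enriched,n_de_background Planted DE gene counts.
#' @param log2_effect Absolute planted log2 effect (default
#'   `log2(1.5)`).
#' @param all_up Make every planted effect up-in-KO.
#' @param seed Integer seed.
#' @return `synthetic_truth` list: `seed`, `genes` data.frame with
#'   `fold_tss`, `fold_body`, `fold_tes`, `log2_effect` (signed; 0 =
#'   null).
#' @export
simulate_truth <- function(genes, n_enriched = c(tss = 50, body = 0,
                                                 tes = 0),
                           enrichment_fold = 5, n_de_enriched = 30,
                           n_de_background = 0,
                           log2_effect = log2(1.5), all_up = FALSE,
                           seed = 1) {
  stopifnot(enrichment_fold >= 1, log2_effect >= 0)
  set.seed(seed)
  n <- nrow(genes)
  tr <- data.frame(gene_id = genes$gene_id,
                   fold_tss = 1, fold_body = 1, fold_tes = 1,
                   log2_effect = 0, stringsAsFactors = FALSE)
  for (w in c("tss", "body", "tes")) {
    k <- if (w %in% names(n_enriched)) n_enriched[[w]] else 0
    if (k > 0)
      tr[[paste0("fold_", w)]][sample.int(n, k)] <- enrichment_fold
  }
  enriched <- tr$fold_tss > 1 | tr$fold_body > 1 | tr$fold_tes > 1
  if (n_de_enriched > sum(enriched))
    stop("n_de_enriched exceeds number of enriched genes")
  de_idx <- c(sample(which(enriched), n_de_enriched),
              sample(which(!enriched), n_de_background))
  sgn <- if (all_up) rep(1, length(de_idx))
         else rep_len(c(1, -1), length(de_idx))
  tr$log2_effect[de_idx] <- sgn * log2_effect
  structure(list(seed = seed, genes = tr), class = "synthetic_truth")
}

place_reads <- function(n, chrom, lo, hi, read_len, fragment_len) {
  # 5' fragment ends uniform over positions keeping the fragment in
  # [lo, hi); reads are the first read_len bases from the 5' end.
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  span <- max(hi - lo - fragment_len, 1)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  fs <- lo + floor(runif(n, 0, span))       # fragment start (+ strand)
  start <- ifelse(strand == "+", fs, fs + fragment_len - read_len)
  data.frame(chrom = chrom, start = start, end = start + read_len,
             strand = strand, stringsAsFactors = FALSE)
}

#' Simulate ChIP and input read libraries
#'
#' Input is uniform background at `background_reads_per_kb` over each
#' chromosome. ChIP is an independent draw of the same background plus,
#' for each gene window with planted fold f > 1, extra fragments at
#' rate `(f - 1) * background_reads_per_kb` placed wholly inside the
#' window, so ChIP read density in that window is f-fold the
#' background. Reads are single-end `read_len` bp (the 5' end of a
#' `fragment_len` bp fragment).
#'
#' @param windows Window table from [derive_windows()].
#' @param chrom_sizes Named chromosome lengths.
#' @param truth A [simulate_truth()] object.
#' @param background_reads_per_kb Background density per library.
#' @param fragment_len,read_len Fragment and read length in bp.
#' @param seed Integer seed.
#' @return list `chip`, `input` ([read_library()] objects).
#' @export
simulate_chip_reads <- function(windows, chrom_sizes, truth,
                                background_reads_per_kb = 30,
                                fragment_len = 300, read_len = 76,
                                seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            background_reads_per_kb > 0, fragment_len >= read_len)
  set.seed(seed)
  background <- function() {
    do.call(rbind, lapply(names(chrom_sizes), function(ch) {
      n <- rpois(1, background_reads_per_kb * chrom_sizes[[ch]] / 1000)
      place_reads(n, ch, 0, chrom_sizes[[ch]], read_len, fragment_len)
    }))
  }
  input_reads <- background()
  chip_reads <- background()
  tg <- truth$genes
  extra <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    f <- tg[[paste0("fold_", w$window)]][match(w$gene_id, tg$gene_id)]
    if (is.na(f) || f <= 1 || w$length == 0) return(NULL)
    n <- rpois(1, (f - 1) * background_reads_per_kb * w$length / 1000)
    place_reads(n, w$chrom, w$start, w$end, read_len, fragment_len)
  })
  extra <- do.call(rbind, extra[!vapply(extra, is.null, logical(1))])
  chip_reads <- rbind(chip_reads, extra)
  list(chip = read_library(chip_reads, "chip"),
       input = read_library(input_reads, "input"))
}

#' Simulate a triplicate WT vs KO expression matrix
#'
#' log2 intensities are gene baseline + probe offset + planted group
#' effect (KO only) + Gaussian noise. Several probes map to each gene
#' (many-to-one, as on a real array); probes of a planted gene share
#' its effect. Detection calls are `present` with probability
#' `detection_rate`, else `marginal` or `absent` in equal shares.
#'
#' @param gene_ids Gene roster.
#' @param effects Named signed log2 effects per gene (0/absent = null),
#'   e.g. `truth$genes$log2_effect` named by gene. `NULL` means all
#'   null.
#' @param probes_per_gene Probes mapping to each gene (default 2).
#' @param n_per_group Samples per genotype (default triplicates).
#' @param noise_sd Residual log2 sd (default 0.1).
#' @param detection_rate P(call = present) per probe x sample.
#' @param baseline_range log2 baseline range across genes.
#' @param seed Integer seed.
#' @return list `log2_mat` (probes x samples), `groups`, `calls`,
#'   `probe_map` (`probe_id`, `gene_id`).
#' @export
simulate_expression <- function(gene_ids, effects = NULL,
                                probes_per_gene = 2, n_per_group = 3,
                                noise_sd = 0.1, detection_rate = 0.95,
                                baseline_range = c(6, 12), seed = 1) {
  stopifnot(noise_sd > 0, n_per_group >= 2, probes_per_gene >= 1)
  set.seed(seed)
  n_genes <- length(gene_ids)
  probe_map <- data.frame(
    probe_id = sprintf("p%05d", seq_len(n_genes * probes_per_gene)),
    gene_id = rep(gene_ids, each = probes_per_gene),
    stringsAsFactors = FALSE)
  eff <- rep(0, n_genes)
  if (!is.null(effects)) {
    m <- match(gene_ids, names(effects))
    eff <- ifelse(is.na(m), 0, unname(effects)[m])
  }
  groups <- rep(c("WT", "KO"), each = n_per_group)
  samples <- paste0(groups, "_", rep(seq_len(n_per_group), 2))
  base_gene <- runif(n_genes, baseline_range[1], baseline_range[2])
  base_probe <- rep(base_gene, each = probes_per_gene) +
    rnorm(nrow(probe_map), 0, 0.25)
  eff_probe <- rep(eff, each = probes_per_gene)
  mu <- outer(eff_probe, as.numeric(groups == "KO")) + base_probe
  log2_mat <- mu + rnorm(length(mu), 0, noise_sd)
  dimnames(log2_mat) <- list(probe_map$probe_id, samples)
  u <- runif(length(log2_mat))
  calls <- matrix(ifelse(u < detection_rate, "present",
                         ifelse(u < (1 + detection_rate) / 2, "marginal",
                                "absent")),
                  nrow = nrow(log2_mat), dimnames = dimnames(log2_mat))
  list(log2_mat = log2_mat, groups = groups, calls = calls,
       probe_map = probe_map)
}

#' Simulate Ct tables with planted fold changes
#'
#' Emulates paired WT/KO littermate cultures: per gene and biological
#' pair, the reference gene amplifies at a constant Ct and the target
#' at `base_dct` cycles later in WT; in KO the target Ct shifts by
#' `-log2(fold)` so the comparative-Ct method recovers `fold`.
#'
#' @param folds Named planted KO/WT fold per gene (> 0).
#' @param n_pairs Biological replicate pairs (default 4).
#' @param n_technical Technical replicates per sample (default 3).
#' @param ct_noise_sd Gaussian Ct noise sd (default 0.05 cycles).
#' @param ref_ct,base_dct Reference Ct and baseline target offset.
#' @param seed Integer seed.
#' @return Ct data.frame: `sample_id`, `genotype`, `pair`, `gene`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(folds, n_pairs = 4, n_technical = 3,
                          ct_noise_sd = 0.05, ref_ct = 18, base_dct = 6,
                          seed = 1) {
  stopifnot(all(folds > 0), n_pairs >= 1, n_technical >= 1)
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_technical),
                      genotype = c("WT", "KO"), pair = seq_len(n_pairs),
                      gene = names(folds), stringsAsFactors = FALSE)
  shift <- ifelse(grid$genotype == "KO", -log2(folds[grid$gene]), 0)
  grid$ct_reference <- ref_ct + rnorm(nrow(grid), 0, ct_noise_sd)
  grid$ct_target <- ref_ct + base_dct + shift +
    rnorm(nrow(grid), 0, ct_noise_sd)
  data.frame(sample_id = paste0(grid$genotype, "_pair", grid$pair),
             genotype = grid$genotype, pair = grid$pair, gene = grid$gene,
             replicate = grid$replicate, ct_target = grid$ct_target,
             ct_reference = grid$ct_reference, stringsAsFactors = FALSE)
}

write_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tmecp2screen\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, genes$start + 1, genes$end, genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

write_reads_bed <- function(lib, path) {
  r <- lib$reads
  gr <- GenomicRanges::GRanges(r$chrom,
                               IRanges::IRanges(r$start + 1, r$end),
                               strand = r$strand,
                               name = paste0("read", seq_len(nrow(r))),
                               score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates [simulate_genome()], [simulate_truth()],
#' [simulate_chip_reads()], [simulate_expression()] and
#' [simulate_qpcr()] under substreams derived from one master seed.
#' Optionally serializes the study to standard formats (GTF, TSV, BED,
#' JSON truth record).
#'
#' @param seed Master seed.
#' @param n_genes,n_chroms Annotation size.
#' @param n_enriched,enrichment_fold,n_de_enriched,n_de_background,log2_effect
#'   Planted-truth design (see [simulate_truth()]).
#' @param background_reads_per_kb Read density per library.
#' @param qpcr_genes Number of planted-DE genes carried into the Ct
#'   table (fold `2^|log2_effect|` in the planted direction).
#' @param flank_bp Window flank for the derived windows.
#' @param out_dir Optional output directory for
#'   genes.gtf/sizes.tsv/chip.bed/input.bed/expr.tsv/calls.tsv/
#'   samples.tsv/probes.tsv/ct.tsv/truth.json.
#' @param ... Passed on to [simulate_expression()].
#' @return list with `genes`, `chrom_sizes`, `windows`, `truth`,
#'   `chip`, `input`, `expression`, `ct`, `seed`.
#' @export
simulate_study <- function(seed = 1, n_genes = 1000, n_chroms = 5,
                           n_enriched = c(tss = 50, body = 0, tes = 0),
                           enrichment_fold = 5, n_de_enriched = 30,
                           n_de_background = 0, log2_effect = log2(1.5),
                           background_reads_per_kb = 30, qpcr_genes = 4,
                           flank_bp = 2000, out_dir = NULL, ...) {
  ss <- derive_subseeds(seed, 5)
  gen <- simulate_genome(n_genes = n_genes, n_chroms = n_chroms,
                         seed = ss[1])
  truth <- simulate_truth(gen$genes, n_enriched = n_enriched,
                          enrichment_fold = enrichment_fold,
                          n_de_enriched = n_de_enriched,
                          n_de_background = n_de_background,
                          log2_effect = log2_effect, seed = ss[2])
  windows <- derive_windows(gen$genes, gen$chrom_sizes, flank_bp = flank_bp)
  libs <- simulate_chip_reads(windows, gen$chrom_sizes, truth,
                              background_reads_per_kb =
                                background_reads_per_kb,
                              seed = ss[3])
  effects <- setNames(truth$genes$log2_effect, truth$genes$gene_id)
  expr <- simulate_expression(gen$genes$gene_id, effects = effects,
                              seed = ss[4], ...)
  de_planted <- truth$genes[truth$genes$log2_effect != 0, ]
  qg <- head(de_planted$gene_id, qpcr_genes)
  folds <- setNames(2^de_planted$log2_effect[match(qg, de_planted$gene_id)],
                    qg)
  ct <- if (length(folds)) simulate_qpcr(folds, seed = ss[5]) else NULL
  study <- list(seed = seed, genes = gen$genes,
                chrom_sizes = gen$chrom_sizes, windows = windows,
                truth = truth, chip = libs$chip, input = libs$input,
                expression = expr, ct = ct)
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Serialize a synthetic study to standard file formats
#'
#' @param study A [simulate_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_gtf(study$genes, fp("genes.gtf"))
  write.table(data.frame(names(study$chrom_sizes),
                         unname(study$chrom_sizes)),
              fp("sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_reads_bed(study$chip, fp("chip.bed"))
  write_reads_bed(study$input, fp("input.bed"))
  ex <- study$expression
  write.table(data.frame(probe_id = rownames(ex$log2_mat), ex$log2_mat,
                         check.names = FALSE),
              fp("expr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(probe_id = rownames(ex$calls), ex$calls,
                         check.names = FALSE),
              fp("calls.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(ex$log2_mat),
                         group = ex$groups),
              fp("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ex$probe_map, fp("probes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(study$ct))
    write.table(study$ct, fp("ct.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed, genes = study$truth$genes),
    fp("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
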