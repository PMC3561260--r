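## Window-level quantification of ChIP and input read density.
##
## MeCP2 binding in astrocytes is diffuse; instead of peak calling,
## read density is summarized per gene window as RPKM, the input RPKM
## is subtracted, and the top decile per window is called bound.

#' Construct a read library
#'
#' @param reads data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`; one row per aligned single-end read.
#' @param label Library label, e.g. `"chip"` or `"input"`.
#' @param total_mapped Total mapped reads N used as the RPKM
#'   denominator. Defaults to `nrow(reads)`; may be larger when the
#'   supplied reads are a subset of the library.
#' @return A `read_library` object.
#' @export
read_library <- function(reads, label = "chip", total_mapped = NULL) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads) && any(reads$start >= reads$end))
    stop("read(s) with start >= end")
  if (is.null(total_mapped)) total_mapped <- nrow(reads)
  if (total_mapped < nrow(reads))
    stop("total_mapped (", total_mapped, ") smaller than number of reads (",
         nrow(reads), ")")
  structure(list(label = label, reads = reads,
                 total_mapped = as.numeric(total_mapped)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat("read_library '", x$label, "': ", nrow(x$reads), " reads, N = ",
      format(x$total_mapped, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Load aligned reads from BED6 or BAM
#'
#' @param path Read file.
#' @param format `"bed"` or `"bam"`; default from the extension.
#' @param label,total_mapped Passed to [read_library()].
#' @param min_mapq Optional minimum mapping quality (BAM only; default
#'   no filter, matching an alignment policy that retains non-unique
#'   reads).
#' @return A `read_library`.
#' @export
load_reads <- function(path, format = NULL, label = "chip",
                       total_mapped = NULL, min_mapq = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    reads <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
    reads$strand[!reads$strand %in% c("+", "-")] <- "+"
  } else if (format == "bam") {
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
      what = c("rname", "pos", "qwidth", "strand", "mapq"))
    b <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(b$pos)
    if (!is.null(min_mapq)) keep <- keep & !is.na(b$mapq) & b$mapq >= min_mapq
    reads <- data.frame(chrom = as.character(b$rname)[keep],
                        start = b$pos[keep] - 1L,
                        end = b$pos[keep] - 1L + b$qwidth[keep],
                        strand = as.character(b$strand)[keep],
                        stringsAsFactors = FALSE)
  } else stop("unknown read format: ", format)
  read_library(reads, label = label, total_mapped = total_mapped)
}

## Strand-aware extension from the 5' end to `ext` bp; ext = 0 means no
## extension. Returns the reads data.frame with updated start/end.
extend_reads <- function(reads, ext) {
  if (ext == 0 || nrow(reads) == 0) return(reads)
  w <- reads$end - reads$start
  if (any(w > ext))
    stop("fragment_extension_bp (", ext, ") shorter than read length (max ",
         max(w), "); use 0 for no extension")
  plus <- reads$strand == "+"
  reads$end[plus] <- reads$start[plus] + ext
  reads$start[!plus] <- reads$end[!plus] - ext
  reads
}

#' Count reads in gene windows
#'
#' Each read is optionally extended from its 5' end to the expected
#' fragment length (sonication yields roughly 200-400 bp fragments; the
#' default extension is the 200 bp lower bound), then assigned to a
#' window either by the midpoint of the extended fragment (default; at
#' most one position per read) or by any 1-bp overlap. Windows of
#' different genes (or of one short gene) may overlap, so a read may
#' count toward several windows.
#'
#' @param lib A [read_library()].
#' @param windows Window table from [derive_windows()].
#' @param fragment_extension_bp Extension length in bp, `0` for none.
#'   Must be at least the read length when nonzero.
#' @param assignment `"midpoint"` or `"any_overlap"`.
#' @return `windows` with a `count` column appended (zero-length
#'   windows get count 0).
#' @export
count_reads_in_windows <- function(lib, windows,
                                   fragment_extension_bp = 200,
                                   assignment = c("midpoint", "any_overlap")) {
  assignment <- match.arg(assignment)
  stopifnot(inherits(lib, "read_library"), fragment_extension_bp >= 0)
  reads <- lib$reads
  win_chroms <- unique(windows$chrom)
  orphan <- setdiff(unique(reads$chrom), win_chroms)
  if (length(orphan))
    message("reads on chromosome(s) outside the window set contribute ",
            "only to total_mapped: ", paste(orphan, collapse = ", "))

  ok <- windows$length > 0
  counts <- numeric(nrow(windows))
  if (nrow(reads) && any(ok)) {
    reads <- reads[reads$chrom %in% win_chroms, , drop = FALSE]
    if (nrow(reads)) {
      ext <- extend_reads(reads, fragment_extension_bp)
      if (assignment == "midpoint") {
        mid <- floor((ext$start + ext$end) / 2)  # 0-based position
        qgr <- GenomicRanges::GRanges(ext$chrom,
                                      IRanges::IRanges(mid + 1, width = 1))
      } else {
        qgr <- GenomicRanges::GRanges(ext$chrom,
                                      IRanges::IRanges(ext$start + 1, ext$end))
      }
      wgr <- GenomicRanges::GRanges(
        windows$chrom[ok],
        IRanges::IRanges(windows$start[ok] + 1, windows$end[ok]))
      counts[ok] <- GenomicRanges::countOverlaps(wgr, qgr)
    }
  }
  windows$count <- counts
  windows
}

#' Reads per kilobase of element per million mapped reads
#'
#' `rpkm = C / ((L / 1000) * (N / 1e6)) = 1e9 * C / (L * N)`.
#'
#' @param count Read count C (vectorized).
#' @param window_length_bp Element length L in bp.
#' @param total_mapped Library total N.
#' @return RPKM values.
#' @export
compute_rpkm <- function(count, window_length_bp, total_mapped) {
  if (any(window_length_bp <= 0)) stop("window length must be positive")
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive")
  if (any(count < 0)) stop("counts must be nonnegative")
  # doubles throughout: L * N overflows 32-bit integers at real depths
  1e9 * as.numeric(count) /
    (as.numeric(window_length_bp) * as.numeric(total_mapped))
}

#' Subtract input RPKM from ChIP RPKM
#'
#' Removes genomic sequencing bias; scores may be negative where input
#' density exceeds ChIP density.
#'
#' @param chip_q,input_q Quantification tables carrying `gene_id`,
#'   `window` and `rpkm`, computed over identical window sets.
#' @return data.frame `gene_id`, `window`, `score`.
#' @export
subtract_input <- function(chip_q, input_q) {
  key_c <- paste(chip_q$gene_id, chip_q$window)
  key_i <- paste(input_q$gene_id, input_q$window)
  only_c <- setdiff(key_c, key_i); only_i <- setdiff(key_i, key_c)
  if (length(only_c) || length(only_i))
    stop("chip/input window sets differ: ",
         paste(head(c(only_c, only_i), 10), collapse = ", "))
  m <- match(key_c, key_i)
  data.frame(gene_id = chip_q$gene_id, window = chip_q$window,
             score = chip_q$rpkm - input_q$rpkm[m],
             stringsAsFactors = FALSE)
}

## ceiling with a guard against double-precision artifacts
## (0.1 * G can land one ulp above G/10).
ceil_frac <- function(fraction, n) {
  x <- fraction * n
  if (abs(x - round(x)) < 1e-9) round(x) else ceiling(x)
}

#' Rank genes by score and flag the top fraction
#'
#' Genes are sorted by score descending with ties broken by ascending
#' `gene_id` (C-locale, stable); the top set holds the first
#' `ceiling(fraction * G)` genes of the G rankable genes.
#'
#' @param scores Numeric scores named by gene, or a vector with
#'   `gene_ids` supplied separately. `NA` scores are unrankable and
#'   excluded.
#' @param gene_ids Gene identifiers matching `scores`.
#' @param fraction Top fraction in (0, 1]; default 0.10.
#' @return data.frame `gene_id`, `score`, `rank`, `top` sorted by rank;
#'   unrankable genes appear last with `rank = NA`, `top = FALSE`.
#' @export
rank_top_decile <- function(scores, gene_ids = names(scores),
                            fraction = 0.10) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  stopifnot(length(scores) == length(gene_ids))
  ok <- !is.na(scores)
  g <- sum(ok)
  if (g < 10)
    warning("only ", g, " rankable genes; decile calling is unstable")
  ord <- order(-scores[ok], gene_ids[ok], method = "radix")
  n_top <- if (g > 0) ceil_frac(fraction, g) else 0
  ranked <- data.frame(gene_id = gene_ids[ok][ord], score = scores[ok][ord],
                       rank = seq_len(g), top = seq_len(g) <= n_top,
                       stringsAsFactors = FALSE)
  if (any(!ok)) {
    ranked <- rbind(ranked,
                    data.frame(gene_id = gene_ids[!ok], score = NA_real_,
                               rank = NA_integer_, top = FALSE,
                               stringsAsFactors = FALSE))
  }
  rownames(ranked) <- NULL
  ranked
}

#' Quantify ChIP and input libraries over gene windows
#'
#' Runs the full window-level pipeline: count reads per window in both
#' libraries, convert to RPKM, subtract input from ChIP, and rank each
#' window's genes, flagging the top fraction.
#'
#' @inheritParams count_reads_in_windows
#' @param chip,input [read_library()] objects.
#' @param fraction Top fraction per window (default 0.10).
#' @return data.frame with one row per gene x window: counts, RPKMs,
#'   input-subtracted `score`, within-window `rank` and `top` flag.
#'   Genes whose window was fully clipped carry `NA` rank.
#' @export
quantify_windows <- function(chip, input, windows,
                             fragment_extension_bp = 200,
                             assignment = c("midpoint", "any_overlap"),
                             fraction = 0.10) {
  assignment <- match.arg(assignment)
  cq <- count_reads_in_windows(chip, windows, fragment_extension_bp,
                               assignment)
  iq <- count_reads_in_windows(input, windows, fragment_extension_bp,
                               assignment)
  res <- windows[, c("gene_id", "window", "chrom", "start", "end", "length")]
  res$count_chip <- cq$count
  res$count_input <- iq$count
  res$rpkm_chip <- res$rpkm_input <- NA_real_
  ok <- res$length > 0
  res$rpkm_chip[ok] <- compute_rpkm(res$count_chip[ok], res$length[ok],
                                    chip$total_mapped)
  res$rpkm_input[ok] <- compute_rpkm(res$count_input[ok], res$length[ok],
                                     input$total_mapped)
  res$score <- res$rpkm_chip - res$rpkm_input
  res$rank <- NA_integer_
  res$top <- FALSE
  for (w in unique(res$window)) {
    sel <- res$window == w
    rk <- rank_top_decile(res$score[sel], res$gene_id[sel], fraction)
    m <- match(res$gene_id[sel], rk$gene_id)
    res$rank[sel] <- rk$rank[m]
    res$top[sel] <- rk$top[m]
  }
  res
}

#' Top-decile gene sets per window
#'
#' @param quantification Output of [quantify_windows()].
#' @return Named list of character vectors (`tss`, `body`, `tes`),
#'   each ordered by descending score.
#' @export
top_gene_sets <- function(quantification) {
  out <- lapply(split(quantification, quantification$window), function(d) {
    d <- d[d$top, ]
    d$gene_id[order(-d$score, d$gene_id, method = "radix")]
  })
  out[intersect(c("tss", "body", "tes"), names(out))]
}

#' Export a binned coverage track as bedGraph
#'
#' Reads are extended to fragment length and per-base coverage is
#' averaged over fixed bins; bins with zero coverage are omitted. Track
#' values are read-count depth (not RPKM), suitable for genome-browser
#' display of diffuse binding domains.
#'
#' @param lib A [read_library()].
#' @param path Output bedGraph path.
#' @param bin_size_bp Bin width (default 50).
#' @param fragment_extension_bp Extension length, `0` for none.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(lib, path, bin_size_bp = 50,
                            fragment_extension_bp = 200) {
  stopifnot(bin_size_bp >= 1)
  reads <- extend_reads(lib$reads, fragment_extension_bp)
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start + 1, reads$end))
  cov <- GenomicRanges::coverage(gr)
  pieces <- lapply(names(cov), function(chr) {
    rle <- cov[[chr]]
    n_bins <- ceiling(length(rle) / bin_size_bp)
    starts <- (seq_len(n_bins) - 1) * bin_size_bp + 1
    ends <- pmin(starts + bin_size_bp - 1, length(rle))
    v <- IRanges::Views(rle, start = starts, end = ends)
    means <- IRanges::viewMeans(v)
    keep <- means > 0
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts[keep], ends[keep]),
                           score = unname(means[keep]))
  })
  track <- do.call(c, pieces[!vapply(pieces, is.null, logical(1))])
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}
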