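## Gene models and the three analysis windows.
##
## A gene model is one genomic span per gene (exons and introns alike);
## no transcript structure is kept because the gene body is defined as
## the full TSS->TES span.

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV (chromosome name, length in bp), no header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  if (any(df$length <= 0) || anyNA(df$length))
    stop("chromosome lengths must be positive")
  if (anyDuplicated(df$chrom))
    stop("duplicate chromosome names in sizes file")
  setNames(as.numeric(df$length), df$chrom)
}

validate_gene_models <- function(genes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene model table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(genes$start >= genes$end))
    stop("gene(s) with start >= end: ",
         paste(genes$gene_id[genes$start >= genes$end], collapse = ", "))
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("missing or invalid strand for gene(s): ",
         paste(genes$gene_id[bad_strand], collapse = ", "))
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  invisible(genes)
}

#' Load gene models from GTF or BED
#'
#' GTF `gene` feature lines (1-based closed) or BED6 records (already
#' 0-based half-open) are converted to one single-span gene model per
#' record. Exon/transcript lines in a GTF are ignored: the gene body is
#' the full genomic span. Duplicate gene identifiers and records without
#' a strand are rejected.
#'
#' @param path Annotation file.
#' @param format `"GTF"` or `"BED"` (case-insensitive). Defaults from the
#'   file extension.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
load_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GTF"
  }
  format <- toupper(format)
  gr <- tryCatch(
    switch(format,
      GTF = rtracklayer::import(path, format = "gtf"),
      BED = rtracklayer::import(path, format = "bed"),
      stop("unknown annotation format: ", format)
    ),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  if (format == "GTF") {
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
    if (is.null(ids)) stop("GTF records carry no gene_id attribute")
  } else {
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids)) stop("BED records carry no name field")
  }
  genes <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_gene_models(genes)
  genes
}

#' Derive the three analysis windows for each gene
#'
#' For a gene on the + strand with span `[s, e)` the windows are
#' TSS `[s - flank, s + flank)`, body `[s, e)` and TES `[e - flank,
#' e + flank)`; on the - strand the TSS sits at `e` and the TES at `s`,
#' with the flanking windows mirrored. With
#' `geometry = "upstream_only"` the TSS window covers only the `flank_bp`
#' bases upstream of the TSS and the TES window only the `flank_bp`
#' bases downstream of the TES. All windows are clipped to the
#' chromosome; a window clipped to zero length is kept in the table with
#' `length = 0` (and a warning) so downstream ranking can exclude it.
#'
#' @param genes Gene-model data.frame (see [load_gene_models()]).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param flank_bp Flank size in bp (default 2000).
#' @param geometry `"symmetric"` (default, +/- flank) or
#'   `"upstream_only"`.
#' @return Long-format data.frame: `gene_id`, `window` (tss/body/tes),
#'   `chrom`, `start`, `end`, `length`, `strand`.
#' @export
derive_windows <- function(genes, chrom_sizes, flank_bp = 2000,
                           geometry = c("symmetric", "upstream_only")) {
  geometry <- match.arg(geometry)
  validate_gene_models(genes)
  stopifnot(is.numeric(flank_bp), length(flank_bp) == 1, flank_bp > 0)
  absent <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(absent))
    stop("chromosome(s) absent from sizes: ", paste(absent, collapse = ", "))

  plus <- genes$strand == "+"
  tss_pos <- ifelse(plus, genes$start, genes$end)
  tes_pos <- ifelse(plus, genes$end, genes$start)

  if (geometry == "symmetric") {
    tss_s <- tss_pos - flank_bp; tss_e <- tss_pos + flank_bp
    tes_s <- tes_pos - flank_bp; tes_e <- tes_pos + flank_bp
  } else {
    # upstream of TSS / downstream of TES, strand-aware
    tss_s <- ifelse(plus, tss_pos - flank_bp, tss_pos)
    tss_e <- ifelse(plus, tss_pos, tss_pos + flank_bp)
    tes_s <- ifelse(plus, tes_pos, tes_pos - flank_bp)
    tes_e <- ifelse(plus, tes_pos + flank_bp, tes_pos)
  }

  one <- function(win, s, e) {
    lim <- unname(chrom_sizes[genes$chrom])
    s <- pmax(s, 0); e <- pmin(e, lim)
    len <- pmax(e - s, 0)
    data.frame(gene_id = genes$gene_id, window = win, chrom = genes$chrom,
               start = ifelse(len > 0, s, NA_real_),
               end = ifelse(len > 0, e, NA_real_),
               length = len, strand = genes$strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("tss", tss_s, tss_e),
               one("body", genes$start, genes$end),
               one("tes", tes_s, tes_e))
  # preserve input gene order, windows nested per gene
  out <- out[order(match(out$gene_id, genes$gene_id),
                   match(out$window, c("tss", "body", "tes"))), ]
  rownames(out) <- NULL
  if (any(out$length == 0)) {
    z <- out[out$length == 0, ]
    warning(nrow(z), " window(s) fully clipped at a chromosome boundary ",
            "(excluded from ranking): ",
            paste(paste0(z$gene_id, ":", z$window), collapse = ", "))
  }
  out
}

#' Export windows as BED6
#'
#' One record per window, named `<gene_id>:<tss|body|tes>`. Zero-length
#' (fully clipped) windows are skipped.
#'
#' @param windows Output of [derive_windows()].
#' @param path Output BED path.
#' @export
export_windows_bed <- function(windows, path) {
  w <- windows[windows$length > 0, ]
  gr <- GenomicRanges::GRanges(
    w$chrom, IRanges::IRanges(w$start + 1L, w$end), strand = w$strand,
    name = paste0(w$gene_id, ":", w$window), score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
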