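# Independent oracles and tiny fixtures, deliberately naive:
# per-read/per-window double loops and definition-level BH, never the
# package's own code paths.

toy_genes <- function() {
  data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 10000, 500),
    end = c(20000, 20000, 3000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
}

toy_sizes <- c(chr1 = 50000, chr2 = 40000)

# Brute-force read counting: extend each read strand-aware from its 5'
# end, then test each (read, window) pair individually.
oracle_counts <- function(reads, windows, ext, assignment) {
  counts <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (w$length == 0) next
    for (j in seq_len(nrow(reads))) {
      r <- reads[j, ]
      if (r$chrom != w$chrom) next
      s <- r$start; e <- r$end
      if (ext > 0) {
        if (r$strand == "+") e <- s + ext else s <- e - ext
      }
      hit <- if (assignment == "midpoint") {
        mid <- floor((s + e) / 2)
        mid >= w$start && mid < w$end
      } else {
        max(s, w$start) < min(e, w$end)
      }
      if (hit) counts[i] <- counts[i] + 1
    }
  }
  counts
}

random_count_instance <- function() {
  n_reads <- sample(0:50, 1)
  n_win <- sample(1:5, 1)
  chroms <- c("chr1", "chr2")
  reads <- data.frame(
    chrom = sample(chroms, n_reads, replace = TRUE),
    start = sample(0:5000, n_reads, replace = TRUE),
    strand = sample(c("+", "-"), n_reads, replace = TRUE),
    stringsAsFactors = FALSE)
  reads$end <- reads$start + sample(20:76, max(n_reads, 1),
                                    replace = TRUE)[seq_len(n_reads)]
  ws <- sample(0:4000, n_win, replace = TRUE)
  windows <- data.frame(
    gene_id = paste0("g", seq_len(n_win)),
    window = sample(c("tss", "body", "tes"), n_win, replace = TRUE),
    chrom = sample(chroms, n_win, replace = TRUE),
    start = ws, end = ws + sample(100:3000, n_win, replace = TRUE),
    strand = "+", stringsAsFactors = FALSE)
  windows$length <- windows$end - windows$start
  list(reads = reads, windows = windows,
       ext = sample(c(0, 100, 200), 1))
}

# Definition-level BH step-up: q for the i-th smallest p is
# min over j >= i of p_(j) * n / j.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    q[o[i]] <- min(1, cand)
  }
  q
}

# Small planted expression matrix without going through the generator.
tiny_log2_matrix <- function(n_probes = 20, effect_probes = integer(0),
                             effect = 0.6, sd = 0.1) {
  groups <- rep(c("WT", "KO"), each = 3)
  m <- matrix(rnorm(n_probes * 6, 8, sd), nrow = n_probes,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              paste0(groups, "_", rep(1:3, 2))))
  m[effect_probes, groups == "KO"] <-
    m[effect_probes, groups == "KO"] + effect
  list(mat = m, groups = groups)
}
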