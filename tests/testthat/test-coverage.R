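test_that("window counting matches the brute-force double loop", {
  set.seed(42)
  for (i in 1:60) {
    inst <- random_count_instance()
    lib <- read_library(inst$reads)
    for (policy in c("midpoint", "any_overlap")) {
      got <- suppressMessages(
        count_reads_in_windows(lib, inst$windows, inst$ext, policy))
      want <- oracle_counts(inst$reads, inst$windows, inst$ext, policy)
      expect_equal(got$count, want,
                   info = paste("instance", i, policy, "ext", inst$ext))
    }
  }
})

test_that("midpoint assignment follows the worked extension example", {
  w <- derive_windows(toy_genes()[1, ], toy_sizes)
  # read [8990,9066)+ extends to [8990,9190), midpoint 9090: in the TSS
  # window only
  r <- data.frame(chrom = "chr1", start = 8990, end = 9066, strand = "+",
                  stringsAsFactors = FALSE)
  got <- count_reads_in_windows(read_library(r), w, 200, "midpoint")
  expect_equal(got$count[got$window == "tss"], 1)
  expect_equal(sum(got$count), 1)
})

test_that("half-open convention excludes a midpoint at the window end", {
  w <- derive_windows(toy_genes()[1, ], toy_sizes)
  # unextended read with midpoint exactly 12000 = TSS window end
  r <- data.frame(chrom = "chr1", start = 11999, end = 12002,
                  strand = "+", stringsAsFactors = FALSE)
  got <- count_reads_in_windows(read_library(r), w, 0, "midpoint")
  expect_equal(got$count[got$window == "tss"], 0)
})

test_that("empty libraries and off-annotation reads count nothing", {
  w <- derive_windows(toy_genes(), toy_sizes)
  empty <- read_library(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), strand = character()))
  expect_equal(sum(count_reads_in_windows(empty, w)$count), 0)
  stray <- read_library(data.frame(chrom = "chrX", start = 100, end = 176,
                                   strand = "+"))
  expect_message(got <- count_reads_in_windows(stray, w), "chrX")
  expect_equal(sum(got$count), 0)
  expect_equal(stray$total_mapped, 1)
})

test_that("RPKM follows the closed form and its scaling laws", {
  expect_identical(compute_rpkm(100, 4000, 1e6), 25.0)
  expect_equal(compute_rpkm(0, 123, 456), 0)
  set.seed(1)
  C <- sample(1:1000, 20); L <- sample(100:5000, 20); N <- 1e6
  expect_equal(compute_rpkm(3 * C, L, N), 3 * compute_rpkm(C, L, N))
  expect_equal(compute_rpkm(C, L, 5 * N), compute_rpkm(C, L, N) / 5)
  expect_equal(compute_rpkm(2 * C, L, 2 * N), compute_rpkm(C, L, N))
  expect_error(compute_rpkm(10, 0, 1e6), "length")
  expect_error(compute_rpkm(10, 100, 0), "mapped")
})

test_that("input subtraction is exact and rejects mismatched gene sets", {
  q1 <- data.frame(gene_id = c("a", "b"), window = "tss",
                   rpkm = c(25, 5), stringsAsFactors = FALSE)
  q2 <- data.frame(gene_id = c("a", "b"), window = "tss",
                   rpkm = c(10, 9), stringsAsFactors = FALSE)
  s <- subtract_input(q1, q2)
  expect_equal(s$score, c(15, -4))  # negative scores permitted
  expect_equal(subtract_input(q1, q1)$score, c(0, 0))
  q3 <- q2; q3$gene_id <- c("a", "zz")
  expect_error(subtract_input(q1, q3), "zz")
})

test_that("top-fraction calling uses the ceiling rule and gene_id tie-break", {
  ids <- sprintf("g%03d", 1:105)
  set.seed(3)
  r <- rank_top_decile(setNames(rnorm(105), ids), fraction = 0.10)
  expect_equal(sum(r$top), 11)                   # ceil(10.5)
  r100 <- rank_top_decile(setNames(rnorm(100), ids[1:100]))
  expect_equal(sum(r100$top), 10)                # exactly G/10
  ties <- rank_top_decile(setNames(rep(1, 100), sample(ids[1:100])))
  expect_equal(ties$gene_id[ties$top], sort(ids[1:100])[1:10])
  expect_error(rank_top_decile(setNames(rnorm(20), ids[1:20]),
                               fraction = 0), "fraction")
  expect_error(rank_top_decile(setNames(rnorm(20), ids[1:20]),
                               fraction = 1.5), "fraction")
  # NA scores are unrankable: G shrinks, flagged last with NA rank
  sc <- setNames(c(rnorm(98), NA, NA), ids[1:100])
  rna <- rank_top_decile(sc)
  expect_equal(sum(rna$top), 10)                 # ceil(0.1 * 98)
  expect_true(all(is.na(rna$rank[rna$gene_id %in% ids[99:100]])))
})

test_that("identical chip and input yield all-zero scores and tie-break decile", {
  set.seed(9)
  gen <- simulate_genome(n_genes = 40, n_chroms = 2, seed = 9)
  w <- derive_windows(gen$genes, gen$chrom_sizes)
  tr <- simulate_truth(gen$genes, c(tss = 0), n_de_enriched = 0, seed = 9)
  lib <- simulate_chip_reads(w, gen$chrom_sizes, tr, seed = 9)$input
  q <- quantify_windows(lib, lib, w)
  expect_true(all(q$score == 0))
  tss <- q[q$window == "tss", ]
  expect_equal(sort(tss$gene_id[tss$top]),
               sort(gen$genes$gene_id)[1:ceiling(0.1 * nrow(gen$genes))])
})

test_that("bedGraph export tiles extended reads into mean-depth bins", {
  # one 76 bp read extended to 200 bp spanning exactly two 100 bp bins
  r <- data.frame(chrom = "chr1", start = 9000, end = 9076, strand = "+",
                  stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".bedGraph")
  export_bedgraph(read_library(r), out, bin_size_bp = 100,
                  fragment_extension_bp = 200)
  tr <- read.table(out, col.names = c("chrom", "start", "end", "value"))
  expect_equal(nrow(tr), 2)
  expect_equal(tr$value, c(1, 1))
  expect_equal(tr$start, c(9000, 9100))

  # conservation: sum(value * bin width) equals summed extended lengths
  set.seed(11)
  r2 <- data.frame(chrom = "chr1",
                   start = sample(300:3000, 40, replace = TRUE),
                   strand = sample(c("+", "-"), 40, replace = TRUE),
                   stringsAsFactors = FALSE)
  r2$end <- r2$start + 76
  export_bedgraph(read_library(r2), out, bin_size_bp = 50,
                  fragment_extension_bp = 200)
  tr2 <- read.table(out, col.names = c("chrom", "start", "end", "value"))
  expect_equal(sum(tr2$value * (tr2$end - tr2$start)), 40 * 200)

  # empty library: empty track body
  empty <- read_library(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), strand = character()))
  export_bedgraph(empty, out)
  expect_equal(length(readLines(out)), 0)
})
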