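make_calls <- function(per_sample) {
  m <- do.call(rbind, per_sample)
  rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  m
}

test_that("detection prefilter requires >=2 detected in the target group", {
  groups <- rep(c("WT", "KO"), each = 3)
  calls <- make_calls(list(
    c("present", "present", "present", "present", "absent", "absent"),
    c("absent", "absent", "absent", "present", "marginal", "absent"),
    c("present", "present", "present", "absent", "absent", "absent")))
  colnames(calls) <- paste0(groups, "_", rep(1:3, 2))
  ko <- detection_prefilter(calls, groups, "KO")
  expect_equal(ko, "p02")  # marginal counts toward detection
  wt <- detection_prefilter(calls, groups, "WT")
  expect_equal(wt, c("p01", "p03"))
  all_present <- matrix("present", 3, 6,
                        dimnames = list(paste0("q", 1:3), colnames(calls)))
  expect_equal(detection_prefilter(all_present, groups, "KO"),
               paste0("q", 1:3))
  expect_error(detection_prefilter(calls, groups, "KO",
                                   min_detected = 4), "exceeds")
})

test_that("quantile_log2 equalizes sample distributions, degenerate cases aside", {
  m <- matrix(c(1, 2, 4, 8, 1, 2, 4, 8), ncol = 2,
              dimnames = list(paste0("p", 1:4), c("a", "b")))
  expect_equal(normalize_log2(m, "quantile_log2"), log2(m))
  set.seed(5)
  m2 <- matrix(rlnorm(200, 5, 1), ncol = 4,
               dimnames = list(paste0("p", 1:50), paste0("s", 1:4)))
  n2 <- normalize_log2(m2, "quantile_log2")
  expect_equal(diff(range(colMeans(n2))), 0, tolerance = 1e-10)
  # single probe: quantile step is degenerate, identity before log2
  one <- matrix(c(4, 16), 1, dimnames = list("p1", c("a", "b")))
  expect_equal(unname(normalize_log2(one, "quantile_log2")[1, ]), c(2, 4))
  expect_error(normalize_log2(-m, "quantile_log2"), "positive")
  expect_identical(normalize_log2(log2(m), "passthrough"), log2(m))
})

test_that("per-probe t statistics match stats::t.test", {
  set.seed(21)
  tl <- tiny_log2_matrix(30)
  de <- differential_expression(tl$mat, tl$groups)
  for (i in sample(30, 8)) {
    ref <- t.test(tl$mat[i, tl$groups == "KO"],
                  tl$mat[i, tl$groups == "WT"], var.equal = TRUE)
    expect_equal(de$t[i], unname(ref$statistic))
    expect_equal(de$p[i], ref$p.value)
  }
  # Welch variant against its own oracle
  dw <- differential_expression(tl$mat, tl$groups, var_equal = FALSE)
  ref <- t.test(tl$mat[3, tl$groups == "KO"],
                tl$mat[3, tl$groups == "WT"], var.equal = FALSE)
  expect_equal(dw$p[3], ref$p.value)
})

test_that("null probes fail and identical groups give p = 1, fold 1", {
  m <- matrix(rep(c(5.0, 5.1, 4.9), 2), nrow = 1, byrow = TRUE,
              dimnames = list("p1", NULL))
  m <- m[, c(1, 2, 3, 1, 2, 3), drop = FALSE]
  m[1, ] <- c(5.0, 5.1, 4.9, 5.0, 5.1, 4.9)
  colnames(m) <- paste0(rep(c("WT", "KO"), each = 3), 1:3)
  de <- differential_expression(m, rep(c("WT", "KO"), each = 3))
  expect_equal(de$p, 1)
  expect_equal(de$fold_change, 1)
  expect_false(de$passes)
})

test_that("fold-change gate is 2^|dlog2| and strictly exceeded", {
  # mean log2 shift of 0.30 -> fold 2^0.30 ~ 1.231 > 1.2
  m <- rbind(p1 = c(8, 8, 8, 8.3, 8.3, 8.3) + c(0, 1e-3, -1e-3) / 10)
  colnames(m) <- paste0(rep(c("WT", "KO"), each = 3), 1:3)
  de <- differential_expression(m, rep(c("WT", "KO"), each = 3))
  expect_equal(de$fold_change, 2^de$log2_fc)
  expect_gt(de$fold_change, 1.2)
  expect_equal(de$direction, "up_in_KO")
})

test_that("zero-variance probes are flagged untestable with a warning", {
  tl <- tiny_log2_matrix(5)
  tl$mat[2, ] <- 7  # constant in both groups
  expect_warning(de <- differential_expression(tl$mat, tl$groups),
                 "untestable")
  expect_false(de$testable[2])
  expect_false(de$passes[2])
  expect_true(is.na(de$p[2]))
})

test_that("BH q-values match the brute-force step-up on random short vectors", {
  p4 <- c(0.001, 0.02, 0.04, 0.9)
  expect_equal(p.adjust(p4, "BH"), c(0.004, 0.04, 0.04 * 4 / 3, 0.9))
  expect_equal(bh_brute_force(p4), p.adjust(p4, "BH"))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute_force(p))
  }
})

test_that("fdr mode adjusts within each direction-specific prefiltered list", {
  set.seed(33)
  tl <- tiny_log2_matrix(40, effect_probes = 1:6, effect = 1)
  probes <- rownames(tl$mat)
  ko_list <- probes[1:30]   # up-candidates tested here
  wt_list <- probes[11:40]
  de <- differential_expression(tl$mat, tl$groups, mode = "fdr",
                                ko_detected = ko_list,
                                wt_detected = wt_list)
  up <- de$direction == "up_in_KO" & de$probe_id %in% ko_list
  expect_equal(de$q[up],
               p.adjust(de$p[de$probe_id %in% ko_list], "BH")[
                 match(de$probe_id[up], de$probe_id[de$probe_id %in% ko_list])])
  # a probe outside its direction's list never passes
  outside <- de$direction == "up_in_KO" & !de$probe_id %in% ko_list
  expect_false(any(de$passes[outside]))
})

test_that("swapping group labels mirrors direction but keeps the pass set", {
  set.seed(14)
  tl <- tiny_log2_matrix(25, effect_probes = 1:5, effect = 0.8)
  de1 <- differential_expression(tl$mat, tl$groups)
  swapped <- ifelse(tl$groups == "WT", "KO", "WT")
  de2 <- differential_expression(tl$mat, swapped)
  expect_equal(de1$passes, de2$passes)
  expect_equal(de1$fold_change, de2$fold_change)
  pass <- de1$passes
  expect_true(all(de1$direction[pass] != de2$direction[pass]))
})

test_that("raising the fold cutoff never adds a passing probe", {
  set.seed(27)
  tl <- tiny_log2_matrix(60, effect_probes = 1:12, effect = 0.45)
  lo <- differential_expression(tl$mat, tl$groups, fc_cutoff = 1.2)
  hi <- differential_expression(tl$mat, tl$groups, fc_cutoff = 1.5)
  expect_true(all(hi$probe_id[hi$passes] %in% lo$probe_id[lo$passes]))
})

test_that("probe-to-gene collapse follows the any-probe rule", {
  de <- data.frame(
    probe_id = paste0("p", 1:5),
    fold_change = c(1.5, 1.3, 1.4, 1.6, 2.0),
    log2_fc = c(0.58, -0.38, 0.49, 0.68, 1.0),
    direction = c("up_in_KO", "down_in_KO", "up_in_KO", "up_in_KO",
                  "up_in_KO"),
    p = c(0.001, 0.002, 0.5, 0.004, 0.0005), q = NA_real_,
    passes = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  map <- data.frame(probe_id = paste0("p", 1:4),
                    gene_id = c("gA", "gA", "gA", "gB"),
                    stringsAsFactors = FALSE)
  out <- collapse_probes_to_genes(de, map)
  expect_equal(sort(out$genes$gene_id), c("gA", "gB"))
  gA <- out$genes[out$genes$gene_id == "gA", ]
  expect_equal(gA$probe_id, "p1")        # smallest-p passing probe
  expect_true(gA$discordant)             # p1 up, p2 down, both pass
  expect_equal(gA$n_probes_passing, 2)
  expect_equal(out$unannotated, "p5")
  none <- collapse_probes_to_genes(de[!de$passes, , drop = FALSE], map)
  expect_equal(nrow(none$genes), 0)
})

test_that("many probes collapse onto fewer genes as on a real array", {
  set.seed(99)
  # 142 passing probes spread over 118 genes (24 genes with two probes)
  genes <- sprintf("gene%03d", 1:118)
  map <- data.frame(
    probe_id = sprintf("pr%03d", 1:142),
    gene_id = c(genes, genes[1:24]),
    stringsAsFactors = FALSE)
  de <- data.frame(probe_id = map$probe_id, fold_change = 1.5,
                   log2_fc = 0.58, direction = "up_in_KO",
                   p = runif(142, 0, 0.004), q = NA_real_, passes = TRUE,
                   stringsAsFactors = FALSE)
  out <- collapse_probes_to_genes(de, map)
  expect_equal(nrow(out$genes), 118)
})
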