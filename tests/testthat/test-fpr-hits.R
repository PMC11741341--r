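make_test_table <- function(ids, logfc, p_adj = rep(0.01, length(ids))) {
  data.frame(protein_id = ids, logFC = logfc, p_adj = p_adj,
             stringsAsFactors = FALSE)
}

test_that("control annotation maps identifiers and resolves ambiguity", {
  ann <- annotate_controls(c("a", "b", "c", "d"), pc_list = c("a", "b"),
                           nc_list = "c")
  expect_equal(ann$label, c("PC", "PC", "NC", "none"))
  expect_equal(attr(ann, "n_ambiguous"), 0L)
  # case-normalized matching
  ann2 <- annotate_controls(c("Sod3", "GEL"), pc_list = "sod3",
                            nc_list = "gel")
  expect_equal(ann2$label, c("PC", "NC"))
  # gene in both lists is labeled none and counted
  amb <- annotate_controls(c("x", "y"), pc_list = c("x", "y"),
                           nc_list = "x")
  expect_equal(amb$label, c("none", "PC"))
  expect_equal(attr(amb, "n_ambiguous"), 1L)
})

test_that("perfectly separated controls calibrate at the first clean control value", {
  tab <- make_test_table(letters[1:5], c(2, 3, 4, 0, 1))
  ann <- annotate_controls(letters[1:5], pc_list = c("a", "b", "c"),
                           nc_list = c("d", "e"))
  fc <- fpr_curve(tab, ann, target_fpr = 0.10)
  # at the top NC value the rate is 1/4; above it the rate drops to 0
  expect_equal(fc$curve$fpr[fc$curve$threshold == 1], 0.25)
  expect_equal(fc$curve$fpr[fc$curve$threshold == 2], 0)
  # candidate thresholds are the observed control ratios, so the
  # calibrated value is the smallest PC ratio above the NC block
  expect_equal(fc$threshold, 2)
  expect_gt(fc$threshold, 1)  # the NC at 1 stays below the cut
})

test_that("curve and calibrated threshold match the exhaustive-sweep oracle", {
  pc <- as.numeric(1:9)
  nc <- c(2, 4)
  ids <- sprintf("g%02d", seq_along(c(pc, nc)))
  tab <- make_test_table(ids, c(pc, nc))
  ann <- annotate_controls(ids, pc_list = ids[1:9], nc_list = ids[10:11])
  fc <- fpr_curve(tab, ann, target_fpr = 0.10)
  expect_equal(fc$threshold, oracle_fpr_threshold(pc, nc, 0.10))
  # the full curve agrees point by point
  for (i in seq_len(nrow(fc$curve))) {
    t <- fc$curve$threshold[i]
    np <- sum(pc >= t); nn <- sum(nc >= t)
    expect_equal(fc$curve$n_pc_above[i], np)
    expect_equal(fc$curve$n_nc_above[i], nn)
    expect_equal(fc$curve$fpr[i], if (np + nn == 0) 0 else nn / (np + nn))
  }

  set.seed(20)
  for (i in 1:100) {
    pc <- round(rnorm(sample(3:40, 1), 1), 2)
    nc <- round(rnorm(sample(3:40, 1), 0), 2)
    ids <- sprintf("g%03d", seq_along(c(pc, nc)))
    tab <- make_test_table(ids, c(pc, nc))
    ann <- annotate_controls(ids, ids[seq_along(pc)],
                             ids[length(pc) + seq_along(nc)])
    target <- runif(1, 0.05, 0.4)
    fc <- fpr_curve(tab, ann, target_fpr = target)
    expect_identical(fc$threshold,
                     oracle_fpr_threshold(pc, nc, target))
  }
})

test_that("at the lowest threshold every control is counted", {
  sim <- simulate_experiment(sim_config(n_proteins = 800, frac_enriched = 0,
                                        seed = 21))
  f <- filter_proteins(correct_impurities(sim$reporter, sim$impurity))
  tt <- moderated_t(log2_channel_matrix(f), sim$design, c("YkiBirA", "Ctrl"))
  lists <- simulate_control_lists(sim$truth)
  ann <- annotate_controls(tt$protein_id, lists$pc, lists$nc)
  fc <- fpr_curve(tt, ann)
  base <- fc$curve[fc$curve$threshold == -Inf, ]
  n_pc <- sum(ann$label == "PC")
  n_nc <- sum(ann$label == "NC")
  expect_equal(base$n_pc_above, n_pc)
  expect_equal(base$n_nc_above, n_nc)
  expect_equal(base$fpr, n_nc / (n_nc + n_pc))
})

test_that("calibration requires both control classes and a sane target", {
  tab <- make_test_table(c("a", "b"), c(1, 2))
  ann <- annotate_controls(c("a", "b"), pc_list = c("a", "b"),
                           nc_list = character(0))
  expect_error(fpr_curve(tab, ann), "at least one PC and one NC")
  expect_error(fpr_curve(tab, ann, target_fpr = 0), "target_fpr")
})

test_that("lowering the target FPR never lowers the threshold", {
  set.seed(22)
  ids <- sprintf("g%03d", 1:60)
  tab <- make_test_table(ids, c(rnorm(40, 1.5), rnorm(20)))
  ann <- annotate_controls(ids, ids[1:40], ids[41:60])
  thr <- vapply(c(0.30, 0.20, 0.10, 0.05), function(tf) {
    fpr_curve(tab, ann, target_fpr = tf)$threshold
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("hit calling applies both criteria in the stated order", {
  tab <- make_test_table(
    paste0("p", 1:5),
    logfc = c(3, 2, 1.5, 0.5, -2),
    p_adj = c(0.01, 0.2, 0.01, 0.001, 0.0001)
  )
  ht <- call_hits(tab, threshold = 1.0, alpha = 0.05)
  expect_equal(hit_ids(ht), c("p1", "p3"))
  expect_equal(ht$protein_id, paste0("p", 1:5))  # sorted by logFC desc
  expect_true(all(ht$hit == (ht$pass_p_adj & ht$pass_ratio)))
  # alpha = 0 empties the hit set; threshold -Inf + alpha 1 selects all
  expect_length(hit_ids(call_hits(tab, 1.0, alpha = 0)), 0)
  expect_length(hit_ids(call_hits(tab, -Inf, alpha = 1)), 5)
  # logFC ties break by protein id ascending
  tie <- make_test_table(c("z", "a"), c(2, 2), c(0.01, 0.01))
  expect_equal(hit_ids(call_hits(tie, 0)), c("a", "z"))
})

test_that("raising the threshold or lowering alpha never adds hits", {
  set.seed(23)
  tab <- make_test_table(sprintf("g%03d", 1:200), rnorm(200, 0.5),
                         runif(200))
  for (i in 1:200) {
    t1 <- runif(1, -1, 2); t2 <- t1 + runif(1, 0, 1)
    a2 <- runif(1, 0, 1); a1 <- a2 + runif(1, 0, 1 - a2)
    big <- hit_ids(call_hits(tab, t1, alpha = a1))
    small <- hit_ids(call_hits(tab, t2, alpha = a2))
    expect_true(all(small %in% big))
  }
})

test_that("overlap summaries follow set arithmetic", {
  same <- overlap_summary(c("a", "b"), c("a", "b"))
  expect_equal(same$jaccard, 1.0)
  expect_equal(same$pct_of_smaller, 1.0)
  disj <- overlap_summary(c("a", "b"), c("c", "d"))
  expect_equal(disj$n_shared, 0)
  expect_equal(disj$jaccard, 0)
  ab <- overlap_summary(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(ab$n_shared, 2)
  expect_equal(ab$jaccard, 2 / 5)
  expect_equal(ab$pct_of_smaller, 2 / 3)
  empty <- overlap_summary(character(0), c("a"))
  expect_equal(empty$pct_of_smaller, 0)
})

test_that("top-k composition counts categories over the leading hits", {
  cats <- setNames(c(rep("inflammatory", 4), rep("metabolic", 3)),
                   paste0("p", 1:7))
  hits <- paste0("p", 1:10)  # p8-p10 uncategorized
  comp <- top_k_composition(hits, cats, k = 10)
  expect_equal(comp[["inflammatory"]], 0.4)
  expect_equal(comp[["other"]], 0.3)
  expect_equal(sum(comp), 1)
  # k beyond the hit count truncates to all hits
  comp5 <- top_k_composition(paste0("p", 1:3), cats, k = 100)
  expect_equal(comp5[["inflammatory"]], 1)
  # single shared category
  expect_equal(top_k_composition(paste0("p", 1:4), cats, k = 4)[["inflammatory"]], 1)
  expect_error(top_k_composition(hits, cats, k = 0), "k")
})
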