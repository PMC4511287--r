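test_that("critical t values match the Student quantiles", {
  expect_equal(round(critical_t(22, 0.01), 3), 2.819)
  expect_equal(critical_t(1e6, 0.05), 1.960, tolerance = 0.001)
  expect_equal(critical_t(10, 1), 0)
  expect_equal(critical_t(15, 0.05, tails = 1), qt(0.95, 15))
})

test_that("t histograms count, clip and conserve correctly", {
  zero <- stat_map(array(0, c(4, 4, 4)), kind = "t", df = 10)
  h <- tvalue_histogram(zero)
  expect_equal(h$count[h$bin_lo == 0], 64)
  expect_equal(sum(h$count), 64)

  set.seed(2)
  v <- rnorm(500, sd = 4)  # plenty outside [-6, 6]
  hc <- tvalue_histogram(v)
  expect_equal(sum(hc$count), 500)
  hd <- tvalue_histogram(v, clip = FALSE)
  expect_equal(sum(hd$count), 500 - attr(hd, "dropped"))
  expect_gt(attr(hd, "dropped"), 0)

  # direct counting oracle
  edges <- -6:6
  oracle <- vapply(seq_len(12), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    sum(if (b == 1) v < hi else if (b == 12) v >= lo else v >= lo & v < hi)
  }, numeric(1))
  expect_equal(hc$count, as.integer(oracle))

  expect_error(tvalue_histogram(numeric(0)), "empty")
  expect_error(tvalue_histogram(v, edges = c(0, 0, 1)), "increasing")
})

test_that("within-subject SEMs follow the Cousineau-Morey recipe", {
  # pure additive structure: subject offset + condition effect
  subj_off <- c(0, 3, -2, 5)
  cond_eff <- c(A = 1, B = -1)
  hists <- expand.grid(subject = paste0("s", 1:4), condition = c("A", "B"),
                       bin_mid = c(-0.5, 0.5), stringsAsFactors = FALSE)
  hists$count <- subj_off[as.integer(factor(hists$subject))] +
    cond_eff[hists$condition] + 10
  out <- average_histograms(hists)
  expect_true(all(abs(out$sem) < 1e-12))

  # C = 2: hand formula with the sqrt(2) inflation
  set.seed(5)
  hists$count <- rnorm(nrow(hists))
  out2 <- average_histograms(hists)
  one <- subset(hists, bin_mid == 0.5)
  wide <- matrix(one$count[order(one$condition, one$subject)], ncol = 2)
  norm <- wide - rowMeans(wide) + mean(wide)
  hand <- apply(norm, 2, sd) / sqrt(4) * sqrt(2)
  got <- out2$sem[out2$bin_mid == 0.5]  # conditions in sorted order (A, B)
  expect_equal(got, unname(hand), tolerance = 1e-12)

  expect_error(average_histograms(subset(hists, condition == "A")),
               "single condition")
})

test_that("significant-voxel counting matches its definition", {
  z <- count_significant(rep(0, 10))
  expect_equal(unlist(z[1, 1:4]), c(n_pos = 0, n_neg = 0,
                                    pct_pos = 0, pct_neg = 0))
  three <- count_significant(c(3, -3, 0), t_crit = 2.819)
  expect_equal(three$n_pos, 1)
  expect_equal(three$n_neg, 1)

  set.seed(7)
  v <- rnorm(2000, sd = 2)
  cs <- count_significant(v, t_crit = 2.5)
  expect_equal(cs$n_pos, sum(v > 2.5))
  expect_equal(cs$n_neg, sum(v < -2.5))
  expect_equal(cs$pct_pos, 100 * sum(v > 2.5) / 2000)
})

test_that("the antagonism index follows its closed form", {
  expect_equal(antagonism_index(50, 50), 0)
  expect_equal(antagonism_index(0, 100), -1)
  expect_equal(antagonism_index(30, 10), 0.5)
  expect_warning(a <- antagonism_index(0, 0), "undefined")
  expect_true(is.nan(a))
  # sign flip of the map flips the index
  expect_equal(antagonism_index(10, 40), -antagonism_index(40, 10))
})

test_that("paired t-tests match the textbook formula and handle edge cases", {
  set.seed(8)
  a <- rnorm(15)
  b <- rnorm(15)
  got <- paired_t_test(a, b)
  orc <- oracle_paired_t(a, b)
  expect_equal(got$t, orc$t, tolerance = 1e-10)
  expect_equal(got$p, orc$p, tolerance = 1e-10)
  expect_equal(got$df, orc$df)
  expect_equal(paired_t_test(b, a)$t, -got$t, tolerance = 1e-12)

  same <- paired_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(deg <- paired_t_test(a + 1, a), "zero-variance")
  expect_true(is.nan(deg$t))
  expect_error(paired_t_test(a, b[-1]), "unequal")
})

test_that("the cohort summary assembles counts, indices and tests", {
  set.seed(9)
  mk_map <- function(shift) {
    stat_map(array(rnorm(1000, mean = shift, sd = 1.5), c(10, 10, 10)),
             kind = "t", df = 20)
  }
  maps <- list(gatelike = lapply(rep(-1.2, 6), mk_map),
               balanced = lapply(rep(0, 6), mk_map))
  ds <- distribution_summary(maps, t_crit = 2.5)
  expect_equal(nrow(ds$subjects), 12)
  expect_true(all(ds$subjects$antagonism >= -1 & ds$subjects$antagonism <= 1))
  expect_setequal(unique(ds$tests$test), c("pos_vs_neg_pct", "antagonism"))
  gate_a <- ds$subjects$antagonism[ds$subjects$task == "gatelike"]
  bal_a <- ds$subjects$antagonism[ds$subjects$task == "balanced"]
  expect_lt(mean(gate_a), mean(bal_a))

  # undefined-index subjects are dropped pairwise with a warning
  maps$gatelike[[2]] <- stat_map(array(0, c(10, 10, 10)), kind = "t", df = 20)
  expect_warning(ds2 <- distribution_summary(maps, t_crit = 2.5), "undefined")
  cross <- ds2$tests[ds2$tests$test == "antagonism", ]
  expect_equal(cross$df, 4)  # 6 subjects minus the dropped pair, minus 1
})
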