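test_that("spot statistics use the sample SD and CoV = SD/|mean|", {
  expect_equal(spot_stats(c(3, 3, 3)), c(mean = 3, sd = 0, cov = 0))
  expect_equal(spot_stats(c(1, 2, 3)), c(mean = 2, sd = 1, cov = 0.5))
  expect_error(spot_stats(3), ">= 2")
})

test_that("welch_t matches the textbook formula and stats::t.test", {
  a <- c(10, 11, 12); b <- c(20, 22, 24)
  w <- welch_t(a, b)
  # direct formula oracle
  se2 <- var(a) / 3 + var(b) / 3
  t_o <- (mean(a) - mean(b)) / sqrt(se2)
  df_o <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_o <- 2 * pt(-abs(t_o), df_o)
  expect_equal(w$t, t_o, tolerance = 1e-10)
  expect_equal(w$df, df_o, tolerance = 1e-10)
  expect_equal(w$p, p_o, tolerance = 1e-10)
  tt <- t.test(a, b)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
})

test_that("welch_t degenerate conventions", {
  expect_equal(welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 1)
  expect_equal(welch_t(c(5, 5, 6), c(5, 6, 5))$t, 0)
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_warning(w <- welch_t(c(2, 2), c(3, 3)), "zero variance")
  expect_lt(w$p, 1e-300)
})

test_that("welch_t equals the equal-variance t when groups are balanced", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    # force exactly equal sample variances by standardizing
    a <- (a - mean(a)) / sd(a); b <- 2 + (b - mean(b)) / sd(b)
    w <- welch_t(a, b)
    s <- t.test(a, b, var.equal = TRUE)
    expect_equal(w$p, s$p.value, tolerance = 1e-10)
    expect_equal(w$df, unname(s$parameter), tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
    out <- numeric(m)
    out[o] <- q
    out
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(42)
  grid <- seq(0.01, 0.99, by = 0.01)
  for (len in 1:6) {
    for (rep in 1:200) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
  # permutation equivariance
  p <- c(0.2, 0.01, 0.7, 0.01, 0.05)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("spot selection enforces both fold and p thresholds", {
  stats <- data.frame(spot_id = c("a", "b", "c", "d"),
                      fold = c(1.49, -1.88, 2.5, 1.6),
                      p = c(0.001, 0.01, 0.2, 0.04),
                      q = c(0.004, 0.02, 0.4, 0.06),
                      stringsAsFactors = FALSE)
  sel <- select_spots(stats, fold_threshold = 1.5, alpha = 0.05,
                      use_adjusted = TRUE)
  expect_identical(sel$spot_id, "b")            # a fails fold, c/d fail q
  expect_identical(sel$direction, NULL)
  sel_raw <- select_spots(stats, use_adjusted = FALSE)
  expect_identical(sel_raw$spot_id, c("b", "d"))
})

test_that("selection is monotone in alpha and fold threshold", {
  set.seed(43)
  stats <- data.frame(spot_id = as.character(1:100),
                      fold = linear_to_fold(2^rnorm(100)),
                      p = runif(100), stringsAsFactors = FALSE)
  stats$q <- bh_adjust(stats$p)
  base <- select_spots(stats, 1.5, 0.05)$spot_id
  expect_true(all(select_spots(stats, 1.5, 0.01)$spot_id %in% base))
  expect_true(all(select_spots(stats, 2.0, 0.05)$spot_id %in% base))
})

test_that("venn classification partitions the union", {
  v <- venn_classify(c("1", "2"), c("2", "3"))
  expect_identical(v[c("both", "abundance_only", "sno_only")],
                   list(both = 1L, abundance_only = 1L, sno_only = 1L))
  v2 <- venn_classify(c("a", "b"), c("a", "b"))
  expect_identical(v2$both, 2L)
  expect_identical(v2$abundance_only + v2$sno_only, 0L)
})

test_that("differential table recovers planted effects and venn categories", {
  sim <- simulate_gelset(synthetic_config(
    n_subjects_per_group = 12, n_spots = 120,
    frac_abundance_diff = 0.15, frac_sno_diff = 0.1,
    abundance_effect_fold = 3, sno_quench_base = 0.3, sno_quench_effect = 0.4,
    seed = 44))
  gs <- normalize_gelset(sim$gelset)
  d_ab <- differential_table(gs, "Asc+")
  d_sno <- differential_table(gs, "Asc-")
  rq <- ror_quantify(gs)
  sel_ab <- select_spots(d_ab)
  sel_sno <- select_sno_spots(d_sno, rq)

  truth_ab <- sim$truth$spot_id[sim$truth$true_abundance_fold != 1]
  truth_sno <- sim$truth$spot_id[sim$truth$true_sno_direction != "unchanged"]
  truth_cat <- ifelse(sim$truth$spot_id %in% truth_ab &
                        sim$truth$spot_id %in% truth_sno, "both",
                      ifelse(sim$truth$spot_id %in% truth_ab, "abundance_only",
                             ifelse(sim$truth$spot_id %in% truth_sno,
                                    "sno_only", "neither")))
  got_cat <- ifelse(sim$truth$spot_id %in% sel_ab$spot_id &
                      sim$truth$spot_id %in% sel_sno$spot_id, "both",
                    ifelse(sim$truth$spot_id %in% sel_ab$spot_id, "abundance_only",
                           ifelse(sim$truth$spot_id %in% sel_sno$spot_id,
                                  "sno_only", "neither")))
  affected <- truth_cat != "neither"
  expect_gte(mean(got_cat[affected] == truth_cat[affected]), 0.9)
})

test_that("differential CoV is computed on the raw volume scale", {
  sim <- simulate_gelset(synthetic_config(n_subjects_per_group = 4,
                                          n_spots = 10, bias_log_sd = 0,
                                          seed = 45))
  gs <- normalize_gelset(sim$gelset)
  d <- differential_table(gs, "Asc+")
  gels_nh <- .gels_for_test(gs, "NH", "Asc+")
  raw <- gs$volumes[1, gels_nh]
  expect_equal(d$cov_NH[1], sd(raw) / mean(raw))
  expect_equal(d$mean_NH[1], mean(log2(raw)))
})
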