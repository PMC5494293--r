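test_that("group_effect computes available-case means and direction", {
  ge <- group_effect(c(1.0, 1.2, 0.8), c(-1.0, -0.8, -1.2))
  expect_equal(ge$mean_dcq_h, 1.0)
  expect_equal(ge$mean_dcq_p, -1.0)
  expect_equal(ge$ddcq, -2.0)
  expect_equal(ge$neg_ddcq, 2.0)
  expect_equal(ge$direction, "up")

  same <- group_effect(c(1, 2), c(2, 1))
  expect_equal(same$ddcq, 0)
  expect_equal(same$direction, "none")

  # swap antisymmetry
  a <- group_effect(c(0.3, 0.5, NA), c(1.1, 0.9))
  b <- group_effect(c(1.1, 0.9), c(0.3, 0.5, NA))
  expect_equal(b$neg_ddcq, -a$neg_ddcq)

  empty <- group_effect(numeric(0), c(1, 2))
  expect_true(is.na(empty$ddcq))
})

test_that("two_sample_t matches closed form and stats::t.test", {
  r <- two_sample_t(c(1, 2, 3), c(3, 4, 5), "student")
  expect_equal(r$t_stat, -2.449490, tolerance = 1e-6)
  expect_equal(r$df, 4)

  set.seed(71)
  for (rep in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    for (v in c("welch", "student")) {
      mine <- two_sample_t(x, y, v)
      ref <- t.test(x, y, var.equal = (v == "student"))
      expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  }

  ident <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t_stat, 0)
  expect_equal(ident$p_value, 1)

  # welch reduces to student for equal variance and equal n
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(two_sample_t(x, y, "welch")$t_stat,
               two_sample_t(x, y, "student")$t_stat, tolerance = 1e-6)

  expect_true(is.na(two_sample_t(1, c(1, 2))$p_value))         # n too small
  expect_true(is.na(two_sample_t(c(1, 1), c(1, 1))$p_value))   # degenerate tie
  expect_warning(r0 <- two_sample_t(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(r0$p_value, 0)
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(81)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    p <- runif(n)^sample(1:3, 1)
    if (rep %% 3 == 0) p[sample(n, min(2, n))] <- p[1]       # inject ties
    if (rep %% 4 == 0) p[sample(n, 1)] <- NA                 # and missing
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    ok <- !is.na(p)
    expect_true(all(q[ok] >= p[ok] - 1e-12 & q[ok] <= 1))
    expect_true(all(diff(q[ok][order(p[ok])]) >= -1e-12))    # monotone in p
    expect_true(all(is.na(q[!ok])))
  }
})

sim_diff <- function(seed, ...) {
  sim <- generate_cq_dataset(sim_config(seed = seed, ...))
  norm <- global_mean_normalize(filter_detected(sim$table, sim$sheet))
  list(sim = sim, tab = diff_exp(norm, sim$sheet))
}

test_that("diff_exp produces a consistent, deterministically sorted table", {
  r <- sim_diff(91, n_mirna = 120, n_up = 5, n_down = 5)
  tab <- r$tab
  expect_s3_class(tab, "diff_exp_table")
  expect_equal(tab$neg_ddcq, -tab$ddcq)
  expect_true(all(tab$direction[!is.na(tab$neg_ddcq) & tab$neg_ddcq > 0] == "up"))
  tested <- !is.na(tab$p_value)
  expect_true(all(tab$q_value[tested] >= tab$p_value[tested] - 1e-12))
  expect_false(is.unsorted(tab$q_value[tested]))
  # per-row agreement with the scalar operations
  grp <- r$sim$sheet$group
  norm <- global_mean_normalize(filter_detected(r$sim$table, r$sim$sheet))
  for (mir in sample(tab$mirna_id, 10)) {
    row <- tab[tab$mirna_id == mir, ]
    dcq <- norm$delta_cq[mir, ]
    ge <- group_effect(dcq[grp == "healthy"], dcq[grp == "periodontitis"])
    expect_equal(row$ddcq, ge$ddcq)
    tt <- two_sample_t(dcq[grp == "healthy"], dcq[grp == "periodontitis"], "welch")
    expect_equal(row$p_value, tt$p_value, tolerance = 1e-12)
  }
})

test_that("selection thresholds are strict and label-swap antisymmetric", {
  fake <- data.frame(mirna_id = c("hsa-miR-a", "hsa-miR-b", "hsa-miR-c",
                                  "hsa-miR-d"),
                     neg_ddcq = c(1.2, 1.0, 3.0, -1.4),
                     q_value = c(0.04, 0.04, 0.06, 0.01))
  class(fake) <- c("diff_exp_table", "data.frame")
  cand <- select_candidates(fake, 0.05, 1.0)
  expect_equal(cand$up$members, "hsa-mir-a")     # 1.0 and q 0.06 excluded
  expect_equal(cand$down$members, "hsa-mir-d")

  r <- sim_diff(101, n_mirna = 150)
  swapped_sheet <- r$sim$sheet
  swapped_sheet$group <- ifelse(swapped_sheet$group == "healthy",
                                "periodontitis", "healthy")
  norm <- global_mean_normalize(filter_detected(r$sim$table, r$sim$sheet))
  tab_sw <- diff_exp(norm, swapped_sheet)
  cand <- select_candidates(r$tab)
  cand_sw <- select_candidates(tab_sw)
  expect_equal(sort(cand$up$members), sort(cand_sw$down$members))
  expect_equal(sort(cand$down$members), sort(cand_sw$up$members))
})

test_that("miRNAs below min_n per group are reported descriptively", {
  m <- rbind(c(30, 31, 32, 33, 29, 28),   # fully detected -> tested
             c(30, NA, NA, NA, 29, 28))   # 1 healthy -> descriptive only
  tab <- make_cq(m)
  sheet <- make_sheet(paste0("S", 1:6), rep(c("healthy", "periodontitis"), each = 3))
  norm <- global_mean_normalize(tab)
  d <- diff_exp(norm, sheet)
  row2 <- d[d$mirna_id == "hsa-miR-t02", ]
  expect_true(is.na(row2$p_value) && is.na(row2$q_value))
  expect_false(is.na(row2$ddcq))
  expect_false(row2$passes)
})
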