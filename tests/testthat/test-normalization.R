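test_that("global-mean normalization matches hand-computed values", {
  tab <- make_cq(matrix(c(30, 32, 34), 3, 1))
  dcq <- global_mean_normalize(tab)$delta_cq
  expect_equal(unname(dcq[, 1]), c(-2, 0, 2))

  # undetected cell excluded from the sample mean
  tab2 <- make_cq(matrix(c(30, 32, NA, 34), 4, 1))
  dcq2 <- global_mean_normalize(tab2)$delta_cq
  expect_equal(unname(dcq2[, 1]), c(-2, 0, NA, 2))

  empty <- make_cq(rbind(c(30, NA), c(31, NA)))
  expect_error(global_mean_normalize(empty), "S2")
})

test_that("common_only restricts the mean to fully detected miRNAs", {
  m <- rbind(c(30, 30), c(32, 32), c(NA, 40 - 1e-9))
  tab <- make_cq(m)
  dcq <- global_mean_normalize(tab, common_only = TRUE)$delta_cq
  expect_equal(unname(dcq[1, ]), c(-1, -1))  # mean over rows 1-2 only
})

test_that("both normalizations are shift-invariant per sample", {
  set.seed(21)
  for (rep in 1:20) {
    tab <- random_cq(25, 5)
    refs <- mirna_list(tab$mirna_ids[1:4], "refs")
    shifts <- runif(5, -3, 3)
    shifted <- make_cq(sweep(tab$cq, 2, shifts, "+"),
                       mirnas = tab$mirna_ids, censor_at = Inf)
    expect_equal(global_mean_normalize(shifted)$delta_cq,
                 global_mean_normalize(tab)$delta_cq, tolerance = 1e-9)
    expect_equal(multi_reference_normalize(shifted, refs)$delta_cq,
                 multi_reference_normalize(tab, refs)$delta_cq,
                 tolerance = 1e-9)
  }
})

test_that("multi-reference normalization zeroes the reference average", {
  set.seed(5)
  tab <- random_cq(20, 6)
  refs <- mirna_list(tab$mirna_ids[c(2, 7, 11)], "refs")
  norm <- multi_reference_normalize(tab, refs)
  ref_rows <- match(refs$members, canonical_mirna(norm$mirna_ids))
  expect_equal(unname(colMeans(norm$delta_cq[ref_rows, ])), rep(0, 6),
               tolerance = 1e-12)
  # r_s = 25, Cq = 30 -> delta 5
  flat <- make_cq(rbind(c(25, 25), c(30, 30)))
  expect_equal(unname(multi_reference_normalize(flat, flat$mirna_ids[1])$delta_cq[2, ]),
               c(5, 5))
})

test_that("multi-reference normalization reports missing references", {
  m <- rbind(c(30, NA), c(25, 26), c(28, 29))
  tab <- make_cq(m)
  expect_error(multi_reference_normalize(tab, tab$mirna_ids[1:2]),
               "hsa-mir-t01 in sample S2")
  expect_error(multi_reference_normalize(tab, "hsa-miR-absent"), "absent")
  expect_error(multi_reference_normalize(tab, character(0)), "empty")
})

test_that("M values agree with the loop-based oracle", {
  set.seed(31)
  for (rep in 1:10) {
    tab <- random_cq(7, 5)
    rk <- rank_stability(tab, k = 6)  # single exclusion, exposes all M values
    bf <- oracle_m_values(tab$cq)
    # the excluded candidate carries its at-removal M; retained carry final M
    excl <- rk$exclusion_order
    expect_equal(length(excl), 1)
    expect_equal(unname(rk$m_value[excl]), unname(bf[excl]), tolerance = 1e-10)
    expect_equal(excl, names(which.max(bf)))
  }
})

test_that("perfectly covarying candidates have M = 0", {
  base <- c(25, 27, 30, 24)
  tab <- make_cq(rbind(base, base + 2, base - 1))
  rk <- rank_stability(tab, k = 2)
  expect_equal(max(rk$m_value), 0)
})

test_that("iterative exclusion equals brute-force recomputation", {
  set.seed(41)
  for (rep in 1:25) {
    n_cand <- sample(4:8, 1)
    n_samp <- sample(3:6, 1)
    k <- sample(2:(n_cand - 1), 1)
    tab <- random_cq(n_cand, n_samp)
    rk <- rank_stability(tab, k = k)
    bf <- oracle_genorm(tab$cq, k)
    expect_equal(rk$exclusion_order, bf$exclusion_order)
    expect_equal(sort(rk$selected_references$members),
                 sort(canonical_mirna(bf$selected)))
  }
})

test_that("rank_stability validates preconditions and skips partial candidates", {
  tab <- random_cq(6, 4)
  expect_error(rank_stability(tab, k = 1), "k must be")
  expect_error(rank_stability(tab, k = 7), "fully detected")
  two_samp <- random_cq(6, 2)
  expect_error(rank_stability(two_samp, k = 2), ">= 3 samples")

  m <- tab$cq
  m[1, 2] <- NA  # candidate 1 no longer fully detected
  tab2 <- make_cq(m, mirnas = tab$mirna_ids)
  rk <- rank_stability(tab2, k = 2)
  expect_false("hsa-mir-t01" %in% canonical_mirna(rk$candidate_ids))
})

test_that("M values are shift-invariant (raw Cq vs normalized delta-Cq)", {
  set.seed(51)
  tab <- random_cq(10, 5)
  refs <- rank_stability(tab, k = 5)
  norm <- multi_reference_normalize(tab, refs$selected_references)
  renorm_tab <- make_cq(norm$delta_cq + 30, mirnas = norm$mirna_ids,
                        censor_at = Inf)
  rk2 <- rank_stability(renorm_tab, k = 5)
  expect_equal(sort(rk2$selected_references$members),
               sort(refs$selected_references$members))
  expect_equal(unname(rk2$m_value[refs$candidate_ids]),
               unname(refs$m_value[refs$candidate_ids]), tolerance = 1e-9)
})

test_that("the five-probe reference panel file is accepted", {
  refs <- read_mirna_list(system.file("extdata", "reference_mirnas.txt",
                                      package = "gcfmir"))
  expect_equal(refs$members,
               canonical_mirna(c("hsa-miR-324-5p", "hsa-miR-29c-5p",
                                 "hsa-miR-107", "hsa-miR-324-3p",
                                 "hsa-miR-30d-5p")))
  set.seed(61)
  tab <- random_cq(5, 4)
  tab <- make_cq(tab$cq, mirnas = c("hsa-miR-324-5p", "hsa-miR-29c-5p",
                                    "hsa-miR-107", "hsa-miR-324-3p",
                                    "hsa-miR-30d-5p"))
  norm <- multi_reference_normalize(tab, refs)
  expect_equal(norm$reference_set$members, refs$members)
  expect_equal(unname(colMeans(norm$delta_cq)), rep(0, 4), tolerance = 1e-12)
})
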