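test_that("fully tied tables give Q = 0, p = 1 by convention", {
  tab <- matrix(5, 4, 3)
  ft <- friedman_test(tab, exact = TRUE)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p.value, 1)
  expect_equal(ft$p.exact, 1)
  # identical columns, varying rows
  tab2 <- matrix(rep(c(1, 7, 2, 9), 3), 4, 3)
  expect_equal(friedman_test(tab2)$statistic, 0)
  expect_equal(friedman_test(tab2)$p.value, 1)
})

test_that("a consistent strict ordering in every row gives Q = 6 at n = k = 3", {
  tab <- rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.5, 0.9))
  ft <- friedman_test(tab, exact = TRUE)
  expect_equal(ft$statistic, 6)
  expect_equal(ft$df, 2)
  expect_equal(ft$p.value, stats::pchisq(6, 2, lower.tail = FALSE))
  expect_equal(ft$p.exact, 1 / 36)       # 6 of the 216 equally likely tables
})

test_that("missing cells are refused rather than imputed", {
  tab <- rbind(c(1, 2, 3), c(4, NA, 6))
  expect_error(friedman_test(tab), "missing cells")
  expect_error(friedman_test(matrix(1:3, 1, 3)), "at least 2 blocks")
  expect_error(friedman_test(matrix(1:3, 3, 1)), "at least 2")
})

test_that("Q agrees with the rank-sum oracle and stats::friedman.test", {
  set.seed(42)
  for (i in 1:25) {
    x <- matrix(runif(5 * 3), 5, 3)
    expect_equal(friedman_test(x)$statistic, oracle_friedman_Q(x), tolerance = 1e-12)
    expect_equal(friedman_test(x)$statistic,
                 unname(stats::friedman.test(x)$statistic), tolerance = 1e-9)
  }
  # with ties (the tie-corrected statistic; 1.4 by hand for this table)
  xt <- rbind(c(1, 1, 2), c(3, 2, 2), c(4, 4, 4), c(1, 2, 3))
  expect_equal(friedman_test(xt)$statistic, 1.4, tolerance = 1e-12)
  expect_equal(friedman_test(xt)$statistic, oracle_friedman_Q(xt), tolerance = 1e-12)
  expect_equal(friedman_test(xt)$statistic,
               unname(stats::friedman.test(xt)$statistic), tolerance = 1e-9)
})

test_that("the exact permutation p matches brute-force enumeration", {
  set.seed(9)
  for (i in 1:10) {
    x <- matrix(runif(4 * 3), 4, 3)
    expect_equal(friedman_test(x, exact = TRUE)$p.exact,
                 oracle_friedman_perm_p(x), tolerance = 1e-12)
  }
})

test_that("Q is invariant under row-wise monotone transforms and column permutation", {
  set.seed(5)
  x <- matrix(runif(6 * 4), 6, 4)
  colnames(x) <- c("Spont", "A", "B", "C")
  y <- x
  y[1, ] <- exp(x[1, ]); y[2, ] <- x[2, ]^3; y[3, ] <- 10 * x[3, ] - 4
  expect_equal(friedman_test(y)$statistic, friedman_test(x)$statistic, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(friedman_test(x[, perm])$statistic, friedman_test(x)$statistic,
               tolerance = 1e-12)
  dn <- dunns_posthoc(x, comparisons = list(c("A", "B")))
  dnp <- dunns_posthoc(x[, perm], comparisons = list(c("A", "B")))
  expect_equal(dn$z, dnp$z, tolerance = 1e-12)
})

test_that("Dunn z and p match the closed form", {
  tab <- rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.5, 0.9))
  colnames(tab) <- c("a", "b", "c")
  dn <- dunns_posthoc(tab, comparisons = list(c("c", "a")))
  expect_equal(dn$z, 2 / sqrt(3 * 4 / (6 * 3)), tolerance = 1e-9)   # 2.449...
  expect_equal(dn$p_value, 2 * (1 - pnorm(abs(dn$z))), tolerance = 1e-12)
  expect_equal(dn$p_adjusted, dn$p_value)                 # single comparison
  # self-comparison is the identity
  self <- dunns_posthoc(tab, comparisons = list(c("a", "a")))
  expect_equal(self$z, 0)
  expect_equal(self$p_adjusted, 1)
  expect_error(dunns_posthoc(tab, comparisons = list(c("a", "zz"))), "unknown condition")
})

test_that("adjusted p-values never undercut unadjusted ones; Spont is the default baseline", {
  set.seed(13)
  for (i in 1:10) {
    x <- matrix(runif(4 * 4), 4, 4)
    colnames(x) <- c("Spont", "d1", "d2", "d3")
    dn <- dunns_posthoc(x)
    expect_equal(nrow(dn), 3)
    expect_true(all(dn$group1 == "Spont"))
    expect_true(all(dn$p_adjusted >= dn$p_value - 1e-15))
    expect_true(all(dn$p_adjusted <= 1))
    dh <- dunns_posthoc(x, p_adjust = "holm")
    expect_true(all(dh$p_adjusted <= dn$p_adjusted + 1e-15))
  }
})

test_that("stars follow the 0.05 / 0.01 convention on adjusted p", {
  tab <- matrix(c(1:8, (1:8) * 2 + 0.5), 8, 2)
  colnames(tab) <- c("Spont", "drug")
  dn <- dunns_posthoc(tab)
  expect_equal(dn$stars, if (dn$p_adjusted < 0.01) "**" else if (dn$p_adjusted < 0.05) "*" else "")
})

test_that("epoch windows recover the regime frequencies of a scheduled simulation", {
  p <- preset("drug_response")
  ev <- ground_truth(p)$event_times_by_station[["0"]] + p$pulse_width_s / 2
  des <- epoch_design(drug_schedule(300, "sildenafil 5 uM"))
  f <- epoch_frequencies(ev, des, 480)
  expect_equal(unname(f["Spont"]), 7.5)
  expect_equal(unname(f["sildenafil 5 uM"]), 3)
})

test_that("epoch window violations are reported with the addition named", {
  des <- epoch_design(drug_schedule(60, "SNP 100 uM"))
  expect_error(epoch_frequencies(numeric(), des, 480), "SNP 100 uM.*pre-window")
  des2 <- epoch_design(drug_schedule(300, "ANP 0.1 uM"))
  expect_error(epoch_frequencies(numeric(), des2, 350), "ANP 0.1 uM.*post-window")
  des3 <- epoch_design(drug_schedule(c(150, 200), c("a", "b")))
  expect_error(epoch_frequencies(numeric(), des3, 480), "overlaps the pre-window")
  expect_equal(as.numeric(epoch_frequencies(numeric(),
                                            epoch_design(drug_schedule(150, "x")), 300)),
               c(0, 0))                      # no events anywhere -> all cells 0
})

test_that("compare_conditions detects a real frequency drop across segments", {
  des <- epoch_design(drug_schedule(300, "sildenafil 5 uM"))
  segs <- lapply(1:8, function(s) {
    p <- preset("drug_response", seed = s)
    set.seed(s)
    ground_truth(p)$event_times_by_station[["0"]] + p$pulse_width_s / 2 +
      rnorm(60, 0, 0.2)[seq_along(ground_truth(p)$event_times_by_station[["0"]])]
  })
  res <- compare_conditions(segs, des, 480)
  expect_equal(dim(res$frequency_table), c(8, 2))
  expect_lt(res$pairwise$p_adjusted[1], 0.05)
  expect_equal(res$pairwise$group1[1], "Spont")
})

test_that("no regime change keeps the false-positive rate nominal", {
  des <- epoch_design(drug_schedule(300, "vehicle"))
  p_vals <- vapply(1:20, function(rep) {
    segs <- lapply(1:8, function(s) {
      p <- preset("drug_response", seed = s)
      p$schedule <- p$schedule[0, ]          # no actual frequency change
      ev <- ground_truth(p)$event_times_by_station[["0"]] + p$pulse_width_s / 2
      set.seed(rep * 100 + s)
      ev + rnorm(length(ev), 0, 0.4)
    })
    compare_conditions(segs, des, 480)$pairwise$p_adjusted[1]
  }, 0)
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("a single condition is refused", {
  expect_error(friedman_test(matrix(runif(8), 8, 1)), "at least 2")
})
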