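# Bootstrap SEs, reproducibility, undefined-resample handling, and the
# pairwise comparison machinery.

boot_stub <- function(label, mean_r, se_r, B = 1000) {
  # minimal lifetable_boot for arithmetic checks of the comparison layer
  v <- c(r = mean_r, lambda = NA_real_, R0 = NA_real_, T = NA_real_)
  s <- c(r = se_r, lambda = NA_real_, R0 = NA_real_, T = NA_real_)
  structure(list(estimate = v, estimates = NULL, boot_mean = v,
                 boot_se = s, flagged = 0L, B = B, seed = 1L,
                 label = label, N = 10L),
            class = "lifetable_boot")
}

test_that("a cohort of identical clones has zero bootstrap SE", {
  co <- clone_cohort(c(1, 2, 3, 4, 4), c(0, 0, 0, 6, 4), n = 12)
  bt <- bootstrap_lifetable(co, B = 200, seed = 3)
  expect_equal(unname(bt$boot_se), rep(0, 4))
  expect_equal(bt$flagged, 0L)
  expect_equal(unname(bt$boot_mean), unname(bt$estimate))
})

test_that("bootstrap output is reproducible given (cohort, B, seed)", {
  co <- toy4_cohort()   # resamples without the one female are flagged
  b1 <- suppressWarnings(bootstrap_lifetable(co, B = 300, seed = 42))
  b2 <- suppressWarnings(bootstrap_lifetable(co, B = 300, seed = 42))
  expect_identical(b1$estimates, b2$estimates)
  b3 <- suppressWarnings(bootstrap_lifetable(co, B = 300, seed = 43))
  expect_false(identical(b1$estimates, b3$estimates))
  # the caller's RNG stream is untouched
  set.seed(7); x1 <- runif(1)
  set.seed(7)
  invisible(suppressWarnings(bootstrap_lifetable(co, B = 10, seed = 1)))
  expect_identical(runif(1), x1)
})

test_that("resamples without eggs are flagged and excluded, not imputed", {
  co <- cohort(list(
    list(id = "f", stage = c(1L, 2L, 3L, 4L), eggs = c(0L, 0L, 0L, 8L)),
    list(id = "m", stage = c(1L, 2L, 3L, 5L), eggs = rep(0L, 4))))
  expect_warning(bt <- bootstrap_lifetable(co, B = 400, seed = 11),
                 "R0 = 0")
  expect_gt(bt$flagged, 0)
  expect_equal(sum(is.na(bt$estimates[, "r"])), bt$flagged)
  expect_equal(sum(!is.na(bt$estimates[, "r"])) + bt$flagged, bt$B)
  # R0 itself is defined for every resample
  expect_false(anyNA(bt$estimates[, "R0"]))
})

test_that("the bootstrap mean converges to the point estimate", {
  co <- generate_cohort(preset_config("outbred", 4, n = 60, seed = 21))
  bt <- bootstrap_lifetable(co, B = 5000, seed = 2)
  expect_lt(abs(bt$boot_mean[["R0"]] - bt$estimate[["R0"]]),
            3 * bt$boot_se[["R0"]] / sqrt(bt$B))
})

test_that("two-group comparison handles identity, separation and zero SE", {
  a <- boot_stub("a", 0.30, 0.01)
  expect_equal(compare_params(a, a, parameters = "r")$p, 1)
  expect_equal(compare_params(a, a, parameters = "r")$diff, 0)
  # means ten pooled SEs apart
  b <- boot_stub("b", 0.30 - 10 * sqrt(2) * 0.01, 0.01)
  expect_lt(compare_params(a, b, parameters = "r")$p, 1e-10)
  # degenerate SEs
  z1 <- boot_stub("z1", 0.5, 0); z2 <- boot_stub("z2", 0.4, 0)
  expect_equal(compare_params(z1, z1, parameters = "r")$p, 1)
  expect_equal(compare_params(z1, z2, parameters = "r")$p, 0)
})

test_that("outbred and inbred lines separate significantly in r", {
  a <- bootstrap_lifetable(
    generate_cohort(preset_config("outbred", 1, n = 120, seed = 31)),
    B = 400, seed = 1)
  b <- bootstrap_lifetable(
    generate_cohort(preset_config("inbred", 7, n = 120, seed = 32)),
    B = 400, seed = 2)
  cmp <- compare_params(a, b, parameters = "r")
  expect_gt(cmp$diff, 0)
  expect_lt(cmp$p, 0.05)
})

test_that("Tukey-Kramer letters behave on degenerate and ordered groups", {
  expect_error(tukey_kramer(list(boot_stub("a", 1, 1))), "at least two")
  # two groups: same ordering as the two-sample comparison
  a <- boot_stub("a", 0.30, 0.01); b <- boot_stub("b", 0.10, 0.01)
  tk <- tukey_kramer(list(a, b), parameter = "r")
  expect_equal(nrow(tk$comparisons), 1L)
  expect_gt(tk$comparisons$diff, 0)
  expect_true(tk$comparisons$sig)
  expect_equal(unname(tk$letters), c("a", "b"))
  # four identical groups share one letter
  same <- lapply(paste0("g", 1:4), function(l) boot_stub(l, 0.2, 0.01))
  tk4 <- tukey_kramer(same, parameter = "r")
  expect_equal(unname(tk4$letters), rep("a", 4))
  # overlapping chain a > b > c with only the extremes separated
  # (adjacent q = 2.5 < q_crit(3, 999) ~ 3.31 < extreme q = 5)
  ch <- list(boot_stub("hi", 0.250, 0.01), boot_stub("mid", 0.225, 0.01),
             boot_stub("lo", 0.200, 0.01))
  tkc <- tukey_kramer(ch, parameter = "r")
  expect_equal(unname(tkc$letters), c("a", "ab", "b"))
})

test_that("generation-wise R0 decline is ordered and separates across spans", {
  # at these cohort sizes adjacent generations can share a letter (their
  # bootstrap SEs overlap on the studentized-range scale), but means must
  # decline and generations three steps apart must always separate
  boots <- lapply(c(1, 4, 7, 10), function(g)
    suppressWarnings(bootstrap_lifetable(
      generate_cohort(preset_config("inbred", g, n = 120, seed = 40 + g)),
      B = 400, seed = 50 + g)))
  tk <- tukey_kramer(boots, parameter = "R0")
  expect_true(all(diff(unname(tk$means)) < 0))
  lset <- strsplit(unname(tk$letters), "")
  expect_equal(lset[[1]][1], "a")
  no_overlap <- function(i, j) length(intersect(lset[[i]], lset[[j]])) == 0
  expect_true(no_overlap(1, 3))   # F1 vs F7
  expect_true(no_overlap(1, 4))   # F1 vs F10
  expect_true(no_overlap(2, 4))   # F4 vs F10
  expect_true(no_overlap(3, 4))   # F7 vs F10
})

test_that("bootstrap intervals cover the scenario's analytic r at nominal-ish rate", {
  cfg <- preset_config("outbred", 1, n = 120)
  r_true <- analytic_schedule(cfg)$r
  hits <- 0L
  nrep <- 120L
  for (i in seq_len(nrep)) {
    co <- generate_cohort(cfg, seed = 7000 + i)
    bt <- bootstrap_lifetable(co, B = 300, seed = 100 + i)
    lo <- bt$boot_mean[["r"]] - 1.96 * bt$boot_se[["r"]]
    hi <- bt$boot_mean[["r"]] + 1.96 * bt$boot_se[["r"]]
    hits <- hits + (r_true >= lo && r_true <= hi)
  }
  expect_gte(hits / nrep, 0.87)
  expect_lte(hits / nrep, 1.0)
})
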