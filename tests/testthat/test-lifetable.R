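# Age-stage tabulation, schedules, demographic parameters and the
# expectancy/reproductive-value recursions.

test_that("age-stage tabulation reproduces hand counts on the toy cohort", {
  tab <- age_stage_table(toy4_cohort())
  expect_equal(tab$sxj[1, "egg"], 1.0, ignore_attr = TRUE)
  expect_equal(tab$sxj[2, "egg"], 0.75, ignore_attr = TRUE)
  expect_equal(tab$sxj[6, "pupa"], 0.5, ignore_attr = TRUE)
  expect_equal(tab$sxj[8, "female"], 0.25, ignore_attr = TRUE)
  expect_equal(tab$fxj[9, "female"], 20, ignore_attr = TRUE)
  # everyone starts as an egg
  expect_equal(sum(tab$sxj[1, ]), 1)

  one <- age_stage_table(one_ind_cohort(c(1, 1, 2)))
  expect_true(all(one$sxj %in% c(0, 1)))
})

test_that("age-specific schedules collapse stages correctly", {
  sch <- schedules(age_stage_table(toy4_cohort()))
  expect_equal(sch$lx[8], 0.5)
  expect_equal(sch$mx[8], 5)
  expect_equal(sch$lxmx[8:10], c(2.5, 5, 2.5))
  # lx non-increasing, anchored at 1
  expect_equal(sch$lx[1], 1)
  expect_true(all(diff(sch$lx) <= 0))

  # no females -> mx identically zero
  males <- clone_cohort(c(1, 2, 3, 5, 5), rep(0, 5), n = 3)
  expect_true(all(schedules(age_stage_table(males))$mx == 0))
})

test_that("averaging over concurrent stages keeps mx at or below fx4", {
  co <- generate_cohort(preset_config("outbred", 1, n = 150, seed = 5))
  tab <- age_stage_table(co)
  sch <- schedules(tab)
  idx <- tab$fxj[, "female"] > 0 & sch$lx > 0
  expect_true(any(idx))
  expect_true(all(sch$mx[idx] <= tab$fxj[idx, "female"] + 1e-12))
})

test_that("net reproductive rate is total eggs per started egg", {
  sch <- schedules(age_stage_table(toy4_cohort()))
  expect_identical(net_reproductive_rate(sch$lxmx), 10)
  expect_identical(net_reproductive_rate(rep(0, 5)), 0)
  for (i in 1:4) {
    co <- rand_preset_cohort(i, n = 40)
    total <- sum(vapply(co$individuals, function(x) sum(x$eggs), numeric(1)))
    R0 <- net_reproductive_rate(schedules(age_stage_table(co))$lxmx)
    expect_equal(R0 * co$N, total, tolerance = 1e-12)
  }
  expect_error(net_reproductive_rate(c(1, NA)), "non-finite")
})

test_that("the Euler-Lotka solver matches closed forms and a grid oracle", {
  # all maternity at age 4 with value e -> r = ln(e)/(4+1) = 0.2
  lxmx <- c(0, 0, 0, 0, exp(1))
  expect_equal(intrinsic_rate(lxmx), 0.2, tolerance = 1e-11)

  sch <- schedules(age_stage_table(toy4_cohort()))
  r <- intrinsic_rate(sch$lxmx)
  expect_equal(r, grid_search_r(sch$lxmx), tolerance = 2e-6)

  # replacement-level cohort: toy eggs scaled by 1/10 -> R0 = 1, r = 0
  co10 <- toy4_cohort()
  co10$individuals[[1]]$eggs <- as.integer(co10$individuals[[1]]$eggs / 10)
  r0 <- intrinsic_rate(schedules(age_stage_table(co10))$lxmx)
  expect_equal(r0, 0, tolerance = 1e-10)

  expect_error(intrinsic_rate(rep(0, 3)), "R0 is zero")
  expect_error(intrinsic_rate(c(0, NaN)), "non-finite")
  expect_error(intrinsic_rate(c(0, 1), tol = -1), "tol")
})

test_that("lambda and T are exact transforms of r and R0", {
  expect_equal(finite_rate(0), 1)
  expect_true(is.na(generation_time(1, 0)))
  expect_error(generation_time(2, 0), "inconsistent")
  expect_error(generation_time(0, 0.1), "R0 > 0")
  r <- 0.25; R0 <- 40
  expect_identical(finite_rate(r), exp(r))
  expect_identical(generation_time(R0, r), log(R0) / r)
})

test_that("empirical transitions match hand counts on the toy cohort", {
  tr <- stage_transitions(toy4_cohort())
  # age 0, egg: 3 of 4 stay eggs, B dies
  expect_equal(tr$counts[1, 1, 1] / tr$n[1, 1], 0.75)
  expect_equal(sum(tr$counts[1, 1, ]) / tr$n[1, 1], 0.75)
  # age 4, larva: A and D pupate, C dies
  expect_equal(tr$counts[5, 2, 3] / tr$n[5, 2], 2 / 3)
  # the longest-lived individual's last day has no survivors
  expect_equal(sum(tr$counts[10, , ]), 0)
  expect_equal(tr$n[10, 4], 1L, ignore_attr = TRUE)
})

test_that("life expectancy matches hand values and the path-enumeration oracle", {
  co <- toy4_cohort()
  tr <- stage_transitions(co)
  e <- life_expectancy(tr)
  expect_equal(e[10, "female"], 1, ignore_attr = TRUE)
  expect_equal(e[9, "female"], 2, ignore_attr = TRUE)
  expect_equal(e[1, "egg"], 6.25, ignore_attr = TRUE)   # (10+1+5+9)/4

  # exhaustive enumeration over all transition paths, toy + tiny synthetic
  for (xj in list(c(0, 1), c(2, 2), c(5, 3), c(7, 4))) {
    expect_equal(e[xj[1] + 1, xj[2]],
                 enum_expectancy(tr, xj[1], xj[2]), ignore_attr = TRUE)
  }
  for (i in 6:8) {
    co2 <- rand_preset_cohort(i, n = 5)
    # truncate long-lived individuals to keep enumeration tiny
    co2$individuals <- lapply(co2$individuals, function(ind) {
      k <- min(length(ind$stage), 15L)
      list(id = ind$id, stage = ind$stage[1:k], eggs = ind$eggs[1:k])
    })
    co2 <- cohort(co2$individuals, label = "tiny")
    tr2 <- stage_transitions(co2)
    e2 <- life_expectancy(tr2)
    for (xcol in seq_len(nrow(tr2$n)))
      for (j in which(tr2$n[xcol, ] > 0))
        expect_equal(e2[xcol, j], enum_expectancy(tr2, xcol - 1L, j),
                     ignore_attr = TRUE)
  }
})

test_that("reproductive value anchors at lambda and vanishes post-reproduction", {
  co <- toy4_cohort()
  lt <- lifetable(co)
  expect_equal(lt$vxj[1, "egg"], lt$lambda, tolerance = 1e-9,
               ignore_attr = TRUE)
  # female alive one day beyond her last egg contributes nothing further
  post <- one_ind_cohort(c(1, 2, 3, 4, 4), eggs = c(0, 0, 0, 5, 0))
  ltp <- lifetable(post)
  expect_equal(ltp$vxj[5, "female"], 0, ignore_attr = TRUE)
})

test_that("scaling fecundity scales R0 exactly and raises r", {
  co <- toy4_cohort()
  lt <- lifetable(co)
  co2 <- co
  co2$individuals <- lapply(co$individuals, function(ind)
    list(id = ind$id, stage = ind$stage, eggs = 3L * ind$eggs))
  lt2 <- lifetable(cohort(co2$individuals, label = "x3"))
  expect_equal(lt2$R0, 3 * lt$R0, tolerance = 1e-12)
  expect_gt(lt2$r, lt$r)
})

test_that("a cohort that lays no eggs has R0 = 0 and flagged rates", {
  co <- cohort(list(list(id = "a", stage = 1L, eggs = 0L),
                    list(id = "b", stage = 1L, eggs = 0L)))
  lt <- lifetable(co)
  expect_equal(lt$R0, 0)
  expect_false(lt$r_defined)
  expect_true(is.na(lt$r) && is.na(lt$lambda) && is.na(lt$T))
})

test_that("fitted life tables satisfy the structural identities", {
  co <- generate_cohort(preset_config("inbred", 4, n = 80, seed = 9))
  lt <- lifetable(co)
  sch <- lt$schedule
  expect_equal(sch$lx, unname(rowSums(lt$table$sxj)), tolerance = 1e-14)
  expect_equal(sch$lx[1], 1)
  expect_true(all(diff(sch$lx) <= 1e-14))
  # Euler-Lotka residual at the solved r
  xp1 <- seq_along(sch$lxmx)
  expect_lt(abs(sum(exp(-lt$r * xp1) * sch$lxmx) - 1), 1e-10)
  expect_identical(lt$lambda, exp(lt$r))
  expect_identical(lt$T, log(lt$R0) / lt$r)
  # occupied cells live at least the current day
  occ <- lt$table$n > 0
  expect_true(all(lt$exj[occ] >= 1))
  expect_true(all(is.na(lt$exj[!occ])))
})

test_that("print, summary, coef and plot methods run", {
  lt <- lifetable(toy4_cohort())
  expect_output(print(lt), "R0 = 10")
  expect_output(print(summary(lt)), "pre-adult survival")
  expect_named(coef(lt), c("r", "lambda", "R0", "T"))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(lt))
})
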