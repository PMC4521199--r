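# Fixtures built in code and independent oracles used across the suite.

toy4_path <- function() {
  system.file("extdata", "toy4.csv", package = "agestage")
}

# four hand-written trajectories: one egg-laying female (A), one egg death
# (B), one larval death (C), one male (D); 40 eggs total
toy4_cohort <- function() {
  cohort(list(
    list(id = "A", stage = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L),
         eggs = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 10L, 20L, 10L)),
    list(id = "B", stage = 1L, eggs = 0L),
    list(id = "C", stage = c(1L, 1L, 2L, 2L, 2L), eggs = rep(0L, 5)),
    list(id = "D", stage = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 5L, 5L),
         eggs = rep(0L, 9))), label = "toy4")
}

one_ind_cohort <- function(stage, eggs = integer(length(stage)),
                           label = "one") {
  cohort(list(list(id = "a", stage = as.integer(stage),
                   eggs = as.integer(eggs))), label = label)
}

clone_cohort <- function(stage, eggs, n, label = "clones") {
  cohort(lapply(seq_len(n), function(i)
    list(id = paste0("c", i), stage = as.integer(stage),
         eggs = as.integer(eggs))), label = label)
}

# small cohorts drawn from rotating scenario presets
rand_preset_cohort <- function(i, n = 30) {
  lines <- c("outbred", "inbred")
  gens <- c(1, 4, 7, 10)
  cfg <- preset_config(lines[i %% 2 + 1], gens[i %% 4 + 1], n = n,
                       seed = 1000 + i)
  generate_cohort(cfg)
}

# dense grid-search root of the Euler-Lotka equation, independent of the
# bisection solver
grid_search_r <- function(lxmx, lo = 0, hi = 1, step = 1e-6) {
  r <- seq(lo, hi, by = step)
  val <- numeric(length(r))
  for (k in which(lxmx > 0)) val <- val + lxmx[k] * exp(-r * k)
  r[which.min(abs(val - 1))]
}

# expected remaining days (inclusive) from cell (age x0, stage j0) by
# explicit enumeration of every stage path through the empirical
# transition fractions
enum_expectancy <- function(trans, x0, j0) {
  A <- nrow(trans$n)
  probs <- numeric(0)
  lens <- numeric(0)
  walk <- function(xcol, j, p, len) {
    if (xcol == A) {
      probs <<- c(probs, p); lens <<- c(lens, len)
      return(invisible())
    }
    ck <- trans$counts[xcol, j, ]
    nx <- trans$n[xcol, j]
    pdie <- 1 - sum(ck) / nx
    if (pdie > 0) {
      probs <<- c(probs, p * pdie); lens <<- c(lens, len)
    }
    for (k in which(ck > 0)) walk(xcol + 1L, k, p * ck[k] / nx, len + 1)
  }
  walk(x0 + 1L, j0, 1, 1)
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  sum(probs * lens)
}

# fast point estimates (r, lambda, R0, T) of a cohort via its maternity
# schedule only (lxmx = column sums of the egg matrix / N); used where the
# full lifetable() matrices are not needed
point_params <- function(co) {
  m <- agestage:::cohort_matrices(co)
  agestage:::.params_from_lxmx(colSums(m$eggs) / co$N)
}
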