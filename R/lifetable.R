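# Age-stage, two-sex life table: schedules, life expectancy, reproductive
# value, and the demographic parameters r, lambda, R0 and T.

#' Tabulate age-stage counts, survival and fecundity
#'
#' Builds the age x stage bookkeeping of the two-sex life table: \code{n[x,j]}
#' is the number of individuals alive at age \code{x} (days, 0-based) in
#' stage \code{j}; \code{sxj = n/N} is the probability that a newly laid egg
#' survives to age \code{x} and stage \code{j}; \code{fxj} is the mean number
#' of eggs laid per individual of age \code{x} and stage \code{j} (nonzero
#' only for adult females).  Pre-adult deaths and males stay in the
#' denominator \code{N} throughout.
#'
#' @param x A \code{\link{cohort}}.
#' @return An object of class \code{"age_stage_table"}: a list with integer
#'   matrix \code{n}, numeric matrices \code{sxj} and \code{fxj} (rows =
#'   ages \code{0..A}, columns = the five stages), \code{ages}, and \code{N}.
#' @export
age_stage_table <- function(x) {
  validate_cohort(x)
  m <- cohort_matrices(x)
  A <- length(m$ages)
  n   <- matrix(0L, nrow = A, ncol = 5L,
                dimnames = list(age = m$ages, stage = names(stage_codes)))
  egg <- matrix(0,  nrow = A, ncol = 5L, dimnames = dimnames(n))
  for (xcol in seq_len(A)) {
    alive <- m$stage[, xcol] > 0L
    if (!any(alive)) next
    n[xcol, ]   <- tabulate(m$stage[alive, xcol], nbins = 5L)
    if (any(m$eggs[, xcol] > 0L)) {
      st <- m$stage[alive, xcol]
      eg <- m$eggs[alive, xcol]
      egg[xcol, ] <- vapply(1:5, function(j) sum(eg[st == j]), numeric(1))
    }
  }
  fxj <- ifelse(n > 0L, egg / n, 0)
  structure(list(n = n, sxj = n / x$N, fxj = fxj, ages = m$ages, N = x$N),
            class = "age_stage_table")
}

#' Age-specific schedules from an age-stage table
#'
#' Collapses stages into the classical age-specific curves:
#' \code{lx = sum_j sxj} (probability of being alive at age x),
#' \code{mx = sum_j sxj fxj / lx} (mean eggs per living individual; 0 where
#' \code{lx = 0}), and the maternity schedule \code{lxmx = lx * mx}.
#'
#' @param tab An \code{\link{age_stage_table}}.
#' @return A data frame with columns \code{age}, \code{lx}, \code{mx},
#'   \code{lxmx}.
#' @export
schedules <- function(tab) {
  stopifnot(inherits(tab, "age_stage_table"))
  lx <- rowSums(tab$sxj)
  lxmx <- rowSums(tab$sxj * tab$fxj)
  mx <- ifelse(lx > 0, lxmx / lx, 0)
  data.frame(age = tab$ages, lx = lx, mx = mx, lxmx = lxmx,
             row.names = NULL)
}

#' Net reproductive rate
#'
#' \code{R0 = sum_x lx mx}: the expected lifetime offspring per individual
#' of the starting cohort.  Equals total eggs laid divided by \code{N}
#' exactly.
#'
#' @param lxmx Numeric vector of age-specific maternity (ages 0-based).
#' @return \code{R0}, a scalar.
#' @export
net_reproductive_rate <- function(lxmx) {
  if (any(!is.finite(lxmx))) stop("non-finite lxmx")
  sum(lxmx)
}

#' Intrinsic rate of increase from the maternity schedule
#'
#' Solves the discrete Euler-Lotka renewal equation
#' \deqn{\sum_x e^{-r(x+1)} l_x m_x = 1}
#' (age \code{x} 0-based, the age-indexing convention of the age-stage
#' two-sex methodology) for the unique real root \code{r}, by bisection on a
#' bracket expanded from \code{[-1, 1]} until it provably contains the root
#' (hard failure outside \code{[-10, 10]}).
#'
#' @param lxmx Numeric vector of age-specific maternity, indexed by age
#'   \code{0..A}.
#' @param tol Absolute tolerance on \code{r} (default \code{1e-12}).
#' @return The intrinsic rate of increase \code{r} (per day).  Its sign
#'   matches the sign of \code{log(R0)}.
#' @export
intrinsic_rate <- function(lxmx, tol = 1e-12) {
  if (any(!is.finite(lxmx))) stop("non-finite lxmx")
  if (tol <= 0) stop("tol must be positive")
  R0 <- sum(lxmx)
  if (R0 <= 0)
    stop("R0 is zero: the intrinsic rate of increase is undefined")
  keep <- lxmx > 0                     # zero-maternity ages contribute 0
  xp1 <- seq_along(lxmx)[keep]         # x + 1 for 0-based ages
  lpos <- lxmx[keep]
  g <- function(r) sum(exp(-r * xp1) * lpos) - 1   # strictly decreasing
  lo <- -1; hi <- 1
  while (g(hi) > 0) {
    hi <- hi * 2
    if (hi > 10) stop("no Euler-Lotka root in [-10, 10]")
  }
  while (g(lo) < 0) {
    lo <- lo * 2
    if (lo < -10) stop("no Euler-Lotka root in [-10, 10]")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Finite rate of increase
#'
#' @param r Intrinsic rate of increase (per day).
#' @return \code{lambda = exp(r)}, the per-day population multiplication
#'   factor.
#' @export
finite_rate <- function(r) exp(r)

#' Mean generation time
#'
#' \code{T = log(R0) / r}: the time for the population to grow
#' \code{R0}-fold at rate \code{r}.  When \code{r = 0} (replacement,
#' \code{R0 = 1}) the generation time is undefined and \code{NA} is
#' returned.
#'
#' @param R0 Net reproductive rate, must be positive.
#' @param r Intrinsic rate of increase.
#' @return Generation time in days, or \code{NA} if \code{r = 0}.
#' @export
generation_time <- function(R0, r) {
  if (R0 <= 0) stop("generation time requires R0 > 0")
  if (r == 0) {
    if (abs(R0 - 1) > 1e-8)
      stop("r = 0 with R0 != 1 is inconsistent")
    return(NA_real_)
  }
  log(R0) / r
}

#' Empirical day-to-day stage transitions
#'
#' For every occupied (age, stage) cell, counts where its \code{n[x,j]}
#' individuals are on the next day: same stage, the next stage (pupae branch
#' to either adult sex; adults are terminal), or dead.  These empirical
#' fractions drive the life-expectancy and reproductive-value recursions.
#'
#' @param x A \code{\link{cohort}}.
#' @return An object of class \code{"stage_transitions"}: list with
#'   \code{counts}, an \code{A x 5 x 5} array (\code{counts[x, j, k]} =
#'   individuals at age \code{x - 1} in stage \code{j} alive the next day in
#'   stage \code{k}), and the occupancy matrix \code{n}.
#' @export
stage_transitions <- function(x) {
  validate_cohort(x)
  m <- cohort_matrices(x)
  A <- length(m$ages)
  cnt <- array(0L, dim = c(A, 5L, 5L))
  if (A > 1L) {
    for (xcol in seq_len(A - 1L)) {
      from <- m$stage[, xcol]
      to   <- m$stage[, xcol + 1L]
      keep <- from > 0L & to > 0L
      if (!any(keep)) next
      tt <- table(factor(from[keep], levels = 1:5),
                  factor(to[keep],   levels = 1:5))
      cnt[xcol, , ] <- cnt[xcol, , ] + unclass(tt)
    }
  }
  n <- matrix(0L, nrow = A, ncol = 5L,
              dimnames = list(age = m$ages, stage = names(stage_codes)))
  for (xcol in seq_len(A)) {
    alive <- m$stage[, xcol] > 0L
    if (any(alive)) n[xcol, ] <- tabulate(m$stage[alive, xcol], nbins = 5L)
  }
  structure(list(counts = cnt, n = n, ages = m$ages),
            class = "stage_transitions")
}

#' Age-stage life expectancy
#'
#' \code{exj[x, j]} is the expected number of further days an individual of
#' age \code{x} and stage \code{j} will live, counting the current day, so
#' \code{exj >= 1} on every occupied cell and \code{exj[0, egg]} equals the
#' cohort's mean lifespan exactly.  Computed by placing unit mass on the
#' cell and propagating it forward through the empirical transition
#' fractions (equivalently, by the backward recursion
#' \code{e[x,j] = 1 + sum_k P(x,j -> k) e[x+1,k]}).
#'
#' @param trans A \code{\link{stage_transitions}} object.
#' @return Matrix of life expectancies (days); \code{NA} on unoccupied
#'   cells.
#' @export
life_expectancy <- function(trans) {
  stopifnot(inherits(trans, "stage_transitions"))
  A <- nrow(trans$n)
  e <- matrix(NA_real_, nrow = A, ncol = 5L, dimnames = dimnames(trans$n))
  for (xcol in A:1) {
    for (j in which(trans$n[xcol, ] > 0L)) {
      val <- 1
      if (xcol < A) {
        ck <- trans$counts[xcol, j, ]
        nz <- which(ck > 0L)
        if (length(nz))
          val <- val + sum(ck[nz] / trans$n[xcol, j] * e[xcol + 1L, nz])
      }
      e[xcol, j] <- val
    }
  }
  e
}

#' Age-stage reproductive value
#'
#' \code{vxj[x, j]} is the expected contribution of an individual of age
#' \code{x} and stage \code{j} to the future population, in
#' growth-discounted egg equivalents:
#' \deqn{v_{xj} = e^{r(x+1)} \sum_{i \ge x} e^{-r(i+1)} \sum_y s'_{iy} f_{iy},}
#' where \eqn{s'} is unit mass on \code{(x, j)} propagated forward through
#' the empirical transition fractions.  \code{vxj[0, egg]} equals the finite
#' rate \code{lambda} up to solver tolerance, because the inner sum at the
#' egg anchor is the Euler-Lotka sum, which is 1 at the solved \code{r}.
#'
#' @param trans A \code{\link{stage_transitions}} object.
#' @param tab The matching \code{\link{age_stage_table}}.
#' @param r Intrinsic rate of increase (from \code{\link{intrinsic_rate}}).
#' @return Matrix of reproductive values; \code{NA} on unoccupied cells.
#' @export
reproductive_value <- function(trans, tab, r) {
  stopifnot(inherits(trans, "stage_transitions"),
            inherits(tab, "age_stage_table"))
  A <- nrow(trans$n)
  w <- matrix(NA_real_, nrow = A, ncol = 5L)
  for (xcol in A:1) {
    for (j in which(trans$n[xcol, ] > 0L)) {
      val <- exp(-r * xcol) * tab$fxj[xcol, j]   # xcol = age + 1
      if (xcol < A) {
        ck <- trans$counts[xcol, j, ]
        nz <- which(ck > 0L)
        if (length(nz))
          val <- val + sum(ck[nz] / trans$n[xcol, j] * w[xcol + 1L, nz])
      }
      w[xcol, j] <- val
    }
  }
  v <- w * exp(r * seq_len(A))
  dimnames(v) <- dimnames(trans$n)
  v
}

#' Fit an age-stage, two-sex life table to a cohort
#'
#' The main entry point: computes the full age-stage bookkeeping
#' (\code{sxj}, \code{fxj}), the age-specific schedules (\code{lx},
#' \code{mx}, \code{lxmx}), age-stage life expectancy \code{exj} and
#' reproductive value \code{vxj}, and the demographic parameters: net
#' reproductive rate \code{R0}, intrinsic rate of increase \code{r} (root of
#' the Euler-Lotka equation), finite rate \code{lambda = exp(r)} and mean
#' generation time \code{T = log(R0)/r}.  If the cohort laid no eggs
#' (\code{R0 = 0}), \code{r}, \code{lambda} and \code{T} are returned as
#' \code{NA} and flagged.
#'
#' @param x A \code{\link{cohort}}.
#' @param tol Absolute tolerance for the Euler-Lotka bisection.
#' @return An object of class \code{"lifetable"}: list with \code{label},
#'   \code{N}, \code{table} (the age-stage table), \code{schedule} (data
#'   frame \code{age, lx, mx, lxmx}), matrices \code{exj} and \code{vxj},
#'   and scalars \code{R0}, \code{r}, \code{lambda}, \code{T},
#'   \code{r_defined}.
#' @examples
#' co <- generate_cohort(preset_config("outbred", 1, n = 50, seed = 1))
#' lt <- lifetable(co)
#' coef(lt)
#' @export
lifetable <- function(x, tol = 1e-12) {
  tab <- age_stage_table(x)
  sch <- schedules(tab)
  R0 <- net_reproductive_rate(sch$lxmx)
  trans <- stage_transitions(x)
  exj <- life_expectancy(trans)
  if (R0 > 0) {
    r <- intrinsic_rate(sch$lxmx, tol = tol)
    lam <- finite_rate(r)
    Tg <- generation_time(R0, r)
    vxj <- reproductive_value(trans, tab, r)
    r_defined <- TRUE
  } else {
    r <- lam <- Tg <- NA_real_
    vxj <- matrix(NA_real_, nrow = nrow(tab$n), ncol = 5L,
                  dimnames = dimnames(tab$n))
    r_defined <- FALSE
  }
  last <- vapply(x$individuals, function(i) i$stage[length(i$stage)],
                 integer(1))
  structure(list(label = x$label, N = x$N, table = tab, schedule = sch,
                 exj = exj, vxj = vxj, R0 = R0, r = r, lambda = lam,
                 T = Tg, r_defined = r_defined, tol = tol,
                 preadult_survival = sum(last >= 4L) / x$N),
            class = "lifetable")
}

#' @export
print.lifetable <- function(x, digits = 4, ...) {
  cat("Age-stage two-sex life table",
      if (nzchar(x$label)) paste0("('", x$label, "')"), "\n")
  cat("  N =", x$N, "; ages 0 -", max(x$schedule$age), "d\n")
  if (x$r_defined) {
    cat(sprintf("  R0 = %s offspring/individual, r = %s /d, lambda = %s /d, T = %s d\n",
                format(x$R0, digits = digits), format(x$r, digits = digits),
                format(x$lambda, digits = digits),
                format(x$T, digits = digits)))
  } else {
    cat("  R0 = 0: r, lambda and T are undefined for this cohort\n")
  }
  invisible(x)
}

#' @export
coef.lifetable <- function(object, ...) {
  c(r = object$r, lambda = object$lambda, R0 = object$R0, T = object$T)
}

#' @export
summary.lifetable <- function(object, ...) {
  sch <- object$schedule
  peak_f <- if (any(object$table$fxj[, 4] > 0))
    object$table$ages[which.max(object$table$fxj[, 4])] else NA_integer_
  out <- list(label = object$label, N = object$N,
              params = coef(object), r_defined = object$r_defined,
              preadult_survival = object$preadult_survival,
              mean_lifespan = sum(sch$lx),
              peak_fecundity_age = peak_f)
  class(out) <- "summary.lifetable"
  out
}

#' @export
print.summary.lifetable <- function(x, ...) {
  cat("Age-stage two-sex life table",
      if (nzchar(x$label)) paste0("('", x$label, "')"), "\n")
  cat(sprintf("  N = %d; mean lifespan %.2f d; pre-adult survival %.3f\n",
              x$N, x$mean_lifespan, x$preadult_survival))
  if (!is.na(x$peak_fecundity_age))
    cat("  peak female daily fecundity at age", x$peak_fecundity_age, "d\n")
  if (x$r_defined) {
    p <- x$params
    cat(sprintf("  r = %.4f /d   lambda = %.4f /d   R0 = %.3f   T = %.2f d\n",
                p["r"], p["lambda"], p["R0"], p["T"]))
  } else cat("  R0 = 0: demographic rates undefined\n")
  invisible(x)
}

#' Plot life-table schedules
#'
#' Base-graphics plot of the age-specific curves: survival \code{lx} (left
#' axis) and fecundity \code{mx}, maternity \code{lxmx} and female daily
#' fecundity \code{fx4} (right axis).
#'
#' @param x A \code{"lifetable"}.
#' @param ... Passed to \code{matplot} for the fecundity curves.
#' @return \code{x}, invisibly.
#' @export
plot.lifetable <- function(x, ...) {
  sch <- x$schedule
  fx4 <- x$table$fxj[, 4]
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(sch$age, sch$lx, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "age (d)", ylab = expression(l[x]),
                 main = if (nzchar(x$label)) x$label else "life-table schedules")
  graphics::par(new = TRUE)
  graphics::matplot(sch$age, cbind(sch$mx, sch$lxmx, fx4), type = "l",
                    lty = c(2, 3, 4), col = c("red", "blue", "darkgreen"),
                    axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(4)
  graphics::mtext("eggs / individual / d", side = 4, line = 2.5)
  graphics::legend("topright", bty = "n",
                   legend = c(expression(l[x]), expression(m[x]),
                              expression(l[x] * m[x]), expression(f[x4])),
                   lty = 1:4, lwd = c(2, 1, 1, 1),
                   col = c("black", "red", "blue", "darkgreen"))
  invisible(x)
}
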