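# Bootstrap means/SEs for demographic parameters and pairwise group
# comparisons (two-sample z tests, Tukey-Kramer with compact letters).

# run code under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, fun) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# schedule -> scalar parameters; the single code path shared by lifetable()
# (via its exported pieces) and the bootstrap resamples
.params_from_lxmx <- function(lxmx, tol = 1e-12) {
  R0 <- sum(lxmx)
  if (R0 <= 0)
    return(c(r = NA_real_, lambda = NA_real_, R0 = R0, T = NA_real_))
  r <- intrinsic_rate(lxmx, tol = tol)
  c(r = r, lambda = finite_rate(r), R0 = R0,
    T = generation_time(R0, r))
}

#' Bootstrap the demographic parameters of a cohort
#'
#' Resamples \code{N} individuals with replacement (the individual is the
#' resampling unit), recomputes the maternity schedule and the parameters
#' \code{r}, \code{lambda}, \code{R0} and \code{T} for each resample, and
#' reports the resample mean and standard deviation (the bootstrap SE) per
#' parameter.  Resamples in which no eggs are laid (\code{R0 = 0}) leave
#' \code{r}, \code{lambda} and \code{T} undefined; such resamples are
#' flagged, counted, and excluded from the mean/SE of the affected
#' parameters rather than imputed.
#'
#' All resample indices are drawn up-front from a generator seeded once, so
#' results are reproducible given \code{(cohort, B, seed)} and independent
#' of evaluation order; the caller's RNG state is left untouched.
#'
#' @param x A \code{\link{cohort}}.
#' @param B Number of bootstrap resamples (default 10000).
#' @param seed Integer RNG seed; chosen randomly (and recorded) if omitted.
#' @param tol Euler-Lotka tolerance passed to \code{\link{intrinsic_rate}}.
#' @return An object of class \code{"lifetable_boot"}: list with
#'   \code{estimate} (point estimates from the full cohort),
#'   \code{estimates} (a \code{B x 4} matrix of resample values),
#'   \code{boot_mean}, \code{boot_se}, \code{flagged} (count of
#'   \code{R0 = 0} resamples), \code{B}, \code{seed}, \code{label},
#'   \code{N}.
#' @examples
#' co <- generate_cohort(preset_config("outbred", 1, n = 40, seed = 1))
#' bt <- bootstrap_lifetable(co, B = 200, seed = 7)
#' summary(bt)
#' @export
bootstrap_lifetable <- function(x, B = 10000, seed = NULL, tol = 1e-10) {
  validate_cohort(x)
  if (B < 1) stop("B must be a positive integer")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  m <- cohort_matrices(x)
  N <- x$N
  eggs  <- m$eggs
  idx <- .with_seed(seed, function()
    matrix(sample.int(N, N * B, replace = TRUE), nrow = B))
  par_names <- c("r", "lambda", "R0", "T")
  est <- matrix(NA_real_, nrow = B, ncol = 4L,
                dimnames = list(NULL, par_names))
  for (b in seq_len(B)) {
    lxmx <- colSums(eggs[idx[b, ], , drop = FALSE]) / N
    est[b, ] <- .params_from_lxmx(lxmx, tol = tol)
  }
  flagged <- sum(est[, "R0"] == 0)
  if (flagged > 0)
    warning(flagged, " of ", B,
            " resamples had R0 = 0; r, lambda and T are excluded there")
  point <- .params_from_lxmx(schedules(age_stage_table(x))$lxmx, tol = tol)
  structure(list(estimate = point,
                 estimates = est,
                 boot_mean = colMeans(est, na.rm = TRUE),
                 boot_se = apply(est, 2, stats::sd, na.rm = TRUE),
                 flagged = flagged, B = B, seed = seed,
                 label = x$label, N = N),
            class = "lifetable_boot")
}

#' @export
print.lifetable_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap of demographic parameters",
      if (nzchar(x$label)) paste0("('", x$label, "')"), "\n")
  cat("  N =", x$N, "; B =", x$B, "resamples; seed =", x$seed,
      if (x$flagged > 0) paste0("; ", x$flagged, " resamples with R0 = 0"),
      "\n")
  tab <- cbind(estimate = x$estimate, boot_mean = x$boot_mean,
               boot_se = x$boot_se)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.lifetable_boot <- function(object, ...) {
  print(object, ...)
}

#' @export
coef.lifetable_boot <- function(object, ...) object$estimate

#' @export
as.data.frame.lifetable_boot <- function(x, ...) {
  data.frame(group = x$label, parameter = names(x$estimate),
             estimate = unname(x$estimate),
             boot_mean = unname(x$boot_mean),
             boot_se = unname(x$boot_se),
             B = x$B, flagged_count = x$flagged, row.names = NULL)
}

#' Compare one demographic parameter between two bootstrapped cohorts
#'
#' Welch-style two-sample test on the bootstrap means:
#' \code{z = (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)}, with a two-sided
#' p-value from the normal reference (the bootstrap SEs are computed from
#' large \code{B}, so no degrees-of-freedom choice is imposed).  When both
#' SEs are zero, \code{p = 1} for equal means and \code{p = 0} otherwise.
#'
#' @param a,b \code{"lifetable_boot"} objects for the two groups.
#' @param parameters Which parameters to compare (default all four).
#' @param alpha Significance level for the \code{sig} flag.
#' @return A data frame with one row per parameter: \code{group_a},
#'   \code{group_b}, \code{parameter}, \code{diff}, \code{se}, \code{stat},
#'   \code{p}, \code{sig}, \code{procedure}.
#' @export
compare_params <- function(a, b, parameters = c("r", "lambda", "R0", "T"),
                           alpha = 0.05) {
  stopifnot(inherits(a, "lifetable_boot"), inherits(b, "lifetable_boot"))
  rows <- lapply(parameters, function(p) {
    d  <- a$boot_mean[[p]] - b$boot_mean[[p]]
    se <- sqrt(a$boot_se[[p]]^2 + b$boot_se[[p]]^2)
    if (se == 0) {
      z <- if (d == 0) 0 else sign(d) * Inf
      pv <- if (d == 0) 1 else 0
    } else {
      z <- d / se
      pv <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group_a = a$label, group_b = b$label, parameter = p,
               diff = d, se = se, stat = z, p = pv, sig = pv < alpha,
               procedure = "two_sample_z", row.names = NULL)
  })
  do.call(rbind, rows)
}

# greedy compact-letter display: groups ordered by decreasing mean; maximal
# runs of mutually "not significantly different from the run anchor" share
# a letter; runs contained in an earlier run are dropped
.cld_letters <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  runs <- list()
  covered <- 0L
  for (i in seq_len(k)) {
    j <- i
    while (j < k && pmat[ord[i], ord[j + 1L]] >= alpha) j <- j + 1L
    if (j > covered || i == 1L) {
      runs[[length(runs) + 1L]] <- i:j
      covered <- j
    }
    if (covered == k && i >= runs[[length(runs)]][1L]) break
  }
  letts <- character(k)
  for (ri in seq_along(runs))
    for (g in runs[[ri]])
      letts[ord[g]] <- paste0(letts[ord[g]], letters[ri])
  letts
}

#' Tukey-Kramer comparison of a parameter across several groups
#'
#' All pairwise comparisons of one bootstrapped parameter across \code{k}
#' groups, using the studentized-range reference: for groups \code{i, j}
#' the statistic is \code{q = |mean_i - mean_j| / sqrt((se_i^2 + se_j^2)/2)}
#' referred to the studentized range distribution with \code{k} means and
#' \code{B - 1} degrees of freedom (the bootstrap sample size standing in
#' for a residual df).  A compact letter display is assigned greedily from
#' the largest mean: groups that are not significantly different share a
#' letter.
#'
#' @param groups A list of two or more \code{"lifetable_boot"} objects.
#' @param parameter One of \code{"r"}, \code{"lambda"}, \code{"R0"},
#'   \code{"T"}.
#' @param alpha Significance level for the letter display.
#' @return An object of class \code{"tukey_kramer"}: list with
#'   \code{comparisons} (data frame of all pairs: \code{diff}, \code{se},
#'   \code{stat}, \code{p}, \code{sig}) and \code{letters} (named character
#'   vector, one entry per group).
#' @export
tukey_kramer <- function(groups, parameter = "r", alpha = 0.05) {
  if (length(groups) < 2L)
    stop("tukey_kramer needs at least two groups")
  stopifnot(all(vapply(groups, inherits, logical(1), "lifetable_boot")),
            parameter %in% c("r", "lambda", "R0", "T"))
  k <- length(groups)
  labs <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labs))
    labs <- make.unique(labs)
  means <- vapply(groups, function(g) g$boot_mean[[parameter]], numeric(1))
  ses   <- vapply(groups, function(g) g$boot_se[[parameter]], numeric(1))
  df <- min(vapply(groups, function(g) g$B, numeric(1))) - 1
  pmat <- matrix(1, k, k, dimnames = list(labs, labs))
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se <- sqrt((ses[i]^2 + ses[j]^2) / 2)
    d <- means[i] - means[j]
    if (se == 0) {
      q <- if (d == 0) 0 else Inf
      pv <- if (d == 0) 1 else 0
    } else {
      q <- abs(d) / se
      pv <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    pmat[i, j] <- pmat[j, i] <- pv
    rows[[length(rows) + 1L]] <-
      data.frame(group_a = labs[i], group_b = labs[j],
                 parameter = parameter, diff = d, se = se, stat = q,
                 p = pv, sig = pv < alpha, procedure = "tukey_kramer",
                 row.names = NULL)
  }
  letts <- .cld_letters(means, pmat, alpha = alpha)
  names(letts) <- labs
  structure(list(comparisons = do.call(rbind, rows), letters = letts,
                 parameter = parameter, means = stats::setNames(means, labs),
                 alpha = alpha),
            class = "tukey_kramer")
}

#' @export
print.tukey_kramer <- function(x, digits = 4, ...) {
  cat("Tukey-Kramer comparison of", x$parameter, "across",
      length(x$letters), "groups (alpha =", x$alpha, ")\n")
  tab <- data.frame(mean = round(x$means, digits), letters = x$letters)
  print(tab)
  invisible(x)
}
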