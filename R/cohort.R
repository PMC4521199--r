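# Cohort container and CSV I/O for per-individual daily life-history records.

#' Life-cycle stage codes
#'
#' Integer codes used throughout the package for the four-stage insect life
#' cycle with a terminal sex branch at adult emergence: egg = 1, larva = 2,
#' pupa = 3, adult female = 4, adult male = 5.
#'
#' @format A named integer vector of length 5.
#' @export
stage_codes <- c(egg = 1L, larva = 2L, pupa = 3L, female = 4L, male = 5L)

# allowed next-day stage moves: stay, or advance one step; pupae branch to
# either adult sex; adults are terminal
.allowed_next <- list(`1` = c(1L, 2L), `2` = c(2L, 3L),
                      `3` = c(3L, 4L, 5L), `4` = 4L, `5` = 5L)

#' Construct a cohort of individual life-history records
#'
#' A cohort holds one record per started egg, each record being the
#' individual's complete daily trajectory from oviposition (age 0) to the
#' last day it was alive.  Death is implicit on the day after the record
#' ends.  Individuals dying before adulthood never carry a sex and remain in
#' the cohort denominator \code{N}, as required by two-sex life table
#' bookkeeping.
#'
#' @param individuals A list; each element a list with components \code{id}
#'   (character scalar), \code{stage} (integer vector of daily stage codes,
#'   see \code{\link{stage_codes}}, indexed by age in days from 0), and
#'   \code{eggs} (integer vector of eggs laid each day, same length).
#' @param label Free-text group tag, e.g. \code{"outbred_F1"}.
#' @return An object of class \code{"cohort"} with elements
#'   \code{individuals}, \code{label} and \code{N} (number of started eggs).
#' @examples
#' ind <- list(id = "a", stage = c(1L, 1L, 2L), eggs = c(0L, 0L, 0L))
#' co <- cohort(list(ind), label = "demo")
#' co$N
#' @export
cohort <- function(individuals, label = "") {
  x <- structure(list(individuals = individuals, label = as.character(label),
                      N = length(individuals)),
                 class = "cohort")
  validate_cohort(x)
  x
}

#' Validate a cohort object
#'
#' Checks the structural invariants of the record format: unique ids,
#' stage codes in 1..5 starting at egg, non-decreasing stage sequences that
#' only stay or advance one step (with the pupa -> female/male branch),
#' non-negative egg counts, and eggs laid only on adult-female days.
#'
#' @param x A \code{"cohort"} object.
#' @return \code{x}, invisibly.  Throws an error describing the first
#'   violated invariant, naming the offending individual.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ids <- vapply(x$individuals, function(i) as.character(i$id), character(1))
  if (anyDuplicated(ids))
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (x$N != length(x$individuals))
    stop("cohort N (", x$N, ") does not match number of records (",
         length(x$individuals), ")")
  for (ind in x$individuals) {
    s <- as.integer(ind$stage)
    e <- as.integer(ind$eggs)
    id <- ind$id
    if (length(s) < 1L)
      stop("individual '", id, "': empty record")
    if (length(e) != length(s))
      stop("individual '", id, "': eggs and stage sequences differ in length")
    if (any(s < 1L | s > 5L))
      stop("individual '", id, "': stage code outside 1..5")
    if (s[1L] != stage_codes[["egg"]])
      stop("individual '", id, "': record must start in the egg stage")
    if (length(s) > 1L) {
      for (k in seq_len(length(s) - 1L)) {
        if (!(s[k + 1L] %in% .allowed_next[[as.character(s[k])]]))
          stop("individual '", id, "': invalid stage move ", s[k], " -> ",
               s[k + 1L], " at age ", k - 1L)
      }
    }
    if (any(e < 0L))
      stop("individual '", id, "': negative egg count")
    if (any(e > 0L & s != stage_codes[["female"]]))
      stop("individual '", id, "': eggs recorded on a non-adult-female day")
  }
  invisible(x)
}

#' Read a cohort from a daily-record CSV file
#'
#' The on-disk format is one row per individual-day with header columns
#' \code{id}, \code{age_day} (integer days since oviposition, 0-based),
#' \code{stage} (integer code 1--5) and \code{eggs} (non-negative integer).
#' Rows for each individual must cover ages \code{0..k} with no gaps or
#' duplicates; the last row is the last day alive.
#'
#' @param path Path to a CSV file.
#' @param label Group tag attached to the cohort.
#' @return A validated \code{\link{cohort}}.
#' @seealso \code{\link{write_cohort}}
#' @export
read_cohort <- function(path, label = "") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age_day", "stage", "eggs")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("cohort file '", path, "' has no rows")
  d$id <- as.character(d$id)
  key <- paste(d$id, d$age_day, sep = "\r")
  if (anyDuplicated(key)) {
    k <- which(duplicated(key))[1L]
    stop("duplicate (id, age_day) row: id '", d$id[k], "', age ",
         d$age_day[k])
  }
  inds <- lapply(split(d, d$id), function(g) {
    g <- g[order(g$age_day), , drop = FALSE]
    if (!identical(as.integer(g$age_day), seq_len(nrow(g)) - 1L))
      stop("individual '", g$id[1L],
           "': age_day must run 0..k with no gaps")
    list(id = g$id[1L], stage = as.integer(g$stage),
         eggs = as.integer(g$eggs))
  })
  # preserve first-appearance order of ids
  inds <- inds[unique(d$id)]
  names(inds) <- NULL
  cohort(inds, label = label)
}

#' Write a cohort to a daily-record CSV file
#'
#' Inverse of \code{\link{read_cohort}}: one row per individual-day.
#'
#' @param x A \code{"cohort"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  parts <- lapply(x$individuals, function(i) {
    data.frame(id = rep(i$id, length(i$stage)),
               age_day = seq_along(i$stage) - 1L,
               stage = as.integer(i$stage),
               eggs = as.integer(i$eggs))
  })
  do.call(rbind, parts)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n  N =", x$N, "started eggs;",
      "max age", max(vapply(x$individuals, function(i) length(i$stage),
                            integer(1))) - 1L, "d\n")
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  life <- vapply(object$individuals, function(i) length(i$stage), integer(1))
  last <- vapply(object$individuals, function(i) i$stage[length(i$stage)],
                 integer(1))
  eggs <- vapply(object$individuals, function(i) sum(i$eggs), numeric(1))
  out <- list(label = object$label, N = object$N,
              mean_lifespan = mean(life),
              n_female = sum(last == stage_codes[["female"]]),
              n_male = sum(last == stage_codes[["male"]]),
              preadult_survival =
                sum(last >= stage_codes[["female"]]) / object$N,
              total_eggs = sum(eggs))
  class(out) <- "summary.cohort"
  out
}

#' @export
print.summary.cohort <- function(x, ...) {
  cat("Cohort", if (nzchar(x$label)) paste0("'", x$label, "'") else "", "\n")
  cat(sprintf("  N = %d; mean lifespan %.2f d (day of oviposition counted)\n",
              x$N, x$mean_lifespan))
  cat(sprintf("  reached adulthood: %d female, %d male (pre-adult survival %.3f)\n",
              x$n_female, x$n_male, x$preadult_survival))
  cat(sprintf("  total eggs laid: %d\n", as.integer(x$total_eggs)))
  invisible(x)
}

# Dense N x (A+1) matrices over cohort ages 0..A: stage code (0 = dead) and
# eggs laid.  Backbone for tabulation and the bootstrap fast path.
cohort_matrices <- function(x) {
  life <- vapply(x$individuals, function(i) length(i$stage), integer(1))
  A <- max(life)                       # number of observed days
  S <- matrix(0L, nrow = x$N, ncol = A)
  E <- matrix(0L, nrow = x$N, ncol = A)
  for (i in seq_len(x$N)) {
    k <- life[i]
    S[i, seq_len(k)] <- as.integer(x$individuals[[i]]$stage)
    E[i, seq_len(k)] <- as.integer(x$individuals[[i]]$eggs)
  }
  list(stage = S, eggs = E, lifespan = life, ages = seq_len(A) - 1L)
}
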