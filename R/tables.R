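# CSV export of fitted life tables: age-specific schedule, age x stage
# matrices, and the scalar parameter table.

.write_matrix_long <- function(m, ages, path) {
  d <- data.frame(age = rep(ages, times = ncol(m)),
                  stage = rep(seq_len(ncol(m)), each = length(ages)),
                  value = as.vector(m))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

.read_matrix_long <- function(path) {
  d <- utils::read.csv(path)
  A <- max(d$age) + 1L
  m <- matrix(NA_real_, nrow = A, ncol = 5L,
              dimnames = list(age = 0:(A - 1L), stage = names(stage_codes)))
  m[cbind(d$age + 1L, d$stage)] <- d$value
  m
}

#' Write a fitted life table to a directory of CSV files
#'
#' Writes \code{schedule.csv} (one row per age: \code{age, lx, mx, lxmx}),
#' one long-format CSV per age-stage matrix (\code{sxj.csv},
#' \code{exj.csv}, \code{vxj.csv}; columns \code{age, stage, value},
#' \code{NA} for unoccupied cells of \code{exj}/\code{vxj}), and
#' \code{params.csv} (\code{parameter, estimate}).  Re-reading with
#' \code{\link{read_lifetable_tables}} reproduces all values to at least 12
#' significant digits.
#'
#' @param x A \code{"lifetable"} from \code{\link{lifetable}}.
#' @param dir Output directory; created if missing.
#' @return \code{dir}, invisibly.
#' @export
write_lifetable <- function(x, dir) {
  stopifnot(inherits(x, "lifetable"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", dir, "'")
  utils::write.csv(x$schedule, file.path(dir, "schedule.csv"),
                   row.names = FALSE, quote = FALSE)
  ages <- x$table$ages
  .write_matrix_long(x$table$sxj, ages, file.path(dir, "sxj.csv"))
  .write_matrix_long(x$exj, ages, file.path(dir, "exj.csv"))
  .write_matrix_long(x$vxj, ages, file.path(dir, "vxj.csv"))
  utils::write.csv(
    data.frame(parameter = c("r", "lambda", "R0", "T"),
               estimate = c(x$r, x$lambda, x$R0, x$T)),
    file.path(dir, "params.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read back the CSV tables written by \code{write_lifetable}
#'
#' @param dir Directory written by \code{\link{write_lifetable}}.
#' @return A list with \code{schedule} (data frame), matrices \code{sxj},
#'   \code{exj}, \code{vxj}, and \code{params} (named numeric vector).
#' @export
read_lifetable_tables <- function(dir) {
  params <- utils::read.csv(file.path(dir, "params.csv"))
  list(schedule = utils::read.csv(file.path(dir, "schedule.csv")),
       sxj = .read_matrix_long(file.path(dir, "sxj.csv")),
       exj = .read_matrix_long(file.path(dir, "exj.csv")),
       vxj = .read_matrix_long(file.path(dir, "vxj.csv")),
       params = stats::setNames(params$estimate, params$parameter))
}
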