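# Internal helpers: seeded RNG scoping, clipping, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit, so seeded operations never disturb the
#' session RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Append a timestamped line to the pipeline log
#'
#' Every exclusion, split, and flag decision in the pipeline is recorded
#' through this hook. Lines are appended to the file named by
#' `options(estrocycle.logfile = ...)`; when unset, messages are emitted only
#' if `options(estrocycle.verbose = TRUE)`.
#'
#' @param fmt `sprintf` format string.
#' @param ... Values interpolated into `fmt`.
#' @return Invisibly, the formatted line.
#' @export
ec_log <- function(fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  logfile <- getOption("estrocycle.logfile", NULL)
  if (!is.null(logfile)) {
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
  } else if (isTRUE(getOption("estrocycle.verbose", FALSE))) {
    message(line)
  }
  invisible(line)
}
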