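# Internal helpers: structured logging and small numeric utilities.

.np_state <- new.env(parent = emptyenv())

#' Collect structured log records
#'
#' While a collector is active (as during [run_pipeline()]), log records are
#' accumulated and returned with the run manifest; otherwise they are emitted
#' as conditions (`message()` for info, `warning()` for warnings).
#'
#' @param stage character scalar naming the pipeline stage.
#' @param level one of `"info"`, `"warning"`, `"error"`.
#' @param msg message text.
#' @keywords internal
np_log <- function(stage, level = "info", msg) {
  rec <- list(stage = stage, level = level, message = msg)
  if (!is.null(.np_state$log)) {
    .np_state$log[[length(.np_state$log) + 1L]] <- rec
  }
  if (identical(level, "warning")) {
    warning(sprintf("[%s] %s", stage, msg), call. = FALSE)
  } else {
    message(sprintf("[%s] %s", stage, msg))
  }
  invisible(rec)
}

np_log_start <- function() {
  .np_state$log <- list()
  invisible(NULL)
}

np_log_drain <- function() {
  out <- .np_state$log
  .np_state$log <- NULL
  if (is.null(out)) out <- list()
  out
}

# log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# run `expr` under a private RNG stream so callers' .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
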