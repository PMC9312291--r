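#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a key
#'
#' All randomness in the package flows from one integer seed; independent
#' stages (subjects, regions, permutations) draw from child streams derived
#' deterministically from the master seed and a string key, so that adding
#' or reordering stages does not perturb the others.
#'
#' @param seed master integer seed.
#' @param ... character or numeric keys naming the child stream.
#' @return an integer in [0, 2^31).
#' @export
child_seed <- function(seed, ...) {
  keys <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (cc in utf8ToInt(keys)) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# shared structured log: functions append condition-free notes a pipeline
# run can collect (dropped voxels, excluded samples, ...)
log_env <- new.env(parent = emptyenv())
log_env$messages <- character(0)

log_note <- function(...) {
  msg <- sprintf(...)
  log_env$messages <- c(log_env$messages, msg)
  invisible(msg)
}

#' Retrieve and optionally clear the package's structured log
#' @param clear logical; reset the log after reading.
#' @return character vector of log messages.
#' @export
get_log <- function(clear = FALSE) {
  msgs <- log_env$messages
  if (clear) log_env$messages <- character(0)
  msgs
}
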