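# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

ex_log <- function(level = c("info", "warn", "error"), ...) {
  level <- match.arg(level)
  msg <- paste0("[exclutax ", level, "] ", paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

ex_stop <- function(...) stop(paste0(...), call. = FALSE)

ex_warn <- function(...) warning(paste0(...), call. = FALSE)

# run expr with the RNG seeded from `seed`, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0

fmt_num <- function(x) formatC(x, digits = 10, format = "g")
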