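# Internal helpers shared across modules.

#' @importFrom stats optimize rexp runif setNames p.adjust pgamma qgamma
#'   fisher.test
#' @importFrom utils write.table read.table
NULL

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_pe <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "paleoenrich_error")))
}

# Column-wise maximum of a matrix without apply() overhead.
col_max <- function(m) {
  do.call(pmax, c(as.data.frame(t(m)), list(na.rm = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
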