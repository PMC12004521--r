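#' @importFrom rlang abort .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows count n distinct rename across
#' @importFrom purrr map map_dbl map_chr map2 pmap imap
#' @importFrom stats sd var acf prcomp rnorm runif setNames qchisq
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_hd <- function(msg, class) {
  abort(msg, class = c(class, "haplodyn_error"))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_hd(sprintf("`%s` must be a single finite number.", name),
            "invalid_spec_error")
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop_hd(sprintf("`%s` = %g is outside [%g, %g].", name, x, lower, upper),
            "invalid_spec_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
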