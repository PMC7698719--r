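# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with `set.seed(seed)` while leaving the caller's global RNG
#' state untouched. Every stochastic operation in the package routes its
#' randomness through this helper so that no function mutates global state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Cumulative trapezoid integral
#'
#' `cumtrapz(t, y)[i]` is the trapezoid-rule integral of `y` over `t[1]..t[i]`.
#' This single quadrature rule is shared by the forward kinetic model and the
#' Patlak inversion so that the round trip is exact.
#'
#' @param t Strictly increasing numeric vector.
#' @param y Numeric vector, same length as `t`.
#' @return Numeric vector of cumulative integrals, first element 0.
#' @export
cumtrapz <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 1L)
  if (length(t) == 1L) return(0)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  c(0, cumsum(diff(t) * (y[-length(y)] + y[-1]) / 2))
}

# R^2 of a fitted lm without summary.lm's perfect-fit warning;
# SST == 0 (constant response fitted exactly) reports 1
r_squared_of <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
}

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# assert scalar finite numeric
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("`%s` must be a finite numeric scalar", name)
  }
  invisible(x)
}
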