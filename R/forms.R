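#' Elementary kinetic rate forms
#'
#' Constructor for the catalogue of elementary kinetic rate laws from which
#' every cellular process in a compartment model is assembled. Supported
#' kinds and their parameters:
#'
#' * `zero_order`: constant rate `k` (cells/day),
#' * `first_order`: `k * X` with rate constant `k` (1/day),
#' * `exponential_saturating`: `k * (1 - exp(-X / theta))`, zero at `X = 0`
#'   and plateauing at `k` (cells/day) with scale `theta` (cells),
#' * `michaelis_menten`: `vmax * X / (km + X)`,
#' * `hill`: `vmax * X^h / (k^h + X^h)` with Hill coefficient `h >= 1`.
#'
#' All parameters must be nonnegative; saturation constants (`km`, `k` of the
#' hill form, `theta`) must be strictly positive. A hill form with `h = 1` is
#' identical to a Michaelis-Menten form with `km = k`.
#'
#' @param type character; one of `"zero_order"`, `"first_order"`,
#'   `"exponential_saturating"`, `"michaelis_menten"`, `"hill"`.
#'   (Named `type` rather than `kind` so that the parameter `k` of several
#'   forms cannot partially match the formal argument.)
#' @param ... named numeric parameters for the chosen type (see above).
#' @return An object of class `rate_form`.
#' @examples
#' f <- rate_form("michaelis_menten", vmax = 5, km = 10)
#' eval_rate(f, 10) # half-saturation: 2.5
#' @export
rate_form <- function(type, ...) {
  kind <- match.arg(type, c("zero_order", "first_order",
                            "exponential_saturating", "michaelis_menten",
                            "hill"))
  params <- c(...)
  required <- .form_param_names(kind)
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop("rate_form '", kind, "' requires parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[required]
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("rate_form parameters must be finite and nonnegative", call. = FALSE)
  }
  if (kind == "hill" && params[["h"]] < 1) {
    stop("hill coefficient h must be >= 1", call. = FALSE)
  }
  structure(list(kind = kind, params = as.list(params)),
            class = "rate_form")
}

.form_param_names <- function(kind) {
  switch(kind,
         zero_order = "k",
         first_order = "k",
         exponential_saturating = c("k", "theta"),
         michaelis_menten = c("vmax", "km"),
         hill = c("vmax", "k", "h"))
}

#' @export
print.rate_form <- function(x, ...) {
  cat("<rate_form> ", x$kind, ": ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a kinetic rate form
#'
#' @param form a [rate_form()].
#' @param X nonnegative cell count (vectorized).
#' @return rate in cells/day, finite and `>= 0`.
#' @export
eval_rate <- function(form, X) {
  stopifnot(inherits(form, "rate_form"))
  if (any(!is.finite(X)) || any(X < 0)) {
    stop("eval_rate: X must be finite and >= 0", call. = FALSE)
  }
  p <- form$params
  switch(form$kind,
         zero_order = rep_len(p$k, length(X)),
         first_order = p$k * X,
         exponential_saturating = .eval_expsat(p$k, p$theta, X),
         michaelis_menten = .eval_mm(p$vmax, p$km, X),
         hill = .eval_hill(p$vmax, p$k, p$h, X))
}

.eval_expsat <- function(k, theta, X) {
  if (theta <= 0) stop("exponential_saturating: theta must be > 0",
                       call. = FALSE)
  k * (1 - exp(-X / theta))
}

.eval_mm <- function(vmax, km, X) {
  if (km <= 0) stop("michaelis_menten: km must be > 0", call. = FALSE)
  vmax * X / (km + X)
}

.eval_hill <- function(vmax, k, h, X) {
  if (k <= 0) stop("hill: k must be > 0", call. = FALSE)
  # compute in ratio form to avoid overflow of X^h for large X
  r <- (X / k)^h
  out <- vmax * r / (1 + r)
  out[is.infinite(r)] <- vmax
  out[X == 0] <- 0
  out
}

#' Hill-type leukemic-influence modifier
#'
#' A dimensionless multiplier `K(L)` on a base kinetic rate encoding how the
#' leukemic burden `L` alters a normal-cell process. Directions:
#'
#' * `suppressive`: `K(L) = 1 / (1 + w * (L / theta_L)^h_L)`, in `(0, 1]`,
#'   monotone non-increasing in `L`. The coupling weight `w` (default 1)
#'   switches the influence off completely when set to 0.
#' * `stimulative`: `K(L) = 1 + beta * L^h_L / (theta_L^h_L + L^h_L)`, in
#'   `[1, 1 + beta]`, monotone non-decreasing.
#' * `none`: `K == 1` regardless of parameters.
#'
#' `K(0) = 1` exactly for every direction (control limit).
#'
#' @param direction `"suppressive"`, `"stimulative"` or `"none"`.
#' @param theta_L leukemic half-influence threshold (cells, > 0).
#' @param h_L Hill coefficient (dimensionless, >= 1).
#' @param beta stimulation strength (>= 0; stimulative only).
#' @param w coupling weight in `[0, 1]` (suppressive only).
#' @return An object of class `leuk_modifier`.
#' @export
leuk_modifier <- function(direction = c("none", "suppressive", "stimulative"),
                          theta_L = 1, h_L = 1, beta = 0, w = 1) {
  direction <- match.arg(direction)
  if (direction != "none") {
    if (!is.finite(theta_L) || theta_L <= 0) {
      stop("leuk_modifier: theta_L must be > 0", call. = FALSE)
    }
    if (!is.finite(h_L) || h_L < 1) {
      stop("leuk_modifier: h_L must be >= 1", call. = FALSE)
    }
  }
  if (direction == "stimulative" && (!is.finite(beta) || beta < 0)) {
    stop("leuk_modifier: beta must be >= 0", call. = FALSE)
  }
  if (direction == "suppressive" && (!is.finite(w) || w < 0)) {
    stop("leuk_modifier: w must be >= 0", call. = FALSE)
  }
  structure(list(direction = direction, theta_L = theta_L, h_L = h_L,
                 beta = beta, w = w),
            class = "leuk_modifier")
}

#' @export
print.leuk_modifier <- function(x, ...) {
  if (x$direction == "none") {
    cat("<leuk_modifier> none (K == 1)\n")
  } else {
    cat("<leuk_modifier> ", x$direction,
        ": theta_L=", x$theta_L, ", h_L=", x$h_L,
        if (x$direction == "stimulative") paste0(", beta=", x$beta)
        else paste0(", w=", x$w),
        "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate a leukemic-influence modifier
#'
#' @param mod a [leuk_modifier()].
#' @param L nonnegative leukemic cell count (vectorized).
#' @return multiplier `K(L)`; `K(0)` is exactly 1.
#' @export
eval_modifier <- function(mod, L) {
  stopifnot(inherits(mod, "leuk_modifier"))
  if (any(!is.finite(L)) || any(L < 0)) {
    stop("eval_modifier: L must be finite and >= 0", call. = FALSE)
  }
  if (mod$direction == "none") return(rep_len(1, length(L)))
  if (mod$direction == "suppressive") {
    if (mod$w == 0) return(rep_len(1, length(L)))
    out <- 1 / (1 + mod$w * (L / mod$theta_L)^mod$h_L)
    out[L == 0] <- 1
    return(out)
  }
  # stimulative
  if (mod$beta == 0) return(rep_len(1, length(L)))
  r <- (L / mod$theta_L)^mod$h_L
  out <- 1 + mod$beta * r / (1 + r)
  out[is.infinite(r)] <- 1 + mod$beta
  out[L == 0] <- 1
  out
}

#' Leukemia-modified kinetic rate
#'
#' The product `eval_rate(form, X) * eval_modifier(mod, L)`; with a `none`
#' modifier this equals the unmodified base rate.
#'
#' @inheritParams eval_rate
#' @inheritParams eval_modifier
#' @export
modified_rate <- function(form, mod, X, L) {
  eval_rate(form, X) * eval_modifier(mod, L)
}
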