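# Compilation of a model_spec into a flat numerical representation that the
# ODE right-hand side and the decomposition evaluate quickly.

.FORM_KINDS <- c(zero_order = 1L, first_order = 2L,
                 exponential_saturating = 3L, michaelis_menten = 4L,
                 hill = 5L)

compile_model <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(params)) spec <- set_params(spec, params)
  states <- names(spec$init)
  n <- length(states)
  P <- length(spec$processes)
  idx <- function(s) if (is.null(s)) 0L else match(s, states)
  isrc <- integer(P); isnk <- integer(P); idrv <- integer(P)
  ibur <- integer(P)
  fkind <- integer(P); fp <- matrix(0, 3, P)
  mkind <- integer(P); mp <- matrix(0, 3, P)  # rows: w/beta, theta_L, h_L
  gate <- logical(P)
  for (i in seq_len(P)) {
    p <- spec$processes[[i]]
    isrc[i] <- idx(p$source); isnk[i] <- idx(p$sink); idrv[i] <- idx(p$driver)
    ibur[i] <- if (is.null(p$burden)) 0L
               else if (p$burden == "forcing") -1L else idx(p$burden)
    fkind[i] <- .FORM_KINDS[[p$form$kind]]
    fv <- unlist(p$form$params)
    fp[seq_along(fv), i] <- fv
    mkind[i] <- match(p$modifier$direction,
                      c("none", "suppressive", "stimulative")) - 1L
    if (mkind[i] == 1L) mp[, i] <- c(p$modifier$w, p$modifier$theta_L,
                                     p$modifier$h_L)
    if (mkind[i] == 2L) mp[, i] <- c(p$modifier$beta, p$modifier$theta_L,
                                     p$modifier$h_L)
    gate[i] <- p$gate
  }
  S <- matrix(0, n, P, dimnames = list(states, names(spec$processes)))
  for (i in seq_len(P)) {
    if (isrc[i] > 0L) S[isrc[i], i] <- S[isrc[i], i] - 1
    if (isnk[i] > 0L) S[isnk[i], i] <- S[isnk[i], i] + 1
  }
  ffun <- NULL
  if (any(ibur == -1L)) {
    if (is.null(spec$forcing)) .stopf("model needs a forcing but none is set")
    if (all(spec$forcing$values == 0)) {
      ffun <- function(t) rep_len(0, length(t))
    } else {
      sf <- stats::splinefun(spec$forcing$times, spec$forcing$values,
                             method = "monoH.FC")
      ffun <- function(t) pmax(sf(t), 0)
    }
  }
  list(states = states, n = n, P = P, S = S,
       isrc = isrc, isnk = isnk, idrv = idrv, ibur = ibur,
       fkind = fkind, mkind = mkind, gate = gate,
       # flat per-process parameter vectors for the fast rate kernel
       fp1 = fp[1, ], fp2 = fp[2, ], fp3 = fp[3, ],
       mp1 = mp[1, ], mp2 = mp[2, ], mp3 = mp[3, ],
       i_zero = which(fkind == 1L), i_first = which(fkind == 2L),
       i_expsat = which(fkind == 3L), i_mm = which(fkind == 4L),
       i_hill = which(fkind == 5L),
       i_supp = which(mkind == 1L), i_stim = which(mkind == 2L),
       idrv1 = pmax(idrv, 1L), ibur1 = pmax(ibur, 1L),
       gate_idx = which(gate),
       forcing = ffun, init = spec$init)
}

# Per-process rates at state x (clipped at zero) and time t.
.process_rates <- function(cm, x, t) {
  x[x < 0] <- 0
  r <- numeric(cm$P)
  drv <- x[cm$idrv1]
  i <- cm$i_zero
  if (length(i)) r[i] <- cm$fp1[i]
  i <- cm$i_first
  if (length(i)) r[i] <- cm$fp1[i] * drv[i]
  i <- cm$i_expsat
  if (length(i)) r[i] <- cm$fp1[i] * (1 - exp(-drv[i] / cm$fp2[i]))
  i <- cm$i_mm
  if (length(i)) r[i] <- cm$fp1[i] * drv[i] / (cm$fp2[i] + drv[i])
  i <- cm$i_hill
  if (length(i)) {
    ratio <- (drv[i] / cm$fp2[i])^cm$fp3[i]
    out <- cm$fp1[i] * ratio / (1 + ratio)
    bad <- is.infinite(ratio)
    if (any(bad)) out[bad] <- cm$fp1[i][bad]
    r[i] <- out
  }
  if (length(cm$i_supp) || length(cm$i_stim)) {
    L <- x[cm$ibur1]
    if (!is.null(cm$forcing)) L[cm$ibur == -1L] <- cm$forcing(t)
    i <- cm$i_supp
    if (length(i)) {
      K <- 1 / (1 + cm$mp1[i] * (L[i] / cm$mp2[i])^cm$mp3[i])
      K[cm$mp1[i] == 0 | L[i] == 0] <- 1
      r[i] <- r[i] * K
    }
    i <- cm$i_stim
    if (length(i)) {
      ratio <- (L[i] / cm$mp2[i])^cm$mp3[i]
      K <- 1 + cm$mp1[i] * ratio / (1 + ratio)
      bad <- is.infinite(ratio)
      if (any(bad)) K[bad] <- 1 + cm$mp1[i][bad]
      K[L[i] == 0] <- 1
      r[i] <- r[i] * K
    }
  }
  if (length(cm$gate_idx)) {
    g <- cm$gate_idx
    r[g][x[cm$isrc[g]] <= 0] <- 0
  }
  r
}

#' Build the model right-hand side
#'
#' Returns the derivative function of the assembled system: for each
#' population, the signed sum of its process rates (gains minus losses),
#' i.e. `dX/dt = f_Prolif - f_Death - f_Export + f_Import` (plus the
#' expansion/differentiation/G0 terms of the sub-models).
#'
#' @param spec a [model_spec()].
#' @param params optional named parameter vector overriding the spec's
#'   current values.
#' @return `function(t, y)` returning the named vector of rates (cells/day).
#' @export
build_rhs <- function(spec, params = NULL) {
  cm <- compile_model(spec, params)
  function(t, y) {
    if (length(y) != cm$n) .stopf("state vector must have %d entries", cm$n)
    dy <- as.vector(cm$S %*% .process_rates(cm, y, t))
    names(dy) <- cm$states
    dy
  }
}
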