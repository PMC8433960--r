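#' Optimizer state for the Adam family
#'
#' Holds the per-parameter first moment `m`, second moment `u`, and (for the
#' DGrad family) the moving average `avg` of element-wise squared gradients,
#' plus the step counter `t`. The counter counts optimizer updates and starts
#' at 1 on the first update; the same `t` drives bias correction and, for
#' DecayDGrad, the impulse and global decay factors.
#'
#' Defaults follow the training settings used throughout the pipeline:
#' first-moment decay `rho1 = 0.9`, second-moment decay `rho2 = 0.99`,
#' learning rate `lr = 1e-4`, `eps = 1e-8`, impulse period `s = 10`,
#' decay-center fraction `c = 0.25`, planned iterations `niter = 3000`.
#'
#' @param method one of `"adam"`, `"dgrad"`, `"decaydgrad"`.
#' @param lr learning rate.
#' @param rho1,rho2 exponential decay rates of the two moments.
#' @param eps divide-by-zero guard.
#' @param s impulse period in iterations (DecayDGrad).
#' @param c fraction of `niter` at which the global decay peaks (DecayDGrad).
#' @param niter total planned training iterations (DecayDGrad).
#' @param avg_mode `"sq_grad"` (default) tracks the moving average of
#'   element-wise squared gradients, the literal definition; `"grad"`
#'   tracks the moving average of raw gradients instead.
#' @return An object of class `optimizer_state`.
#' @export
optimizer_state <- function(method = c("adam", "dgrad", "decaydgrad"),
                            lr = 1e-4, rho1 = 0.9, rho2 = 0.99, eps = 1e-8,
                            s = 10L, c = 0.25, niter = 3000L,
                            avg_mode = c("sq_grad", "grad")) {
  method <- match.arg(method)
  avg_mode <- match.arg(avg_mode)
  if (s < 1L) stop("s must be >= 1")
  if (niter < 1L) stop("niter must be >= 1")
  structure(
    list(method = method, lr = lr, rho1 = rho1, rho2 = rho2, eps = eps,
         s = as.integer(s), c = c, niter = as.integer(niter),
         avg_mode = avg_mode, t = 0L, m = list(), u = list(), avg = list()),
    class = "optimizer_state"
  )
}

check_grads <- function(grads) {
  for (nm in names(grads)) {
    if (any(!is.finite(grads[[nm]])))
      stop("non-finite gradient for parameter '", nm, "'")
  }
}

# Shared moment bookkeeping: increments t, updates m/u (and avg when asked),
# and returns bias-corrected mhat/uhat per parameter tensor.
update_moments <- function(state, grads, with_avg) {
  check_grads(grads)
  state$t <- state$t + 1L
  mhat <- list(); uhat <- list()
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m_prev <- if (is.null(state$m[[nm]])) g * 0 else state$m[[nm]]
    u_prev <- if (is.null(state$u[[nm]])) g * 0 else state$u[[nm]]
    state$m[[nm]] <- state$rho1 * m_prev + (1 - state$rho1) * g
    state$u[[nm]] <- state$rho2 * u_prev + (1 - state$rho2) * g^2
    mhat[[nm]] <- state$m[[nm]] / (1 - state$rho1^state$t)
    uhat[[nm]] <- state$u[[nm]] / (1 - state$rho2^state$t)
    if (with_avg) {
      a_prev <- if (is.null(state$avg[[nm]])) g * 0 else state$avg[[nm]]
      tracked <- if (state$avg_mode == "sq_grad") g^2 else g
      state$avg[[nm]] <- state$rho2 * a_prev + (1 - state$rho2) * tracked
    }
  }
  list(state = state, mhat = mhat, uhat = uhat)
}

#' One Adam update
#'
#' Moments `m_t = rho1*m_{t-1} + (1-rho1)*g_t` and
#' `u_t = rho2*u_{t-1} + (1-rho2)*g_t^2` with bias correction
#' `mhat = m_t/(1-rho1^t)`, `uhat = u_t/(1-rho2^t)`, then
#' `theta <- theta - lr * mhat / (sqrt(uhat) + eps)`, all element-wise.
#'
#' @param state an [optimizer_state()].
#' @param grads named list of gradient tensors (a subset of `params` names).
#' @param params named list of parameter tensors.
#' @return `list(params, state)` with updated values.
#' @export
adam_step <- function(state, grads, params) {
  up <- update_moments(state, grads, with_avg = FALSE)
  state <- up$state
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] -
      state$lr * up$mhat[[nm]] / (sqrt(up$uhat[[nm]]) + state$eps)
  }
  list(params = params, state = state)
}

#' DGrad modulation factor
#'
#' Updates the moving average `avg` of squared gradients, then computes the
#' absolute deviation `dag = |g - avg|`, normalizes it by its maximum over
#' the parameter tensor, and maps it through `Sig(4 * daghat)`. Components
#' where `dag = 0` get exactly 0.5; the maximal component gets
#' `Sig(4) ~= 0.982`. A tensor whose deviations are all zero (degenerate
#' maximum) is defined to have `daghat = 0` everywhere.
#'
#' @param state an [optimizer_state()]; its `avg` and `t` fields are
#'   advanced as a side effect of the returned state.
#' @param grads named list of gradient tensors.
#' @return `list(xi, state)`: `xi` is a named list of modulation tensors in
#'   `[0.5, Sig(4)]`.
#' @export
dgrad_modulation <- function(state, grads) {
  check_grads(grads)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    a_prev <- if (is.null(state$avg[[nm]])) g * 0 else state$avg[[nm]]
    tracked <- if (state$avg_mode == "sq_grad") g^2 else g
    state$avg[[nm]] <- state$rho2 * a_prev + (1 - state$rho2) * tracked
  }
  list(xi = modulation_from_avg(state, grads), state = state)
}

modulation_from_avg <- function(state, grads) {
  xi <- list()
  for (nm in names(grads)) {
    dag <- abs(grads[[nm]] - state$avg[[nm]])
    mx <- max(dag)
    daghat <- if (mx > 0) dag / mx else dag * 0
    xi[[nm]] <- sigmoid(4 * daghat)
  }
  xi
}

#' One DGrad update
#'
#' Adam moments and bias correction exactly as in [adam_step()], with the
#' update scaled element-wise by the modulation of [dgrad_modulation()]:
#' `theta <- theta - lr * xi * mhat / (sqrt(uhat) + eps)`.
#'
#' @inheritParams adam_step
#' @param xi_override optional named list replacing the computed modulation
#'   (used to study the reduction to Adam; `xi = 1` reproduces Adam).
#' @return `list(params, state)`.
#' @export
dgrad_step <- function(state, grads, params, xi_override = NULL) {
  up <- update_moments(state, grads, with_avg = TRUE)
  state <- up$state
  xi <- if (is.null(xi_override)) modulation_from_avg(state, grads)
        else xi_override
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] -
      state$lr * xi[[nm]] * up$mhat[[nm]] / (sqrt(up$uhat[[nm]]) + state$eps)
  }
  list(params = params, state = state)
}

#' Periodic impulse factor
#'
#' `imp_t = exp(-(2 * (t mod s) / s)^2)`, in (0, 1], with period `s` and
#' maximum 1 at every multiple of `s`. Locally attenuates the DGrad step
#' within each span of `s` iterations.
#'
#' @param t iteration counter (>= 0).
#' @param s period in iterations (>= 1).
#' @return numeric in (0, 1] (vectorized over `t`).
#' @export
impulse <- function(t, s = 10L) {
  if (any(s <= 0)) stop("s must be >= 1")
  exp(-(2 * (t %% s) / s)^2)
}

#' Global bell-shaped decay factor
#'
#' `d_t = exp(-2 * (t - c*niter)^2 / niter^2)`, in (0, 1], peaking at
#' `t = c * niter`. Keeps the effective learning rate high early in
#' training and lets it decay over the remaining iterations.
#'
#' @param t iteration counter.
#' @param c fraction of `niter` at which the factor peaks.
#' @param niter total planned iterations (>= 1).
#' @return numeric in (0, 1] (vectorized over `t`).
#' @export
global_decay <- function(t, c = 0.25, niter = 3000L) {
  if (any(niter <= 0)) stop("niter must be >= 1")
  exp(-2 * (t - c * niter)^2 / niter^2)
}

#' One DecayDGrad update
#'
#' Identical to [dgrad_step()] except that the modulation is additionally
#' multiplied by the scalar `impulse(t, s) * global_decay(t, c, niter)`
#' evaluated at the post-increment step counter `t = 1, 2, ...`.
#'
#' @inheritParams adam_step
#' @return `list(params, state)`.
#' @export
decaydgrad_step <- function(state, grads, params) {
  up <- update_moments(state, grads, with_avg = TRUE)
  state <- up$state
  xi <- modulation_from_avg(state, grads)
  scale <- impulse(state$t, state$s) *
    global_decay(state$t, state$c, state$niter)
  for (nm in names(grads)) {
    params[[nm]] <- params[[nm]] -
      state$lr * (xi[[nm]] * scale) * up$mhat[[nm]] /
        (sqrt(up$uhat[[nm]]) + state$eps)
  }
  list(params = params, state = state)
}

#' One update with the state's configured method
#'
#' Dispatches to [adam_step()], [dgrad_step()] or [decaydgrad_step()].
#'
#' @inheritParams adam_step
#' @return `list(params, state)`.
#' @export
optimizer_step <- function(state, grads, params) {
  switch(state$method,
    adam = adam_step(state, grads, params),
    dgrad = dgrad_step(state, grads, params),
    decaydgrad = decaydgrad_step(state, grads, params))
}

#' Trace of the DecayDGrad schedule factors
#'
#' Evaluates `imp_t`, `d_t` and their product over `t = 1..niter`, the
#' curves that shape the DecayDGrad learning-rate schedule.
#'
#' @param niter number of iterations to trace.
#' @param s impulse period.
#' @param c decay-center fraction.
#' @return `data.frame(t, imp, d, imp_d)`.
#' @export
optimizer_trace <- function(niter = 3000L, s = 10L, c = 0.25) {
  t <- seq_len(niter)
  imp <- impulse(t, s)
  d <- global_decay(t, c, niter)
  data.frame(t = t, imp = imp, d = d, imp_d = imp * d)
}
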