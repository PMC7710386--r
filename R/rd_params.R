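#' Kinetic parameters of the two-factor reaction-diffusion system
#'
#' The reaction kinetics are linear with clipped synthesis terms:
#' \deqn{f(u, v) = \mathrm{clip}(Au + Bv + C, 0, synU_{max}) - Du}
#' \deqn{g(u, v) = \mathrm{clip}(Eu - F, 0, synV_{max}) - Gv}
#' where `u` is the pigment ("core") factor and `v` its long-range
#' antagonist. `R` is a global reaction-rate multiplier applied to both
#' kinetics during integration. Defaults are the standard parameter set for
#' this model class; `C` is the free knob that moves the system between the
#' dark-spot, labyrinth and light-spot regimes (see
#' [calibrate_c_endpoints()]).
#'
#' Sign convention: `B` is the coefficient of `v` in the synthesis of `u`
#' and must be negative for `v` to act as the inhibitor (the default is
#' `-0.08`; the magnitude 0.08 is the standard value). With `B >= 0` the
#' kinetics have no negative feedback loop and the uniform state is stable
#' for any diffusion ratio, so no Turing pattern can form.
#'
#' @param A,B,C,D,E,F,G Reaction coefficients (dimensionless).
#' @param synUmax,synVmax Upper clip limits for the synthesis terms of `u`
#'   and `v` (both must be positive).
#' @param R Reaction rate multiplier (positive).
#' @return An object of class `kinetic_params` (named list).
#' @export
#' @examples
#' kp <- kinetic_params(C = 0.02)
#' reaction(0, 0, kp)
kinetic_params <- function(A = 0.08, B = -0.08, C = 0, D = 0.03, E = 0.1,
                           F = 0.12, G = 0.06,
                           synUmax = 0.23, synVmax = 0.5, R = 80) {
  stopifnot(synUmax > 0, synVmax > 0, R > 0)
  structure(list(A = A, B = B, C = C, D = D, E = E, F = F, G = G,
                 synUmax = synUmax, synVmax = synVmax, R = R),
            class = "kinetic_params")
}

#' Diffusion coefficients
#'
#' @param Du,Dv Diffusion coefficients of the two factors. Turing pattern
#'   formation requires `Dv > Du > 0` (long-range inhibition).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(Du = 0.5, Dv = 10.0) {
  stopifnot(Du >= 0, Dv >= 0)
  structure(list(Du = Du, Dv = Dv), class = "diffusion_params")
}

clip01 <- function(x, hi) pmin(pmax(x, 0), hi)

#' Reaction kinetics with clipped synthesis
#'
#' Evaluates `f(u, v)` and `g(u, v)`. The synthesis terms `Au + Bv + C` and
#' `Eu - F` are clipped to `[0, synUmax]` and `[0, synVmax]` *before* the
#' linear decay terms `Du` and `Gv` are subtracted. Vectorized over `u`, `v`
#' and over per-cell parameter vectors.
#'
#' @param u,v Concentrations (numeric vectors).
#' @param p A [kinetic_params()] object, or a list of per-cell parameter
#'   vectors with the same names (see [parameter_field()]).
#' @return A list with components `du` (= f) and `dv` (= g).
#' @export
reaction <- function(u, v, p) {
  synU <- clip01(p$A * u + p$B * v + p$C, p$synUmax)
  synV <- clip01(p$E * u - p$F, p$synVmax)
  list(du = synU - p$D * u, dv = synV - p$G * v)
}

#' Solve the clipped rest state of the kinetics
#'
#' Finds the spatially uniform fixed point `f(u*, v*) = g(u*, v*) = 0`,
#' accounting for the synthesis clipping: each of the two synthesis terms can
#' be on its linear branch, clipped at 0, or clipped at its maximum, giving
#' nine candidate linear systems. All consistent candidates are enumerated
#' and the (unique, for sensible parameters) self-consistent solution with
#' non-negative concentrations is returned.
#'
#' @param p A [kinetic_params()] object (scalar parameters).
#' @return Named numeric vector `c(u, v)` of the rest state.
#' @export
#' @examples
#' fp <- fixed_point(kinetic_params(C = 0.02))
#' unlist(reaction(fp[["u"]], fp[["v"]], kinetic_params(C = 0.02)))
fixed_point <- function(p) {
  branches <- c("lin", "lo", "hi")
  sols <- list()
  for (bu in branches) for (bv in branches) {
    # u-equation: synU - D u = 0; v-equation: synV - G v = 0
    # synU depends on branch: lin = A u + B v + C; lo = 0; hi = synUmax
    # Solve the resulting linear 2x2 system for (u, v).
    if (bv == "lin") {
      # G v = E u - F on the linear branch
      v_of_u <- function(u) (p$E * u - p$F) / p$G
    } else if (bv == "lo") {
      v_of_u <- function(u) 0
    } else {
      v_of_u <- function(u) p$synVmax / p$G
    }
    u_sol <- switch(bu,
      lin = {
        # A u + B v(u) + C = D u
        if (bv == "lin") {
          denom <- p$A + p$B * p$E / p$G - p$D
          if (abs(denom) < 1e-14) next
          -(p$C - p$B * p$F / p$G) / denom
        } else {
          v0 <- v_of_u(0)
          denom <- p$A - p$D
          if (abs(denom) < 1e-14) next
          -(p$B * v0 + p$C) / denom
        }
      },
      lo = 0,
      hi = p$synUmax / p$D
    )
    if (!is.finite(u_sol)) next
    v_sol <- v_of_u(u_sol)
    # consistency of the assumed branches
    sU <- p$A * u_sol + p$B * v_sol + p$C
    sV <- p$E * u_sol - p$F
    tol <- 1e-12
    okU <- switch(bu,
      lin = sU >= -tol && sU <= p$synUmax + tol,
      lo = sU <= tol,
      hi = sU >= p$synUmax - tol)
    okV <- switch(bv,
      lin = sV >= -tol && sV <= p$synVmax + tol,
      lo = sV <= tol,
      hi = sV >= p$synVmax - tol)
    if (okU && okV && u_sol >= -tol && v_sol >= -tol)
      sols[[length(sols) + 1L]] <- c(u = max(u_sol, 0), v = max(v_sol, 0))
  }
  if (length(sols) == 0L)
    stop("no consistent clipped fixed point found")
  sols[[1L]]
}
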