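#' Lumped-parameter circulation parameters
#'
#' Parameters of the pulmonary-atrial-aortic-systemic circuit coupled to
#' the ventricle.  Resistances in kPa s/cm^3, compliances in cm^3/kPa,
#' pressures in kPa: \code{R_PULM} pulmonary resistance (0.023),
#' \code{R_SYST} systemic resistance (0.11), \code{R_AO} proximal aortic
#' impedance (0.001), \code{R_op_mv} / \code{R_op_aov} fully open mitral /
#' aortic valve resistances (0.0008 / 0.0005), \code{C_A} atrial compliance
#' (20), \code{C_SYST} aortic compliance (10), \code{P_PA} pulmonary source
#' pressure (3.0), \code{P_SV} systemic venous pressure (6.0).  The
#' closed-valve resistance \code{R_cc} (10) and the valve sigmoid steepness
#' \code{beta} (50 /kPa) complete the smooth valve law.  Initial conditions
#' \code{P_A0} (1.5) and \code{P_AO0} (10) start the transient near the
#' periodic state.
#'
#' @param ... name = value overrides of any default.
#' @return A named list of class \code{"lv_circulation"}.
#' @export
lv_circulation <- function(...) {
  p <- list(R_PULM = 0.023, R_SYST = 0.11, R_AO = 0.001,
            R_op_mv = 0.0008, R_op_aov = 0.0005,
            C_A = 20, C_SYST = 10, P_PA = 3.0, P_SV = 6.0,
            R_cc = 10, beta = 50, P_A0 = 1.5, P_AO0 = 10)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown circulation parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$R_PULM > 0, p$R_SYST > 0, p$R_AO > 0, p$C_A > 0, p$C_SYST > 0,
            p$R_cc > p$R_op_mv, p$R_cc > p$R_op_aov, p$beta > 0)
  structure(p, class = "lv_circulation")
}

.sigmoid_resistance <- function(dp, R_cc, R_op, beta) {
  R_cc - (R_cc - R_op) / (1 + exp(-beta * dp))
}

#' Pressure-dependent valve resistances
#'
#' Smooth sigmoidal switch of the mitral and aortic valve resistances
#' between the closed (\code{R_cc}) and fully open values:
#' \deqn{R_{MV} = R_{cc} - (R_{cc} - R_{op,mv}) / (1 + e^{-\beta(P_A - p)}),}
#' and analogously for the aortic valve with argument \code{p - P_aov}.
#'
#' @param P_A atrial pressure (kPa).
#' @param p LV cavity pressure (kPa).
#' @param P_aov proximal aortic pressure (kPa).
#' @param params an [lv_circulation()] list.
#' @return A list with \code{R_MV} and \code{R_AOV} (kPa s/cm^3).
#' @export
valve_resistances <- function(P_A, p, P_aov, params = lv_circulation()) {
  list(R_MV = .sigmoid_resistance(P_A - p, params$R_cc, params$R_op_mv, params$beta),
       R_AOV = .sigmoid_resistance(p - P_aov, params$R_cc, params$R_op_aov, params$beta))
}

#' Proximal aortic pressure
#'
#' Resistive divider between the cavity pressure and the aortic compliance
#' node: \deqn{P_{aov} = (p R_{AO} + P_{AO} R_{AOV}) / (R_{AO} + R_{AOV}).}
#'
#' @param p LV cavity pressure (kPa).
#' @param P_AO aortic pressure beyond the impedance (kPa).
#' @param R_AOV current aortic valve resistance (kPa s/cm^3).
#' @param params an [lv_circulation()] list.
#' @return \code{P_aov} (kPa).
#' @export
proximal_aortic_pressure <- function(p, P_AO, R_AOV, params = lv_circulation()) {
  (p * params$R_AO + P_AO * R_AOV) / (params$R_AO + R_AOV)
}

## The aortic valve law and the pressure divider are mutually dependent
## (R_AOV needs P_aov, P_aov needs R_AOV).  For given (p, P_AO) solve the
## scalar fixed point for R_AOV in [R_op_aov, R_cc]; the bracket is always
## valid because the sigmoid maps into the open interval.
.solve_aortic_valve <- function(p, P_AO, params) {
  dp <- p - P_AO
  ## saturated sigmoid: the divider cannot change the branch
  if (params$beta * dp < -40) return(params$R_cc)
  R <- .sigmoid_resistance(dp, params$R_cc, params$R_op_aov, params$beta)
  ok <- FALSE
  for (it in 1:40) {
    Rn <- .sigmoid_resistance(dp * R / (params$R_AO + R),
                              params$R_cc, params$R_op_aov, params$beta)
    if (abs(Rn - R) < 1e-12 * max(1, R)) {
      R <- Rn
      ok <- TRUE
      break
    }
    R <- 0.5 * (R + Rn)
  }
  if (!ok) {
    f <- function(R) R - .sigmoid_resistance(dp * R / (params$R_AO + R),
                                             params$R_cc, params$R_op_aov,
                                             params$beta)
    R <- stats::uniroot(f, c(params$R_op_aov * (1 - 1e-9),
                             params$R_cc * (1 + 1e-9)), tol = 1e-13)$root
  }
  R
}

#' Circulation node equations
#'
#' Rates of the atrial and aortic pressures, and the residual of the
#' flow-balance constraint that couples the mechanics to the circuit:
#' \deqn{dP_A/dt = [ (P_{PA}-P_A)/R_{PULM} - (P_A-p)/R_{MV} ] / C_A,}
#' \deqn{dP_{AO}/dt = [ (P_{aov}-P_{AO})/R_{AO} - (P_{AO}-P_{SV})/R_{SYST} ] / C_{SYST},}
#' \deqn{0 = dV/dt - (P_A-p)/R_{MV} + (p-P_{aov})/R_{AOV}.}
#'
#' @param P_A,P_AO,p node pressures (kPa).
#' @param dV_dt rate of cavity volume change (cm^3/s).
#' @param params an [lv_circulation()] list.
#' @return A list with \code{dP_A}, \code{dP_AO} (kPa/s), the constraint
#'   \code{residual} (cm^3/s), and the resolved \code{P_aov}, \code{R_MV},
#'   \code{R_AOV}.
#' @export
circuit_rates <- function(P_A, P_AO, p, dV_dt = 0, params = lv_circulation()) {
  R_AOV <- .solve_aortic_valve(p, P_AO, params)
  P_aov <- proximal_aortic_pressure(p, P_AO, R_AOV, params)
  R_MV <- .sigmoid_resistance(P_A - p, params$R_cc, params$R_op_mv, params$beta)
  q_mv <- (P_A - p) / R_MV
  q_ao <- (p - P_aov) / R_AOV
  list(dP_A = ((params$P_PA - P_A) / params$R_PULM - q_mv) / params$C_A,
       dP_AO = ((P_aov - P_AO) / params$R_AO -
                  (P_AO - params$P_SV) / params$R_SYST) / params$C_SYST,
       residual = dV_dt - q_mv + q_ao,
       P_aov = P_aov, R_MV = R_MV, R_AOV = R_AOV,
       q_mv = q_mv, q_ao = q_ao)
}
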