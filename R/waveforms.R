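#' Loading specification for one compression cycle
#'
#' Parameters of the three boundary-condition waveforms: the sinusoidal
#' displacement applied to the top solid face, the spring-foundation (Robin)
#' stiffness on the four lateral solid faces, and the sinusoidal normal
#' pressure on the six open fluid faces.
#'
#' The spring stiffness is a per-area foundation modulus: the restoring
#' traction is `-k * (u - U0)`.  The printed literature value carries the
#' unit N/mm^2 per mm of displacement, i.e. N/mm^3; with `k_units =
#' "N/mm^3"` (default) the value is converted once to Pa/m internally.  At
#' the default magnitude the lateral faces are effectively rigidly supported
#' in their normal direction, which the solvers tolerate.
#'
#' @param B_um displacement amplitude in micrometres (peak-to-peak; the
#'   waveform ranges over `[0, B]`).
#' @param T_s loading period in seconds.
#' @param C_pa pressure amplitude in pascals (waveform ranges over `[0, C]`).
#' @param k_value spring foundation stiffness in `k_units`.
#' @param k_units one of `"N/mm^3"` (= N/mm^2 traction per mm displacement)
#'   or `"Pa/m"`.
#' @param U0_um initial lateral-surface displacement in micrometres.
#' @return an object of class `load_spec`; field `k_pa_per_m` holds the
#'   converted SI stiffness.
#' @export
load_spec <- function(B_um = 0.8, T_s = 1, C_pa = 667,
                      k_value = 16e9, k_units = "N/mm^3", U0_um = 0) {
  if (B_um < 0 || T_s <= 0 || C_pa < 0 || k_value < 0)
    stop("load_spec requires B_um >= 0, T_s > 0, C_pa >= 0, k_value >= 0")
  k_pa_per_m <- switch(k_units,
    "N/mm^3" = k_value * 1e9,
    "N/mm^2/mm" = k_value * 1e9,
    "Pa/m" = k_value,
    stop("unknown k_units: ", k_units))
  structure(
    list(B_um = B_um, T_s = T_s, C_pa = C_pa,
         k_value = k_value, k_units = k_units,
         k_pa_per_m = k_pa_per_m, U0_um = U0_um),
    class = "load_spec")
}

#' Displacement waveform of the top-face load
#'
#' `u(t) = (B/2) * (sin(2*pi*(t - T/4)/T) + 1)`: zero at `t = 0`, maximum
#' `B` at `t = T/2`, period `T`.
#'
#' @param t time in seconds (vectorised).
#' @param spec a [load_spec()].
#' @return displacement in micrometres, in `[0, B]`.
#' @export
displacement_waveform <- function(t, spec = load_spec()) {
  spec$B_um / 2 * (sin(2 * pi * (t - spec$T_s / 4) / spec$T_s) + 1)
}

#' Rate of the displacement waveform
#'
#' Analytic time derivative of [displacement_waveform()]; maximal at
#' `t = T/4`, which is where wall-driven marrow flow peaks.
#'
#' @inheritParams displacement_waveform
#' @return displacement rate in micrometres per second.
#' @export
displacement_rate <- function(t, spec = load_spec()) {
  spec$B_um * pi / spec$T_s * cos(2 * pi * (t - spec$T_s / 4) / spec$T_s)
}

#' Open-boundary pressure waveform
#'
#' `P(t) = (C/2) * (sin(2*pi*(t - T/4)/T) + 1)`, applied as normal pressure
#' on all six outer faces of the fluid box, in phase with the displacement
#' load.
#'
#' @inheritParams displacement_waveform
#' @return pressure in pascals, in `[0, C]`.
#' @export
pressure_waveform <- function(t, spec = load_spec()) {
  spec$C_pa / 2 * (sin(2 * pi * (t - spec$T_s / 4) / spec$T_s) + 1)
}

#' Spring-foundation traction on a lateral solid face
#'
#' Robin boundary traction `-k * (u - U0)` opposing the normal displacement
#' of the lateral surface, emulating the restraint of the surrounding
#' (unmodelled) cancellous bone.
#'
#' @param u_solid_um current normal displacement of the surface in
#'   micrometres (vectorised).
#' @param spec a [load_spec()].
#' @return traction in pascals (negative when displacement exceeds `U0`).
#' @export
spring_traction <- function(u_solid_um, spec = load_spec()) {
  -spec$k_pa_per_m * (u_solid_um - spec$U0_um) * 1e-6
}

#' Export the loading waveforms as a table
#'
#' @param spec a [load_spec()].
#' @param n_steps number of uniform samples over one period.
#' @return data.frame with columns `t_s`, `u_um`, `dudt_um_s`, `p_pa`.
#' @export
waveform_table <- function(spec = load_spec(), n_steps = 100L) {
  t <- seq(0, spec$T_s, length.out = n_steps + 1L)[seq_len(n_steps)]
  data.frame(t_s = t,
             u_um = displacement_waveform(t, spec),
             dudt_um_s = displacement_rate(t, spec),
             p_pa = pressure_waveform(t, spec))
}
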