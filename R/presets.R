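# Reference parameter sets.  Every numeric value is transcribed from the
# corresponding figure caption of the source study; the presets are the
# operating points all bundled analyses and acceptance checks run at.
#
# Shared backbone: N_e = N_i = 5000, tau_e = tau_i = 10 ms, tau_s = 1 ms,
# eta_bar = -5, delta = 1, v_th = 500, v_r = -500.

preset_table <- function() {
  base <- list(n = 5000L, tau = 10, tau_s = 1, eta_bar = -5, delta = 1,
               v_th = 500, v_r = -500)
  list(
    fig1 = utils::modifyList(base, list(
      j_ee = 0, j_ei = 15, j_ii = 10, j_ie = 15,
      i_ext_i = 0,
      # the step stimulus on the E-cells (the caption shows it graphically):
      # quiescent settle, three ascending steps into the rhythmic regime,
      # partial release, then off
      drive_start = c(0, 100, 200, 300, 400, 450),
      drive_e = c(0, 4, 8, 12, 6, 0),
      drive_i = c(0, 0, 0, 0, 0, 0))),
    fig2_ping = utils::modifyList(base, list(
      j_ee = 0, j_ei = 15, j_ii = 0, j_ie = 15,
      i_ext_e = 10, i_ext_i = 0)),
    fig3_ing = utils::modifyList(base, list(
      j_ee = 0, j_ei = 10, j_ii = 15, j_ie = 0,
      i_ext_e = 25, i_ext_i = 25)),
    fig5_coupled = utils::modifyList(base, list(
      j_ee = 0, j_ei = 15, j_ii = 0, j_ie = 15,
      i_ext_e = 10, i_ext_i = 0,
      g_ee = 0.1, g_ie = 0.5, delay = 0)),
    fig6_scan = utils::modifyList(base, list(
      j_ee = 0, j_ei = 15, j_ii = 0, j_ie = 15,
      i_ext_e = 10, i_ext_i = 0,
      g_ee = 0.1, g_ie = 0.5, delay = 6,
      scan_delays = seq(0, 12, by = 0.25))),
    fig7_ing_coupled = utils::modifyList(base, list(
      j_ee = 0, j_ei = 10, j_ii = 15, j_ie = 0,
      i_ext_e = 25, i_ext_i = 25,
      g_ee = 0, g_ie = 0.3, delay = 0.2)),
    fig9_global = utils::modifyList(base, list(
      j_ee = 0, j_ei = 15, j_ii = 0, j_ie = 15,
      i_ext_e = 10, i_ext_i = 0,
      g_ee = 0.1, g_ie = 0.5, delay = 6,
      pulse_amplitude = 1, pulse_duration = 0.1))
  )
}

#' Reference parameter presets
#'
#' Returns a fully assembled configuration bundle for one of the
#' reference operating points used throughout the package: the
#' step-driven fidelity benchmark (`fig1`), the PING and ING rhythm
#' operating points (`fig2_ping`, `fig3_ing`), the coupled-circuit
#' locking configurations (`fig5_coupled`, `fig6_scan`,
#' `fig7_ing_coupled`) and the global-PRC configuration (`fig9_global`).
#'
#' @param name Preset name; an unknown name raises an error listing the
#'   valid ones.
#'
#' @return An object of class `config_bundle` with fields `e_params`,
#'   `i_params`, `couplings`, `drive` (a [drive_protocol()]), `cross`
#'   (a [cross_coupling()] or `NULL`), `pulse` (or `NULL`), `extra`
#'   (preset-specific scan grids), `name`.
#' @examples
#' figure_preset("fig2_ping")
#' @export
figure_preset <- function(name) {
  tab <- preset_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tab))
    stop("preset-not-found: unknown preset '", name, "'; valid presets: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  drive <- if (!is.null(p$drive_start))
    drive_protocol(p$drive_start, p$drive_e, p$drive_i)
  else
    constant_drive(p$i_ext_e %||% 0, p$i_ext_i %||% 0)
  cross <- if (!is.null(p$g_ee) || !is.null(p$g_ie))
    cross_coupling(p$g_ee %||% 0, p$g_ie %||% 0, p$delay %||% 0)
  pulse <- if (!is.null(p$pulse_amplitude))
    list(amplitude = p$pulse_amplitude, duration = p$pulse_duration)
  structure(list(
    e_params = population_params(p$tau, p$eta_bar, p$delta, p$n,
                                 p$v_th, p$v_r),
    i_params = population_params(p$tau, p$eta_bar, p$delta, p$n,
                                 p$v_th, p$v_r),
    couplings = synaptic_couplings(p$j_ee, p$j_ei, p$j_ie, p$j_ii, p$tau_s),
    drive = drive,
    cross = cross,
    pulse = pulse,
    extra = p["scan_delays"][!vapply(p["scan_delays"], is.null, logical(1))],
    name = name), class = "config_bundle")
}

#' @export
print.config_bundle <- function(x, ...) {
  cat(sprintf("Configuration bundle '%s'\n", x$name %||% "custom"))
  print(x$e_params)
  cat(sprintf("Couplings: J_ee = %g, J_ei = %g, J_ie = %g, J_ii = %g, tau_s = %g ms\n",
              x$couplings$j_ee, x$couplings$j_ei, x$couplings$j_ie,
              x$couplings$j_ii, x$couplings$tau_s))
  if (!is.null(x$cross)) print(x$cross)
  invisible(x)
}
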