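#' Thresholds for the four-state classification
#'
#' The state definitions are comparative (high/low motility, short/long
#' correlation, minimal/moderate/monotonic neighbor exchange); the
#' numeric cutoffs here are artifact constants calibrated once against
#' the simulator presets and shipped as defaults.
#'
#' @param v_rms_low um/h; below this the tissue is arrested (jammed).
#' @param l_corr_low um; below this motion is spatially disordered.
#' @param exchange_slope_high um/h; at or above this neighbor exchange
#'   marks a fluid.
#' @param si_sd_low shape-index SD; secondary (tie-breaking) criterion
#'   only, since shape data may be absent.
#' @return a `state_thresholds` list.
#' @export
state_thresholds <- function(v_rms_low = 2, l_corr_low = 14,
                             exchange_slope_high = 0.15,
                             si_sd_low = 0.25) {
  abort_if(v_rms_low <= 0 || l_corr_low <= 0,
           "thresholds must be positive")
  structure(list(v_rms_low = v_rms_low, l_corr_low = l_corr_low,
                 exchange_slope_high = exchange_slope_high,
                 si_sd_low = si_sd_low),
            class = "state_thresholds")
}

#' Classify the dynamic state of a monolayer
#'
#' Rule table over the computed metric bundle:
#' \itemize{
#'   \item `V_rms < v_rms_low` -> `jammed_solid` (arrested tissue);
#'   \item else `L_corr < l_corr_low` -> `unjammed_disordered_fluid`
#'     (motile but spatially uncoordinated);
#'   \item else `exchange_slope >= exchange_slope_high` ->
#'     `flocking_fluid` (coordinated motion with neighbor exchange);
#'   \item else `flocking_solid` (coordinated motion in a topologically
#'     constrained tissue).
#' }
#' The order parameter is recorded in the call but is not a splitting
#' criterion: the state definitions split on motility, correlation
#' length and neighbor exchange, with alignment entering through the
#' correlation length.
#'
#' @param metrics named list with `v_rms` (um/h), `l_corr` (um; may be
#'   `NA` if the correlation fit did not converge), `exchange_slope`
#'   (um/h); optionally `psi`, `si_sd`.
#' @param thresholds a [state_thresholds()].
#' @return a `tissue_state_call`: list with `state`, `metrics`,
#'   `thresholds`, `rationale`. `state` is `"unclassifiable"` (with the
#'   reasons in `rationale`) when a needed metric is undefined.
#' @export
classify_state <- function(metrics, thresholds = state_thresholds()) {
  required <- c("v_rms", "l_corr", "exchange_slope")
  missing <- setdiff(required, names(metrics))
  abort_if(length(missing) > 0,
           paste0("metrics missing: ", paste(missing, collapse = ", ")))
  call_out <- function(state, rationale) {
    structure(list(state = state, metrics = metrics,
                   thresholds = thresholds, rationale = rationale),
              class = "tissue_state_call")
  }
  v <- metrics$v_rms
  if (!is.finite(v)) {
    return(call_out("unclassifiable", "v_rms is undefined"))
  }
  if (v < thresholds$v_rms_low) {
    return(call_out("jammed_solid",
                    sprintf("v_rms %.2f < %.2f um/h: arrested", v,
                            thresholds$v_rms_low)))
  }
  L <- metrics$l_corr
  if (!is.finite(L)) {
    return(call_out("unclassifiable",
                    "motile tissue but L_corr is undefined (fit did not converge)"))
  }
  if (L < thresholds$l_corr_low) {
    return(call_out("unjammed_disordered_fluid",
                    sprintf("v_rms %.2f >= %.2f and L_corr %.1f < %.1f um: motile, uncoordinated",
                            v, thresholds$v_rms_low, L,
                            thresholds$l_corr_low)))
  }
  s <- metrics$exchange_slope
  if (!is.finite(s)) {
    return(call_out("unclassifiable",
                    "coordinated motile tissue but exchange_slope is undefined"))
  }
  if (s >= thresholds$exchange_slope_high) {
    call_out("flocking_fluid",
             sprintf("L_corr %.1f >= %.1f um and exchange slope %.3f >= %.3f um/h: coordinated with neighbor exchange",
                     L, thresholds$l_corr_low, s,
                     thresholds$exchange_slope_high))
  } else {
    call_out("flocking_solid",
             sprintf("L_corr %.1f >= %.1f um and exchange slope %.3f < %.3f um/h: coordinated, neighbors retained",
                     L, thresholds$l_corr_low, s,
                     thresholds$exchange_slope_high))
  }
}

#' @export
print.tissue_state_call <- function(x, ...) {
  cat(sprintf("<tissue_state_call> %s\n  %s\n", x$state, x$rationale))
  invisible(x)
}
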