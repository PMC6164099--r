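#' Analytic surface-plasmon resonance angle (three-layer limit)
#'
#' For a thick metal film between prism and dielectric, resonance occurs
#' where the in-plane wavevector of the evanescent wave matches the
#' surface-plasmon propagation constant:
#' \deqn{\theta_{SPR} = \arcsin\!\left(\frac{1}{n_p}
#'   \sqrt{\frac{\varepsilon_m n_d^2}{\varepsilon_m + n_d^2}}\right)}
#' where eps_m is the real part of the metal permittivity and n_d the
#' refractive index of the sensing medium. A bound surface plasmon requires
#' eps_m < 0 and eps_m + n_d^2 < 0, and the prism must be optically dense
#' enough that the arcsine argument does not exceed 1.
#'
#' @param n_prism Prism refractive index (real, > 0).
#' @param eps_metal_real Real part of the metal permittivity (< 0).
#' @param n_dielectric Sensing-medium refractive index (real, > 0).
#' @return Resonance angle in degrees.
#' @examples
#' resonance_angle_analytic(1.510, Re(n_to_eps(complex(real = 0.13455,
#'                                                     imaginary = 3.98651))), 1.0)
#' @export
resonance_angle_analytic <- function(n_prism, eps_metal_real, n_dielectric) {
  if (!is_scalar_number(n_prism) || !is_scalar_number(eps_metal_real) ||
      !is_scalar_number(n_dielectric) || n_prism <= 0 || n_dielectric <= 0) {
    spr_stop("inputs must be finite with n_prism, n_dielectric > 0",
             "sprshell_input_error")
  }
  if (eps_metal_real >= 0 || eps_metal_real + n_dielectric^2 >= 0) {
    spr_stop("no bound surface plasmon: need eps_m < 0 and eps_m + nd^2 < 0",
             "sprshell_no_solution_error")
  }
  s <- sqrt(eps_metal_real * n_dielectric^2 /
              (eps_metal_real + n_dielectric^2)) / n_prism
  if (s > 1) {
    spr_stop("prism cannot phase-match the surface plasmon (sin > 1)",
             "sprshell_no_solution_error")
  }
  rad2deg(asin(s))
}

#' Locate the reflectivity dip in an angular spectrum
#'
#' Finds the global minimum of the sampled reflectivity and refines it by a
#' parabola through the minimum and its two neighbours (exact for locally
#' quadratic dips, reproducible to well below the grid step). A minimum on
#' the grid boundary cannot be refined and raises a warning.
#'
#' @param spectrum An [angular_scan()] result, or any data frame with
#'   columns `angle_deg` and `reflectivity`.
#' @return Object of class `dip_result`: list with `theta_spr_deg`, `r_min`,
#'   `grid_step`, `refined` (logical), `boundary` (logical).
#' @export
find_dip <- function(spectrum) {
  th <- spectrum$angle_deg
  R <- spectrum$reflectivity
  n <- length(th)
  if (n < 1L) spr_stop("empty spectrum", "sprshell_input_error")
  i <- which.min(R)
  step <- if (n > 1L) th[2] - th[1] else NA_real_
  if (i == 1L || i == n) {
    warning(warningCondition(
      "reflectivity minimum lies on the scan boundary; dip not refined",
      class = "sprshell_boundary_dip_warning"))
    out <- list(theta_spr_deg = th[i], r_min = R[i], grid_step = step,
                refined = FALSE, boundary = TRUE)
  } else {
    y1 <- R[i - 1L]; y2 <- R[i]; y3 <- R[i + 1L]
    curv <- y1 - 2 * y2 + y3
    if (curv <= 0) {                      # flat triple: keep grid point
      out <- list(theta_spr_deg = th[i], r_min = y2, grid_step = step,
                  refined = FALSE, boundary = FALSE)
    } else {
      h <- th[i + 1L] - th[i]
      dx <- 0.5 * (y1 - y3) / curv        # vertex offset in units of h
      out <- list(theta_spr_deg = th[i] + dx * h,
                  r_min = y2 - 0.25 * (y1 - y3) * dx,
                  grid_step = step, refined = TRUE, boundary = FALSE)
    }
  }
  structure(out, class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("<dip_result> theta_SPR = %.4f deg, R_min = %.5g%s\n",
              x$theta_spr_deg, x$r_min,
              if (x$boundary) " (on scan boundary)" else ""))
  invisible(x)
}

#' Refractometric sensitivity from a dip shift
#'
#' S = delta_theta / delta_n in degrees per refractive-index unit (RIU),
#' from the dip angles of two configurations whose sensing-medium indices
#' differ by delta_n. Both differences are stored signed; the convention is
#' (b) minus (a), with (a) the reference (e.g. water) configuration.
#'
#' @param theta_a_deg,theta_b_deg Dip angles of the two configurations
#'   (degrees).
#' @param n_a,n_b Sensing-medium refractive indices of the two
#'   configurations; must differ.
#' @return Object of class `sensitivity_report`: list with
#'   `delta_theta_deg`, `delta_n`, `S_deg_per_riu`.
#' @export
sensitivity <- function(theta_a_deg, theta_b_deg, n_a, n_b) {
  if (!is_scalar_number(theta_a_deg) || !is_scalar_number(theta_b_deg) ||
      !is_scalar_number(n_a) || !is_scalar_number(n_b)) {
    spr_stop("all inputs must be finite numbers", "sprshell_input_error")
  }
  if (n_a == n_b) {
    spr_stop("delta_n = 0: sensitivity undefined",
             "sprshell_undefined_sensitivity_error")
  }
  dth <- theta_b_deg - theta_a_deg
  dn <- n_b - n_a
  structure(list(delta_theta_deg = dth, delta_n = dn,
                 S_deg_per_riu = dth / dn),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> dtheta = %.4f deg, dn = %.4g RIU, S = %.4f deg/RIU\n",
    x$delta_theta_deg, x$delta_n, x$S_deg_per_riu))
  invisible(x)
}

#' Sensitivity enhancement of one configuration over another
#'
#' Percentage gain of the core-shell-loaded sensor over the baseline:
#' (S_with - S_without) / S_without * 100.
#'
#' @param S_with Sensitivity of the enhanced (core-shell) configuration.
#' @param S_without Baseline sensitivity; must be nonzero.
#' @return Enhancement in percent.
#' @export
enhancement <- function(S_with, S_without) {
  if (!is_scalar_number(S_with) || !is_scalar_number(S_without)) {
    spr_stop("sensitivities must be finite numbers", "sprshell_input_error")
  }
  if (S_without == 0) {
    spr_stop("zero baseline sensitivity: enhancement undefined",
             "sprshell_undefined_enhancement_error")
  }
  (S_with - S_without) / S_without * 100
}

#' JSON report for dip and sensitivity results
#'
#' Serializes a [find_dip()] or [sensitivity()] result (plus any inputs the
#' caller wants echoed) to JSON.
#'
#' @param result A `dip_result` or `sensitivity_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @param inputs Optional named list echoed under `"inputs"`.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(result, path = NULL, inputs = NULL) {
  payload <- unclass(result)
  payload$type <- class(result)[1]
  if (!is.null(inputs)) payload$inputs <- inputs
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
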