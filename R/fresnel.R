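#' Build a stratified layer stack
#'
#' Ordered planar stack for reflectivity calculations: an incidence
#' half-space (the prism), zero or more finite films, and an exit
#' half-space. The incidence medium must be lossless so the incidence angle
#' is well defined.
#'
#' @param layers List of layers, each a list with `material` (an
#'   [optical_constant()] or a complex refractive index) and either
#'   `thickness_nm` (> 0) or `halfspace = TRUE`. First and last layers must
#'   be half-spaces. An optional `name` per layer is kept for display.
#' @param wavelength_nm Vacuum wavelength in nm.
#' @return Object of class `layer_stack`.
#' @examples
#' mats <- default_materials()
#' layer_stack(list(
#'   list(material = mats$bk7, halfspace = TRUE),
#'   list(material = mats$silver, thickness_nm = 40),
#'   list(material = mats$air, halfspace = TRUE)
#' ), wavelength_nm = 632.8)
#' @export
layer_stack <- function(layers, wavelength_nm = 632.8) {
  if (!is.list(layers) || length(layers) < 2L) {
    spr_stop("a stack needs at least two layers (two half-spaces)",
             "sprshell_input_error")
  }
  if (!is_scalar_number(wavelength_nm) || wavelength_nm <= 0) {
    spr_stop("wavelength_nm must be positive", "sprshell_input_error")
  }
  n <- length(layers)
  parsed <- lapply(seq_len(n), function(i) {
    ly <- layers[[i]]
    m <- ly$material
    oc <- if (inherits(m, "optical_constant")) m
          else optical_constant(n = m, wavelength_nm = wavelength_nm)
    half <- isTRUE(ly$halfspace)
    th <- ly$thickness_nm
    if (half && !is.null(th)) {
      spr_stop("a half-space layer cannot carry a thickness",
               "sprshell_input_error")
    }
    if (!half) {
      if (!is_scalar_number(th) || th < 0) {
        spr_stop(sprintf("layer %d: thickness_nm must be a number >= 0", i),
                 "sprshell_input_error")
      }
    }
    list(name = ly$name %||% oc$name %||% sprintf("layer%d", i),
         eps = oc$eps, n = oc$n,
         thickness_nm = if (half) Inf else th, halfspace = half)
  })
  if (!parsed[[1]]$halfspace || !parsed[[n]]$halfspace) {
    spr_stop("first and last layers must be half-spaces",
             "sprshell_input_error")
  }
  if (any(vapply(parsed[-c(1, n)], function(l) l$halfspace, logical(1)))) {
    spr_stop("interior layers must have finite thickness",
             "sprshell_input_error")
  }
  if (abs(Im(parsed[[1]]$n)) > 0) {
    spr_stop("incidence medium must be lossless (real index)",
             "sprshell_input_error")
  }
  structure(list(layers = parsed, wavelength_nm = wavelength_nm),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers @ %.1f nm\n",
              length(x$layers), x$wavelength_nm))
  for (l in x$layers) {
    cat(sprintf("  %-24s n = %-22s %s\n", l$name, format(l$n, digits = 6),
                if (l$halfspace) "half-space"
                else sprintf("d = %g nm", l$thickness_nm)))
  }
  invisible(x)
}

#' Perpendicular wavevector component in a medium
#'
#' kz = sqrt(eps k0^2 - kx^2) with the branch chosen so that Im(kz) >= 0
#' (fields decay away from the interface); on the real axis the branch with
#' Re(kz) >= 0 (forward propagation) is taken.
#'
#' @param eps Complex permittivity (vectorized).
#' @param kx Parallel wavevector component (real, conserved across layers).
#' @param k0 Vacuum wavenumber 2*pi/lambda (> 0).
#' @return Complex kz, same length as `eps`.
#' @export
kz_comp <- function(eps, kx, k0) {
  if (!is_scalar_number(kx) || !is_scalar_number(k0) || k0 <= 0) {
    spr_stop("kx must be real and k0 > 0", "sprshell_input_error")
  }
  v <- sqrt(as.complex(eps) * k0^2 - kx^2)
  flip <- Im(v) < 0 | (Im(v) == 0 & Re(v) < 0)
  v[flip] <- -v[flip]
  v
}

#' Fresnel interface coefficient, p-polarization
#'
#' r_ij = (kz_i eps_j - kz_j eps_i) / (kz_i eps_j + kz_j eps_i) for a wave
#' travelling from medium i into medium j.
#'
#' @param eps_i,eps_j Complex permittivities of the two media.
#' @param kz_i,kz_j Perpendicular wavevector components from [kz_comp()].
#' @return Complex amplitude reflection coefficient.
#' @export
interface_rp <- function(eps_i, eps_j, kz_i, kz_j) {
  den <- kz_i * eps_j + kz_j * eps_i
  if (Mod(den) < 1e-300) {
    spr_stop("p-polarized interface coefficient singular (grazing/pole)",
             "sprshell_pole_error")
  }
  (kz_i * eps_j - kz_j * eps_i) / den
}

#' Fresnel interface coefficient, s-polarization
#'
#' r_ij = (kz_i - kz_j) / (kz_i + kz_j). Provided for symmetry checks;
#' surface plasmons couple only to p-polarized light.
#'
#' @param kz_i,kz_j Perpendicular wavevector components.
#' @return Complex amplitude reflection coefficient.
#' @export
interface_rs <- function(kz_i, kz_j) {
  den <- kz_i + kz_j
  if (Mod(den) < 1e-300) {
    spr_stop("s-polarized interface coefficient singular",
             "sprshell_pole_error")
  }
  (kz_i - kz_j) / den
}

# amplitude reflection coefficient by right-fold of the two-interface
# combination rule: r = (r_ij + r_below e^{2i kz d}) / (1 + r_ij r_below ...)
.reflect_recursive <- function(eps, d, kz, pol) {
  n <- length(eps)
  iface <- function(i, j) {
    if (pol == "p") interface_rp(eps[i], eps[j], kz[i], kz[j])
    else interface_rs(kz[i], kz[j])
  }
  r <- iface(n - 1L, n)
  if (n > 2L) {
    for (j in seq(n - 2L, 1L)) {
      ph <- exp(2i * kz[j + 1L] * d[j])
      rij <- iface(j, j + 1L)
      r <- (rij + r * ph) / (1 + rij * r * ph)
    }
  }
  r
}

# amplitude reflection coefficient via the 2x2 characteristic matrix;
# independent route used as a numerical cross-check of the recursion
.reflect_matrix <- function(eps, d, kz, k0, pol) {
  n <- length(eps)
  q <- if (pol == "p") kz / eps else kz  # surface admittance up to constants
  M <- diag(2) + 0i
  if (n > 2L) {
    for (j in seq(2L, n - 1L)) {
      delta <- kz[j] * d[j - 1L]
      Mj <- matrix(c(cos(delta), -1i * q[j] * sin(delta),
                     -1i * sin(delta) / q[j], cos(delta)), 2, 2)
      M <- M %*% Mj
    }
  }
  num <- q[1] * (M[1, 1] + M[1, 2] * q[n]) - (M[2, 1] + M[2, 2] * q[n])
  den <- q[1] * (M[1, 1] + M[1, 2] * q[n]) + (M[2, 1] + M[2, 2] * q[n])
  num / den
}

#' Reflectivity of a layer stack at one incidence angle
#'
#' Energy reflectance |r|^2 of a plane wave incident from the first
#' (prism) half-space at `theta_deg`, measured in the prism. Two routes are
#' implemented: the recursive two-interface combination rule generalized to
#' N media (default) and the 2x2 characteristic-matrix method; they agree
#' to machine precision and serve as mutual cross-checks.
#'
#' @param stack A [layer_stack()].
#' @param theta_deg Incidence angle in degrees, 0 <= theta < 90
#'   (vectorized).
#' @param polarization `"p"` (default; supports surface plasmons) or `"s"`.
#' @param method `"recursive"` or `"matrix"`.
#' @return Numeric reflectivity in [0, 1] (same length as `theta_deg`).
#' @export
reflectivity <- function(stack, theta_deg, polarization = c("p", "s"),
                         method = c("recursive", "matrix")) {
  polarization <- match.arg(polarization)
  method <- match.arg(method)
  stopifnot(inherits(stack, "layer_stack"))
  if (any(theta_deg < 0 | theta_deg >= 90)) {
    spr_stop("incidence angle must satisfy 0 <= theta < 90 degrees",
             "sprshell_input_error")
  }
  eps <- vapply(stack$layers, function(l) l$eps, complex(1))
  nL <- length(eps)
  d <- vapply(stack$layers[-c(1, nL)], function(l) l$thickness_nm, numeric(1))
  keep <- d > 0  # zero-thickness films are no-ops
  eps_eff <- c(eps[1], eps[-c(1, nL)][keep], eps[nL])
  d_eff <- d[keep]
  k0 <- 2 * pi / stack$wavelength_nm
  np <- Re(stack$layers[[1]]$n)
  vapply(theta_deg, function(th) {
    kx <- k0 * np * sin(deg2rad(th))
    kz <- kz_comp(eps_eff, kx, k0)
    r <- if (method == "recursive") {
      .reflect_recursive(eps_eff, d_eff, kz, polarization)
    } else {
      .reflect_matrix(eps_eff, d_eff, kz, k0, polarization)
    }
    Mod(r)^2
  }, numeric(1))
}

#' Angular reflectivity scan
#'
#' Evaluates [reflectivity()] on a closed regular angle grid, producing the
#' angle-interrogated ATR spectrum.
#'
#' @param stack A [layer_stack()].
#' @param theta_min,theta_max Scan range in degrees, `theta_min < theta_max`.
#' @param step Grid step in degrees (> 0); default 0.005.
#' @param polarization,method Passed to [reflectivity()].
#' @return Object of class `angular_spectrum`: a data frame with columns
#'   `angle_deg` and `reflectivity`, carrying the stack and scan metadata
#'   as attributes.
#' @export
angular_scan <- function(stack, theta_min = 40, theta_max = 60,
                         step = 0.005, polarization = "p",
                         method = "recursive") {
  if (!is_scalar_number(step) || step <= 0 || theta_min >= theta_max) {
    spr_stop("need theta_min < theta_max and step > 0",
             "sprshell_invalid_range_error")
  }
  angles <- seq(theta_min, theta_max, by = step)
  if (length(angles) < 1L) {
    spr_stop("empty angular grid", "sprshell_invalid_range_error")
  }
  R <- reflectivity(stack, angles, polarization, method)
  structure(
    data.frame(angle_deg = angles, reflectivity = R),
    class = c("angular_spectrum", "data.frame"),
    stack = stack, step = step,
    range = c(theta_min, theta_max), polarization = polarization
  )
}

#' @export
print.angular_spectrum <- function(x, ...) {
  rng <- attr(x, "range")
  cat(sprintf(
    "<angular_spectrum> %d points, %.4g-%.4g deg (step %g), min R = %.4g\n",
    nrow(x), rng[1], rng[2], attr(x, "step"), min(x$reflectivity)))
  invisible(x)
}

#' Write an angular spectrum to CSV
#'
#' Plain CSV with header `angle_deg,reflectivity`, '.' decimal separator,
#' LF line endings, full double precision.
#'
#' @param spectrum An [angular_scan()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("angle_deg,reflectivity", con, sep = "\n")
  writeLines(sprintf("%.17g,%.17g", spectrum$angle_deg,
                     spectrum$reflectivity), con, sep = "\n")
  invisible(path)
}
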