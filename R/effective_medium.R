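#' Core-shell sphere geometry
#'
#' Geometry of a spherical core of radius `b` coated to outer radius `a`;
#' the quasi-static homogenization depends on the geometry only through the
#' fill fraction f = (b/a)^3. Either give (`b`, `a`) or `f` directly.
#'
#' @param b Core radius in nm (> 0).
#' @param a Outer radius in nm (>= b).
#' @param f Fill fraction (b/a)^3 in (0, 1]; alternative to (`b`, `a`).
#' @return Object of class `core_shell_geometry` with fields `b`, `a`, `f`
#'   and `shell_nm` (a - b, `NA` when only `f` is known).
#' @examples
#' core_shell_geometry(b = 10, a = 15)
#' core_shell_geometry(f = 0.73)
#' @export
core_shell_geometry <- function(b = NULL, a = NULL, f = NULL) {
  if (is.null(f)) {
    if (!is_scalar_number(b) || !is_scalar_number(a) || b <= 0 || a < b) {
      spr_stop("need radii 0 < b <= a", "sprshell_input_error")
    }
    f <- (b / a)^3
  } else {
    if (!is_scalar_number(f) || f <= 0 || f > 1) {
      spr_stop("f must be in (0, 1]", "sprshell_input_error")
    }
    b <- NA_real_; a <- NA_real_
  }
  structure(list(b = b, a = a, f = f,
                 shell_nm = if (is.na(a)) NA_real_ else a - b),
            class = "core_shell_geometry")
}

#' @export
print.core_shell_geometry <- function(x, ...) {
  cat(sprintf("<core_shell_geometry> b = %s nm, a = %s nm, f = %.6g\n",
              format(x$b), format(x$a), x$f))
  invisible(x)
}

#' Effective permittivity of a core-shell sphere (internal homogenization)
#'
#' Quasi-static effective permittivity of a sphere with core permittivity
#' `eps_core` and shell permittivity `eps_shell`:
#' \deqn{\varepsilon_{eff} = \varepsilon_s
#'   \frac{(\varepsilon_c + 2\varepsilon_s) + 2f(\varepsilon_c - \varepsilon_s)}
#'        {(\varepsilon_c + 2\varepsilon_s) - f(\varepsilon_c - \varepsilon_s)}}
#' with fill fraction f = (b/a)^3. Limits: f -> 0 gives the shell
#' permittivity; equal constituents give the common value for any geometry.
#'
#' @param geom A [core_shell_geometry()] (or a number, taken as `f`).
#' @param eps_core Complex core permittivity.
#' @param eps_shell Complex shell permittivity.
#' @return Complex effective permittivity.
#' @examples
#' cal <- calibrated_constituents()
#' coreshell_eps(core_shell_geometry(b = 10, a = 15), cal$eps_core, cal$eps_shell)
#' @export
coreshell_eps <- function(geom, eps_core, eps_shell) {
  f <- if (inherits(geom, "core_shell_geometry")) geom$f
       else core_shell_geometry(f = geom)$f
  ec <- as_complex1(eps_core, "eps_core")
  es <- as_complex1(eps_shell, "eps_shell")
  num <- (ec + 2 * es) + 2 * f * (ec - es)
  den <- (ec + 2 * es) - f * (ec - es)
  if (Mod(den) < 1e-14 * max(Mod(c(ec, es, 1)))) {
    spr_stop("core-shell homogenization pole: vanishing denominator",
             "sprshell_pole_error", f = f)
  }
  es * num / den
}

#' Equivalent permittivity of a coated grain (grain + interfacial shell)
#'
#' Quasi-static equivalent permittivity of a grain of permittivity `eps2`
#' wrapped in an interfacial shell of permittivity `eps1`, with volume ratio
#' alpha = (a/R)^3 of grain to coated particle:
#' \deqn{\varepsilon_n = \varepsilon_1
#'   \frac{(2\varepsilon_1 + \varepsilon_2) + 2\alpha(\varepsilon_2 - \varepsilon_1)}
#'        {(2\varepsilon_1 + \varepsilon_2) - \alpha(\varepsilon_2 - \varepsilon_1)}}
#' At alpha = 1 the shell vanishes and the expression reduces exactly to
#' `eps2`; equal permittivities give the common value for any alpha.
#'
#' @param eps1 Complex shell (biomaterial) permittivity.
#' @param eps2 Complex grain (core-shell nanoparticle) permittivity.
#' @param alpha Volume ratio (a/R)^3 in (0, 1].
#' @return Complex equivalent permittivity of the coated grain.
#' @export
coated_grain_eps <- function(eps1, eps2, alpha) {
  e1 <- as_complex1(eps1, "eps1")
  e2 <- as_complex1(eps2, "eps2")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    spr_stop("alpha must be in (0, 1]", "sprshell_input_error")
  }
  num <- (2 * e1 + e2) + 2 * alpha * (e2 - e1)
  den <- (2 * e1 + e2) - alpha * (e2 - e1)
  if (Mod(den) < 1e-14 * max(Mod(c(e1, e2, 1)))) {
    spr_stop("coated-grain pole: vanishing denominator",
             "sprshell_pole_error", alpha = alpha)
  }
  e1 * num / den
}

#' Composite mixture specification
#'
#' Describes the sensing-layer composite: coated grains (core-shell
#' nanoparticle + biomaterial interfacial shell) dispersed in a host
#' (water) at volume fraction `F`.
#'
#' @param eps_grain Complex permittivity of the bare grain (core-shell
#'   effective permittivity).
#' @param eps_shell Complex permittivity of the interfacial biomaterial
#'   shell.
#' @param eps_host Complex permittivity of the host medium.
#' @param alpha Grain-to-particle volume ratio (a/R)^3 in (0, 1].
#' @param F Volume fraction of coated particles in the host, in [0, 1].
#' @return Object of class `composite_spec`.
#' @export
composite_spec <- function(eps_grain, eps_shell, eps_host, alpha, F) {
  e2 <- as_complex1(eps_grain, "eps_grain")
  e1 <- as_complex1(eps_shell, "eps_shell")
  em <- as_complex1(eps_host, "eps_host")
  if (any(c(Im(e1), Im(e2), Im(em)) < 0)) {
    spr_stop("composite constituents must be passive (Im >= 0)",
             "sprshell_input_error")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    spr_stop("alpha must be in (0, 1]", "sprshell_input_error")
  }
  if (!is_scalar_number(F) || F < 0 || F > 1) {
    spr_stop("F must be in [0, 1]", "sprshell_input_error")
  }
  structure(list(eps_grain = e2, eps_shell = e1, eps_host = em,
                 alpha = alpha, F = F),
            class = "composite_spec")
}

#' @export
print.composite_spec <- function(x, ...) {
  cat(sprintf(paste0("<composite_spec> grain %s | shell %s | host %s | ",
                     "alpha = %.4g, F = %.4g\n"),
              format(x$eps_grain, digits = 5),
              format(x$eps_shell, digits = 5),
              format(x$eps_host, digits = 5), x$alpha, x$F))
  invisible(x)
}

# the two closed-form roots of the mixing relation
# (1-F)(x - em)/(2x + em) + F (x - en)/(x + en) = 0, cleared of denominators:
# (1+F) x^2 + [(1-F)(en - em) + F(em - 2 en)] x - em en = 0
.mix_roots <- function(F, em, en) {
  A <- 1 + F
  B <- (1 - F) * (en - em) + F * (em - 2 * en)
  C <- -em * en
  s <- sqrt(as.complex(B^2 - 4 * A * C))
  c((-B + s) / (2 * A), (-B - s) / (2 * A))
}

.mix_residual <- function(x, F, em, en) {
  Mod((1 - F) * (x - em) / (2 * x + em) + F * (x - en) / (x + en))
}

#' Effective permittivity of the composite sensing layer
#'
#' Solves the Maxwell-Garnett-type mixing relation for the composite of
#' coated grains in a host. The default `"paper"` variant solves
#' \deqn{(1-F)\frac{\varepsilon - \varepsilon_m}{2\varepsilon + \varepsilon_m}
#'   + F\frac{\varepsilon - \varepsilon_n}{\varepsilon + \varepsilon_n} = 0}
#' as a quadratic in the composite permittivity, selecting the root that is
#' continuous with the host value as F -> 0 (tracked by marching F up from
#' zero and following the nearest root) and is passive (Im >= -1e-12). The
#' `"standard"` variant is the textbook Maxwell-Garnett closed form, whose
#' second denominator is \eqn{\varepsilon_n + 2\varepsilon} instead; the two
#' variants differ for F > 0 and are deliberately not interchangeable.
#'
#' Exact endpoints short-circuit: F = 0 returns the host permittivity,
#' F = 1 returns the coated-grain permittivity.
#'
#' @param spec A [composite_spec()]. The coated-grain permittivity eps_n is
#'   computed internally via [coated_grain_eps()].
#' @param variant `"paper"` (quadratic relation above) or `"standard"`
#'   (textbook Maxwell-Garnett).
#' @param n_steps Homotopy steps for root tracking (default 64).
#' @return Complex effective permittivity of the composite.
#' @examples
#' cal <- calibrated_constituents()
#' e2 <- coreshell_eps(core_shell_geometry(f = 0.73), cal$eps_core, cal$eps_shell)
#' sp <- composite_spec(e2, n_to_eps(1.38), n_to_eps(1.33), alpha = 0.73, F = 0.1)
#' composite_eps(sp)
#' @export
composite_eps <- function(spec, variant = c("paper", "standard"),
                          n_steps = 64L) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "composite_spec"))
  em <- spec$eps_host
  en <- coated_grain_eps(spec$eps_shell, spec$eps_grain, spec$alpha)
  F <- spec$F
  if (F == 0) return(em)
  if (F == 1) return(en)

  if (variant == "standard") {
    # closed form: (x - em)/(x + 2 em) = F (en - em)/(en + 2 em)
    t <- F * (en - em) / (en + 2 * em)
    return(em * (1 + 2 * t) / (1 - t))
  }

  # homotopy in F from the host-only limit, nearest-root tracking
  x <- em
  for (Fi in seq(0, F, length.out = n_steps + 1L)[-1L]) {
    r <- .mix_roots(Fi, em, en)
    x <- r[which.min(Mod(r - x))]
  }
  if (Im(x) < -1e-12) {
    r <- .mix_roots(F, em, en)
    other <- r[which.max(Mod(r - x))]
    if (Im(other) >= -1e-12) {
      x <- other
    } else {
      spr_stop("no passive root of the mixing relation",
               "sprshell_no_physical_root_error", roots = r)
    }
  }
  resid <- .mix_residual(x, F, em, en)
  if (resid > 1e-10) {
    spr_stop(sprintf("mixing-relation residual %.3g exceeds 1e-10", resid),
             "sprshell_solver_error")
  }
  x
}
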