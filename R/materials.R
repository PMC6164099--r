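#' Convert a complex refractive index to a relative permittivity
#'
#' For a non-magnetic medium the relative permittivity is the square of the
#' complex refractive index, eps = (n + ik)^2.
#'
#' @param n Complex (or real) refractive index; vectorized.
#' @return Complex relative permittivity of the same length.
#' @examples
#' n_to_eps(1.33)                      # water, 1.7689
#' n_to_eps(complex(real = 0.13455, imaginary = 3.98651))  # silver at 632.8 nm
#' @export
n_to_eps <- function(n) {
  n <- as.complex(n)
  n * n
}

#' Convert a relative permittivity to a complex refractive index
#'
#' Principal square root with the passive-medium branch: the returned index
#' has non-negative imaginary part (absorbing or lossless), and non-negative
#' real part.
#'
#' @param eps Complex relative permittivity; vectorized.
#' @return Complex refractive index n + ik with Im >= 0.
#' @export
eps_to_n <- function(eps) {
  n <- sqrt(as.complex(eps))
  flip <- Im(n) < 0 | (Im(n) == 0 & Re(n) < 0)
  n[flip] <- -n[flip]
  n
}

#' Optical constant of a medium at a fixed wavelength
#'
#' Bundles the complex refractive index and the equivalent relative
#' permittivity of a medium at one stated vacuum wavelength. Exactly one of
#' `n` or `eps` must be given; the other is derived (eps = n^2).
#'
#' @param n Complex refractive index, Im(n) >= 0 (passive medium).
#' @param eps Complex relative permittivity.
#' @param wavelength_nm Vacuum wavelength in nm (default 632.8, HeNe).
#' @param name Optional material name.
#' @return An object of class `optical_constant` with fields `name`, `n`,
#'   `eps`, `wavelength_nm`.
#' @examples
#' optical_constant(n = 1.510, name = "bk7")
#' @export
optical_constant <- function(n = NULL, eps = NULL, wavelength_nm = 632.8,
                             name = NULL) {
  if (is.null(n) == is.null(eps)) {
    spr_stop("give exactly one of n or eps", "sprshell_input_error")
  }
  if (!is_scalar_number(wavelength_nm) || wavelength_nm <= 0) {
    spr_stop("wavelength_nm must be a positive number", "sprshell_input_error")
  }
  if (is.null(n)) {
    eps <- as_complex1(eps, "eps")
    n <- eps_to_n(eps)
  } else {
    n <- as_complex1(n, "n")
    eps <- n_to_eps(n)
  }
  if (Im(n) < 0) {
    spr_stop("Im(n) < 0: gain media are not supported", "sprshell_input_error")
  }
  structure(
    list(name = name, n = n, eps = eps, wavelength_nm = wavelength_nm),
    class = "optical_constant"
  )
}

#' @export
print.optical_constant <- function(x, ...) {
  cat(sprintf("<optical_constant%s @ %.1f nm>  n = %s,  eps = %s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$wavelength_nm, format(x$n, digits = 6),
              format(x$eps, digits = 6)))
  invisible(x)
}

#' Read a materials file
#'
#' Parses a YAML file mapping material names to optical constants, given as
#' either `{n_real, n_imag}` or `{eps_real, eps_imag}`, with a file-level
#' `wavelength_nm`.
#'
#' @param path Path to the YAML materials file.
#' @return Named list of [optical_constant()] objects.
#' @export
read_materials <- function(path) {
  raw <- yaml::read_yaml(path)
  wl <- raw$wavelength_nm %||% 632.8
  out <- lapply(names(raw$materials), function(nm) {
    m <- raw$materials[[nm]]
    if (!is.null(m$n_real)) {
      optical_constant(n = complex(real = m$n_real,
                                   imaginary = m$n_imag %||% 0),
                       wavelength_nm = wl, name = nm)
    } else if (!is.null(m$eps_real)) {
      optical_constant(eps = complex(real = m$eps_real,
                                     imaginary = m$eps_imag %||% 0),
                       wavelength_nm = wl, name = nm)
    } else {
      spr_stop(sprintf("material '%s': need n_real or eps_real", nm),
               "sprshell_config_error")
    }
  })
  names(out) <- names(raw$materials)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in material registry at 632.8 nm
#'
#' Optical constants used throughout the Kretschmann-geometry scenarios: BK7
#' prism glass, silver film, water, air, and the biomaterials blood plasma,
#' haemoglobin cytoplasm (dilute and 12.93 mmol/L concentrated) and lecithin.
#' The silver index is the Johnson-Christy value at 632.8 nm.
#'
#' Constituent permittivities of the magnetite core and gold shell are *not*
#' in this registry: they are recovered by calibration, see
#' [calibrated_constituents()].
#'
#' @return Named list of [optical_constant()] objects.
#' @export
default_materials <- function() {
  read_materials(system.file("extdata", "materials.yaml",
                             package = "sprshell", mustWork = TRUE))
}

#' Published core-shell effective-permittivity tables
#'
#' The three published tables of quasi-static effective permittivities of
#' magnetite-core/gold-shell nanospheres: shell-thickness variation at fixed
#' core radius 10 nm, core-radius variation at fixed 1 nm shell, and fill
#' fraction variation at fixed outer radius 10 nm.
#'
#' @return Data frame with columns `table`, `b_nm`, `a_nm`, `eps_eff`
#'   (complex), and exact fill fraction `f` = (b/a)^3.
#' @export
coreshell_tables <- function() {
  path <- system.file("extdata", "coreshell_tables.csv",
                      package = "sprshell", mustWork = TRUE)
  d <- utils::read.csv(path)
  d$eps_eff <- complex(real = d$eps_real, imaginary = d$eps_imag)
  d$f <- (d$b_nm / d$a_nm)^3
  d[, c("table", "b_nm", "a_nm", "f", "eps_eff")]
}

# residual of the internal-homogenization relation in pole-free polynomial
# form: g = eps_s*[(ec+2es) + 2f(ec-es)] - eps_eff*[(ec+2es) - f(ec-es)]
.cal_g <- function(f, eeff, ec, es) {
  es * ((ec + 2 * es) + 2 * f * (ec - es)) -
    eeff * ((ec + 2 * es) - f * (ec - es))
}

# the two algebraic solutions of the two-row calibration system.
# Eliminating eps_core from the pair of homogenization relations and
# clearing denominators leaves (after dropping the extraneous eps_s = 0
# factor) a quadratic in eps_s:
#   6 (f1 - f2) es^2 + B es + 3 e1 e2 (f2 - f1) = 0
# so two rows determine the constituents only up to a discrete two-fold
# ambiguity; eps_core follows from eps_s by a Moebius expression.
.cal_candidates <- function(f1, e1, f2, e2) {
  A <- 6 * (f1 - f2)
  B <- e1 * (2 + f1) * (1 + 2 * f2) + 2 * (1 - f1) * e2 * (1 - f2) -
    e2 * (2 + f2) * (1 + 2 * f1) - 2 * (1 - f2) * e1 * (1 - f1)
  C <- 3 * e1 * e2 * (f2 - f1)
  s <- sqrt(as.complex(B^2 - 4 * A * C))
  es <- c((-B + s) / (2 * A), (-B - s) / (2 * A))
  den <- es * (1 + 2 * f1) - e1 * (1 - f1)
  ec <- (e1 * es * (2 + f1) - 2 * es^2 * (1 - f1)) / den
  keep <- Mod(den) > 1e-14 * max(Mod(c(e1, e2, 1))) & is.finite(Mod(ec))
  list(es = es[keep], ec = ec[keep])
}

#' Recover core and shell constituent permittivities from effective values
#'
#' The constituent permittivities of the core (magnetite) and shell (gold)
#' are back-solved from pairs (geometry, effective permittivity) of the
#' internal-homogenization relation. Two rows with distinct fill fractions
#' determine the two complex unknowns up to a discrete two-fold ambiguity:
#' eliminating the core permittivity reduces the system to a quadratic in
#' the shell permittivity, whose two roots both reproduce the input rows
#' exactly. Both algebraic solutions are computed; the returned one is
#' selected by, in order, (i) smallest total forward residual over *all*
#' supplied rows (extra rows beyond the solving pair disambiguate), (ii)
#' passivity of both constituents (Im >= 0), (iii) proximity of the shell
#' permittivity to the linear-in-f extrapolation of the data to f = 0 (a
#' vanishing core is pure shell) and of the core to the extrapolation to
#' f = 1. The rejected solution is reported as `alternate`. The selected
#' root is polished by a Newton iteration with analytic Jacobian on the
#' pole-free polynomial form of the relation.
#'
#' The solving pair is the two rows with the most extreme fill fractions
#' (best conditioning); fill fractions are the exact (b/a)^3. Rows with a
#' homogeneous sphere (all effective values equal) yield
#' eps_core = eps_shell by construction.
#'
#' @param rows Data frame with columns `b_nm`, `a_nm` (or `f`) and `eps_eff`
#'   (complex effective permittivity).
#' @param tol Convergence tolerance on the Newton residual (default 1e-12).
#' @param max_iter Newton iteration cap (default 100).
#' @return List with `eps_core`, `eps_shell`, `iterations`, `residuals`
#'   (absolute forward-evaluation residual at every input row),
#'   `calibration_rows` (indices of the solving pair), `ambiguous` (TRUE
#'   when both algebraic solutions are passive and exact on the solving
#'   pair), and `alternate` (the rejected solution, or NULL).
#' @export
recover_constituents <- function(rows, tol = 1e-12, max_iter = 100L) {
  if (is.null(rows$f)) rows$f <- (rows$b_nm / rows$a_nm)^3
  if (nrow(rows) < 2L) {
    spr_stop("need at least two calibration rows", "sprshell_input_error")
  }
  eeff <- as.complex(rows$eps_eff)
  if (any(!is.finite(Re(eeff)) | !is.finite(Im(eeff)))) {
    spr_stop("effective permittivities must be finite", "sprshell_input_error")
  }
  i_lo <- which.min(rows$f)
  i_hi <- which.max(rows$f)
  if (rows$f[i_lo] == rows$f[i_hi]) {
    spr_stop("calibration rows have identical fill fractions: degenerate system",
             "sprshell_degenerate_error")
  }
  f1 <- rows$f[i_hi]; e1 <- eeff[i_hi]
  f2 <- rows$f[i_lo]; e2 <- eeff[i_lo]
  scale <- max(Mod(c(e1, e2)), 1)

  cand <- .cal_candidates(f1, e1, f2, e2)
  if (!length(cand$es)) {
    spr_stop("constituent calibration failed: no finite algebraic solution",
             "sprshell_calibration_error")
  }
  total_resid <- function(ec, es) {
    sum(vapply(seq_len(nrow(rows)), function(i) {
      Mod(coreshell_eps(core_shell_geometry(f = rows$f[i]), ec, es) -
            eeff[i])
    }, numeric(1)))
  }
  k <- length(cand$es)
  resid_all <- vapply(seq_len(k), function(j) {
    total_resid(cand$ec[j], cand$es[j])
  }, numeric(1))
  pair_resid <- vapply(seq_len(k), function(j) {
    Mod(.cal_g(f1, e1, cand$ec[j], cand$es[j])) +
      Mod(.cal_g(f2, e2, cand$ec[j], cand$es[j]))
  }, numeric(1))
  passive <- Im(cand$es) >= -1e-9 & Im(cand$ec) >= -1e-9
  # linear-in-f extrapolation of the data to the pure-shell / pure-core ends
  es0 <- e2 - (e1 - e2) * f2 / (f1 - f2)
  ec1 <- e1 + (e1 - e2) * (1 - f1) / (f1 - f2)
  heuristic <- Mod(cand$es - es0) + Mod(cand$ec - ec1)
  best <- which(resid_all <= min(resid_all) + 1e-8 * scale)
  if (length(best) > 1L && any(passive[best])) {
    best <- best[passive[best]]
  }
  pick <- best[which.min(heuristic[best])]
  ec <- cand$ec[pick]; es <- cand$es[pick]
  ambiguous <- k > 1L && all(passive) && all(pair_resid < 1e-6 * scale) &&
    diff(range(resid_all)) < 1e-8 * scale
  alternate <- if (k > 1L) {
    j <- setdiff(seq_len(k), pick)[1]
    list(eps_core = cand$ec[j], eps_shell = cand$es[j],
         passive = passive[j])
  }

  # Newton polish with analytic Jacobian (removes rounding from the
  # closed-form evaluation; converges in one or two steps)
  it <- 0L
  repeat {
    G <- c(.cal_g(f1, e1, ec, es), .cal_g(f2, e2, ec, es))
    if (max(Mod(G)) < tol * scale^2) break
    if (it >= max_iter) {
      spr_stop("constituent calibration did not converge",
               "sprshell_calibration_error", residual = max(Mod(G)))
    }
    J <- matrix(c(
      es * (1 + 2 * f1) - e1 * (1 - f1),
      es * (1 + 2 * f2) - e2 * (1 - f2),
      (ec + 4 * es) + 2 * f1 * (ec - 2 * es) - e1 * (2 + f1),
      (ec + 4 * es) + 2 * f2 * (ec - 2 * es) - e2 * (2 + f2)
    ), nrow = 2)
    dx <- tryCatch(solve(J, -G), error = function(e) {
      spr_stop("singular Jacobian during constituent calibration",
               "sprshell_calibration_error")
    })
    step <- min(1, 4 * scale / max(Mod(dx)))
    ec <- ec + step * dx[1]
    es <- es + step * dx[2]
    it <- it + 1L
  }
  res <- vapply(seq_len(nrow(rows)), function(i) {
    Mod(coreshell_eps(core_shell_geometry(f = rows$f[i]), ec, es) - eeff[i])
  }, numeric(1))
  list(eps_core = ec, eps_shell = es, iterations = it,
       residuals = res, calibration_rows = c(i_hi, i_lo),
       ambiguous = ambiguous, alternate = alternate)
}

#' Calibrated core/shell constituent permittivities
#'
#' Convenience wrapper around [recover_constituents()] using the two
#' extreme-fill-fraction rows of the published shell-thickness table
#' (b = 10, a = 11 and b = 10, a = 100 nm) as the calibration pair; the
#' remaining rows of all three tables are left as held-out checks. Fill
#' fractions are always the exact (b/a)^3, never the rounded printed values.
#'
#' @return As [recover_constituents()], plus the `rows` used.
#' @export
calibrated_constituents <- function() {
  tab <- coreshell_tables()
  t1 <- tab[tab$table == 1, ]
  pick <- t1[t1$a_nm %in% c(11, 100) & t1$b_nm == 10, ]
  out <- recover_constituents(pick)
  out$rows <- pick
  out
}
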