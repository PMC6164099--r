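# internal helpers shared across modules

# classed error so callers can distinguish physics failures from bad input
spr_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "sprshell_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

as_complex1 <- function(x, what = "value") {
  if (!(is.numeric(x) || is.complex(x)) || length(x) != 1L) {
    spr_stop(sprintf("%s must be a single numeric or complex value", what),
             "sprshell_input_error")
  }
  x <- as.complex(x)
  if (!is.finite(Re(x)) || !is.finite(Im(x))) {
    spr_stop(sprintf("%s must be finite", what), "sprshell_input_error")
  }
  x
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
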