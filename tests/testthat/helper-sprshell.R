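# shared fixtures for the test suite (all built in code, fully deterministic)

MATS <- default_materials()
CAL <- calibrated_constituents()

# four-layer Kretschmann stack: prism / silver(40) / film(n_film, 20) / air
kretschmann_stack <- function(n_film, d_ag = 40, d_film = 20) {
  layer_stack(list(
    list(material = MATS$bk7, halfspace = TRUE),
    list(material = MATS$silver, thickness_nm = d_ag),
    list(material = n_film, thickness_nm = d_film, name = "film"),
    list(material = MATS$air, halfspace = TRUE)
  ), wavelength_nm = 632.8)
}

# random passive stratified stack: lossless prism, lossy interior films,
# passive exit half-space
random_stack <- function(n_layers) {
  stopifnot(n_layers >= 2)
  mk_eps <- function() complex(real = stats::runif(1, -18, 5),
                               imaginary = stats::runif(1, 0, 4))
  layers <- vector("list", n_layers)
  layers[[1]] <- list(material = stats::runif(1, 1.3, 1.8), halfspace = TRUE)
  if (n_layers > 2) {
    for (j in 2:(n_layers - 1)) {
      layers[[j]] <- list(
        material = optical_constant(eps = mk_eps()),
        thickness_nm = stats::runif(1, 5, 200))
    }
  }
  layers[[n_layers]] <- list(
    material = optical_constant(eps = complex(
      real = stats::runif(1, 0.5, 4), imaginary = stats::runif(1, 0, 1))),
    halfspace = TRUE)
  layer_stack(layers, wavelength_nm = 632.8)
}

random_passive_eps <- function(re_range = c(-15, 6), im_range = c(0, 4)) {
  complex(real = stats::runif(1, re_range[1], re_range[2]),
          imaginary = stats::runif(1, im_range[1], im_range[2]))
}
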