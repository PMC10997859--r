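#' Synthetic tungsten-anode bremsstrahlung spectrum
#'
#' Deterministic Kramers-form bremsstrahlung generator: unfiltered fluence
#' `phi_E proportional to (E_max - E) / E` on `[1 keV, E_max]`, hardened by an
#' aluminium-equivalent self-filtration `t = self_filtration_scale * cot(anode
#' angle)` that emulates the beam hardening inside the anode (smaller angles
#' give longer exit paths through the target and thus harder beams).  No
#' characteristic x-ray lines are modelled; the generator exists to exercise
#' every algorithm offline, not to replace a full tube-spectrum model.
#'
#' @param tube_potential tube voltage in kV (= E_max in keV).
#' @param anode_angle anode angle in degrees, in (0, 90).
#' @param self_filtration_scale mm of aluminium-equivalent self-filtration per
#'   unit of `cot(anode_angle)`.  The default 0.1 mm puts about 0.5 mm
#'   Al-equivalent in the beam at the conventional 12 degree angle, typical of
#'   a lightly filtered diagnostic tube port.
#' @param grid_step energy grid step in keV.
#' @return An [energy_spectrum()] with tube metadata attached.
#' @export
synthetic_spectrum <- function(tube_potential, anode_angle,
                               self_filtration_scale = 0.1,
                               grid_step = 0.5) {
  if (!is.finite(tube_potential) || tube_potential <= grid_step) {
    stop("tube_potential must exceed the grid step")
  }
  if (!is.finite(anode_angle) || anode_angle <= 0 || anode_angle >= 90) {
    stop("anode_angle must lie in (0, 90) degrees")
  }
  e <- seq(ENERGY_CUTOFF_KEV, tube_potential, by = grid_step)
  if (e[length(e)] < tube_potential - 1e-9) e <- c(e, tube_potential)
  phi <- (tube_potential - e) / e
  phi[length(phi)] <- 0  # Kramers endpoint
  t_self <- self_filtration_scale / tan(anode_angle * pi / 180)
  mu <- interpolate_coefficient(al_attenuation(), e)
  phi <- phi * exp(-mu * t_self)
  energy_spectrum(
    e, phi, kv = tube_potential, anode_deg = anode_angle,
    provider = sprintf("synthetic-kramers/self_filtration_scale=%g",
                       self_filtration_scale)
  )
}

#' Spectrum providers
#'
#' A spectrum provider is a function `(tube_potential_kv, anode_angle_deg) ->
#' energy_spectrum` used by the establishment routines.
#' `synthetic_provider()` wraps [synthetic_spectrum()]; `spekpy_provider()`
#' adapts the external SpekPy tungsten-anode model (run through the `python`
#' interpreter) with its default configuration at 1 m in air, and fails with
#' an installation hint when the model is not importable.  The provider's
#' parameter resolution (for caching) is carried as the `"resolution"`
#' attribute; the synthetic generator is exact in its parameters, so its
#' resolution is 0 and caching only ever reuses exact repeats.
#'
#' @param self_filtration_scale,grid_step passed to [synthetic_spectrum()].
#' @return A provider function.
#' @export
synthetic_provider <- function(self_filtration_scale = 0.1, grid_step = 0.5) {
  f <- function(tube_potential, anode_angle) {
    synthetic_spectrum(tube_potential, anode_angle,
                       self_filtration_scale = self_filtration_scale,
                       grid_step = grid_step)
  }
  attr(f, "resolution") <- 0
  attr(f, "name") <- "synthetic-kramers"
  f
}

#' @rdname synthetic_provider
#' @param python path to the python interpreter with the external model.
#' @export
spekpy_provider <- function(python = "python") {
  probe <- suppressWarnings(
    system2(python, c("-c", shQuote("import spekpy")),
            stdout = FALSE, stderr = FALSE)
  )
  if (!identical(probe, 0L)) {
    stop(
      "the external SpekPy spectrum model is not importable from '", python,
      "'; install it with 'pip install spekpy' to use this provider, or use ",
      "synthetic_provider() for offline work",
      call. = FALSE
    )
  }
  f <- function(tube_potential, anode_angle) {
    out <- tempfile(fileext = ".csv")
    code <- sprintf(paste0(
      "import spekpy, numpy as np\n",
      "s = spekpy.Spek(kvp=%.10g, th=%.10g)\n",
      "e, phi = s.get_spectrum(edges=False)\n",
      "np.savetxt(%s, np.column_stack([e, phi]), delimiter=',')\n"
    ), tube_potential, anode_angle, deparse(out))
    status <- system2(python, c("-c", shQuote(code)))
    if (!identical(status, 0L)) stop("external spectrum model call failed")
    dat <- utils::read.table(out, sep = ",", col.names = c("energy", "fluence"))
    keep <- dat$energy >= ENERGY_CUTOFF_KEV
    ver <- system2(python, c("-c", shQuote("import spekpy;print(spekpy.__version__)")),
                   stdout = TRUE)
    energy_spectrum(dat$energy[keep], dat$fluence[keep],
                    kv = tube_potential, anode_deg = anode_angle,
                    provider = sprintf("spekpy/%s", ver[1]))
  }
  attr(f, "resolution") <- 0
  attr(f, "name") <- "spekpy"
  f
}

#' Is a spectrum provider usable?
#'
#' @param provider a provider name (`"synthetic"` or `"spekpy"`).
#' @return `TRUE` or `FALSE` (never an error).
#' @export
provider_available <- function(provider = "spekpy") {
  if (identical(provider, "synthetic")) return(TRUE)
  identical(
    suppressWarnings(system2("python", c("-c", shQuote("import spekpy")),
                             stdout = FALSE, stderr = FALSE)),
    0L
  )
}
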