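#' Photon fluence spectrum
#'
#' Construct a photon-fluence spectrum: fluence per unit energy
#' (photons mm^-2 keV^-1, conventionally at 1 m from the focal spot) on a
#' strictly ascending energy grid in keV.  The absolute fluence scale is
#' irrelevant to SNR2_in, which is a ratio; air kerma scales linearly with it.
#'
#' @param energies keV grid, strictly ascending, all >= 1 keV.
#' @param fluence photons mm^-2 keV^-1, non-negative, at least one positive.
#' @param kv tube potential metadata in kV (optional); when present the grid
#'   must not exceed it.
#' @param anode_deg anode angle metadata in degrees (optional).
#' @param filtration list of applied filtrations, each `list(material=, mm=)`.
#' @param provider free-text provenance of the spectrum model (optional).
#' @return An object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(energies, fluence, kv = NULL, anode_deg = NULL,
                            filtration = list(), provider = NULL) {
  energies <- as.numeric(energies)
  fluence <- as.numeric(fluence)
  if (length(energies) != length(fluence)) {
    stop("energies and fluence must have equal length")
  }
  if (length(energies) < 2) stop("a spectrum needs at least 2 grid points")
  if (any(diff(energies) <= 0)) stop("energy grid must be strictly ascending")
  if (any(energies < ENERGY_CUTOFF_KEV * (1 - 1e-9))) {
    stop("energy grid must not extend below the 1 keV cutoff")
  }
  if (any(!is.finite(fluence)) || any(fluence < 0)) {
    stop("fluence must be finite and non-negative")
  }
  if (!any(fluence > 0)) stop("spectrum has no positive fluence")
  if (!is.null(kv) && max(energies) > kv * (1 + 1e-9)) {
    stop("energy grid exceeds the stated tube potential")
  }
  structure(
    list(energies = energies, fluence = fluence, kv = kv,
         anode_deg = anode_deg, filtration = filtration, provider = provider),
    class = "energy_spectrum"
  )
}

#' @export
print.energy_spectrum <- function(x, ...) {
  filt <- if (length(x$filtration)) {
    paste(vapply(x$filtration, function(f) sprintf("%s %.4g mm", f$material, f$mm),
                 character(1)), collapse = " + ")
  } else "none"
  cat(sprintf(
    "<energy_spectrum> %d bins, %.4g-%.4g keV%s%s, filtration: %s\n",
    length(x$energies), min(x$energies), max(x$energies),
    if (!is.null(x$kv)) sprintf(", %g kV", x$kv) else "",
    if (!is.null(x$anode_deg)) sprintf(", anode %g deg", x$anode_deg) else "",
    filt
  ))
  invisible(x)
}

#' Attenuate a spectrum by an aluminium filter (Beer-Lambert)
#'
#' Multiplies the fluence bin-wise by `exp(-mu_al(E) * thickness)`.  The grid
#' is unchanged (no regridding) and the filtration metadata is appended.
#' Attenuation composes: `attenuate(s, a + b)` equals
#' `attenuate(attenuate(s, a), b)` bin-wise.
#'
#' @param spectrum an [energy_spectrum()].
#' @param thickness aluminium thickness in mm, >= 0.
#' @param table attenuation coefficient table (1/mm); defaults to the
#'   packaged aluminium table.
#' @return The attenuated `energy_spectrum`.
#' @export
attenuate <- function(spectrum, thickness, table = al_attenuation()) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  if (!is.finite(thickness) || thickness < 0) {
    stop("filter thickness must be finite and >= 0")
  }
  mu <- spectrum_mu(spectrum, table)
  out <- spectrum
  out$fluence <- spectrum$fluence * exp(-mu * thickness)
  if (thickness > 0) {
    out$filtration <- c(spectrum$filtration,
                        list(list(material = "Al", mm = thickness)))
  }
  # fluence may underflow to all-zero only for absurd thickness; guard
  if (!any(out$fluence > 0)) stop("attenuation removed all fluence")
  out
}

# mu_al interpolated once per spectrum grid and cached on the object's
# environment-free structure via attribute; recomputing gives bit-identical
# values so the cache is purely an optimisation.
spectrum_mu <- function(spectrum, table = al_attenuation()) {
  cached <- attr(spectrum, ".mu_al")
  if (!is.null(cached) && identical(attr(cached, "kind"), table$kind) &&
      length(cached) == length(spectrum$energies)) {
    return(as.numeric(cached))
  }
  interpolate_coefficient(table, spectrum$energies)
}

#' Read and write spectrum CSV files
#'
#' The on-disk dialect is plain CSV with `#`-prefixed header lines carrying
#' metadata (`kv`, `anode_deg`, `filtration`, `provider`, `schema_version`)
#' followed by two comma-separated columns `energy_keV,fluence_per_keV_per_mm2`.
#' The round trip preserves grids and fluence to full double precision.
#'
#' @param spectrum an [energy_spectrum()].
#' @param path file path.
#' @return `write_spectrum_csv` returns `path` invisibly; `read_spectrum_csv`
#'   returns an `energy_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  filt <- paste(
    vapply(spectrum$filtration, function(f) sprintf("%s:%.17g", f$material, f$mm),
           character(1)),
    collapse = ";"
  )
  hdr <- c(
    "# schema_version: 1",
    if (!is.null(spectrum$kv)) sprintf("# kv: %.17g", spectrum$kv),
    if (!is.null(spectrum$anode_deg)) sprintf("# anode_deg: %.17g", spectrum$anode_deg),
    if (nzchar(filt)) sprintf("# filtration: %s", filt),
    if (!is.null(spectrum$provider)) sprintf("# provider: %s", spectrum$provider),
    "energy_keV,fluence_per_keV_per_mm2"
  )
  body <- sprintf("%.17g,%.17g", spectrum$energies, spectrum$fluence)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s: ", key), meta_lines, value = TRUE)
    if (!length(hit)) NULL else sub(sprintf("^# %s: ", key), "", hit[1])
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[!grepl("^energy_keV", body) & nzchar(trimws(body))]
  dat <- utils::read.table(text = body, sep = ",",
                           col.names = c("energy", "fluence"))
  filtration <- list()
  fs <- get_meta("filtration")
  if (!is.null(fs) && nzchar(fs)) {
    filtration <- lapply(strsplit(fs, ";")[[1]], function(tok) {
      parts <- strsplit(tok, ":")[[1]]
      list(material = parts[1], mm = as.numeric(parts[2]))
    })
  }
  kv <- get_meta("kv")
  anode <- get_meta("anode_deg")
  energy_spectrum(
    dat$energy, dat$fluence,
    kv = if (is.null(kv)) NULL else as.numeric(kv),
    anode_deg = if (is.null(anode)) NULL else as.numeric(anode),
    filtration = filtration,
    provider = get_meta("provider")
  )
}
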