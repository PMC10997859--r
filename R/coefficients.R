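# Conversion from the spectral kerma integrand [keV * cm^2/g * mm^-2] to uGy:
# 1 keV = 1.602176634e-16 J, 1 cm^2/g = 0.1 m^2/kg, 1 mm^-2 = 1e6 m^-2,
# 1 Gy = 1e6 uGy.  Verified against a hand-computed monoenergetic case in the
# test suite.
UGY_PER_KEV_CM2G_MM2 <- 1.602176634e-5

# Energies below this are outside the validity of the spectral model and of
# the packaged coefficient tables' intended use; integration clips here.
ENERGY_CUTOFF_KEV <- 1.0

#' Energy-indexed interaction coefficient table
#'
#' Construct a table of interaction coefficients versus photon energy, the
#' carrier for the mass energy-transfer coefficient of air (cm^2/g) and the
#' linear attenuation coefficient of aluminium (1/mm).  Absorption edges are
#' represented by two nodes at (numerically) almost identical energies; the
#' constructor detects these and records smooth-segment boundaries so that
#' interpolation never straddles an edge.
#'
#' @param energies numeric, photon energies in keV, strictly increasing, > 0.
#' @param values numeric, coefficient values, all > 0.  Units are cm^2/g for
#'   mass coefficients and 1/mm for linear attenuation coefficients.
#' @param kind one of `"mass_energy_transfer_air"`, `"total_attenuation_al"`
#'   or another descriptive label.
#' @return An object of class `coefficient_table`.
#' @export
coefficient_table <- function(energies, values, kind = "generic") {
  energies <- as.numeric(energies)
  values <- as.numeric(values)
  if (length(energies) != length(values)) {
    stop("energies and values must have equal length")
  }
  if (length(energies) < 2) stop("a coefficient table needs at least 2 nodes")
  if (any(!is.finite(energies)) || any(energies <= 0)) {
    stop("energies must be finite and > 0")
  }
  if (any(diff(energies) <= 0)) stop("energies must be strictly increasing")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("coefficient values must be finite and > 0")
  }
  # Edge detection: consecutive nodes closer than 1e-4 relative mark an
  # absorption edge; interpolation is confined to the smooth segment.
  edge <- which(diff(energies) / energies[-length(energies)] < 1e-4)
  segment <- cumsum(c(1L, as.integer(seq_along(energies)[-1] %in% (edge + 1L))))
  structure(
    list(energies = energies, values = values, kind = kind, segment = segment),
    class = "coefficient_table"
  )
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat(sprintf(
    "<coefficient_table> kind=%s, %d nodes, %.4g-%.4g keV, %d smooth segment(s)\n",
    x$kind, length(x$energies), min(x$energies), max(x$energies),
    max(x$segment)
  ))
  invisible(x)
}

#' Interpolate a coefficient table quadratically on a log-log scale
#'
#' Evaluates the coefficient at arbitrary energies by fitting a quadratic
#' through the logarithms of the three nearest tabulated nodes (log energy vs
#' log value) and exponentiating, the standard scheme for photon interaction
#' data.  Tabulated values are reproduced exactly at the nodes.  Windows never
#' straddle an absorption edge; within a two-node segment the scheme degrades
#' to log-log linear.
#'
#' @param table a [coefficient_table()].
#' @param energy numeric vector of query energies in keV; every element must
#'   lie within the table span (no extrapolation).
#' @return numeric vector of interpolated coefficient values.
#' @export
interpolate_coefficient <- function(table, energy) {
  stopifnot(inherits(table, "coefficient_table"))
  e <- as.numeric(energy)
  if (any(!is.finite(e))) stop("query energies must be finite")
  lo <- table$energies[1L]
  hi <- table$energies[length(table$energies)]
  if (any(e < lo * (1 - 1e-12)) || any(e > hi * (1 + 1e-12))) {
    stop(sprintf(
      "energy out of table range [%.6g, %.6g] keV for kind '%s'",
      lo, hi, table$kind
    ))
  }
  e <- pmin(pmax(e, lo), hi)
  lx <- log(table$energies)
  ly <- log(table$values)
  n <- length(lx)
  # Interval index: i such that x[i] <= q < x[i+1]
  i <- findInterval(e, table$energies, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= n] <- n - 1L
  # Queries sitting exactly on a node (including the doubled edge nodes)
  # return the tabulated value of that node.
  exact_lo <- abs(e - table$energies[i]) <= 1e-12 * e
  exact_hi <- abs(e - table$energies[i + 1L]) <= 1e-12 * e
  exact <- exact_lo | exact_hi
  if (any(exact)) {
    out <- numeric(length(e))
    out[exact] <- table$values[ifelse(exact_lo, i, i + 1L)][exact]
    if (any(!exact)) {
      out[!exact] <- interpolate_coefficient(
        table, e[!exact]
      )
    }
    return(out)
  }
  # Queries landing between the doubled edge nodes snap to the upper branch.
  on_edge <- table$segment[i] != table$segment[i + 1L]
  i[on_edge] <- pmin(i[on_edge] + 1L, n - 1L)

  # Window start: the 3 nodes (j, j+1, j+2); prefer centring the nearer node
  # in log distance, then clamp into the segment of the bracketing interval.
  lq <- log(e)
  j <- ifelse(lq - lx[i] < lx[i + 1L] - lq, i - 1L, i)
  seg <- table$segment[i]
  seg_first <- match(seg, table$segment)                 # first index of segment
  seg_last <- n + 1L - match(seg, rev(table$segment))    # last index of segment
  j <- pmax(j, seg_first)
  j <- pmin(j, seg_last - 2L)
  two_node <- seg_last - seg_first < 2L                  # segment too short

  out <- numeric(length(e))
  q3 <- !two_node
  if (any(q3)) {
    j3 <- j[q3]
    x1 <- lx[j3]; x2 <- lx[j3 + 1L]; x3 <- lx[j3 + 2L]
    y1 <- ly[j3]; y2 <- ly[j3 + 1L]; y3 <- ly[j3 + 2L]
    x <- lq[q3]
    out[q3] <- exp(
      y1 * (x - x2) * (x - x3) / ((x1 - x2) * (x1 - x3)) +
      y2 * (x - x1) * (x - x3) / ((x2 - x1) * (x2 - x3)) +
      y3 * (x - x1) * (x - x2) / ((x3 - x1) * (x3 - x2))
    )
  }
  if (any(two_node)) {
    jl <- pmax(i[two_node], 1L)
    x1 <- lx[jl]; x2 <- lx[jl + 1L]
    y1 <- ly[jl]; y2 <- ly[jl + 1L]
    x <- lq[two_node]
    out[two_node] <- exp(y1 + (y2 - y1) * (x - x1) / (x2 - x1))
  }
  out
}

#' Quadrature weights for composite Simpson integration on a grid
#'
#' Returns weights `w` such that `sum(w * f)` is the composite Simpson
#' integral of samples `f` over the (possibly non-uniform) ascending grid.
#' Interval pairs are integrated by the quadratic through their three nodes;
#' a trailing odd interval is integrated by the trapezoidal rule.
#'
#' @param energies ascending numeric grid (>= 3 points).
#' @return numeric weight vector of the same length.
#' @keywords internal
simpson_weights <- function(energies) {
  x <- as.numeric(energies)
  n <- length(x)
  if (n < 3) stop("Simpson integration needs at least 3 samples")
  if (any(diff(x) <= 0)) stop("grid must be strictly ascending")
  w <- numeric(n)
  k <- 1L
  while (k + 2L <= n) {
    h1 <- x[k + 1L] - x[k]
    h2 <- x[k + 2L] - x[k + 1L]
    h <- h1 + h2
    w[k]       <- w[k]       + h / 6 * (2 - h2 / h1)
    w[k + 1L]  <- w[k + 1L]  + h / 6 * (h * h / (h1 * h2))
    w[k + 2L]  <- w[k + 2L]  + h / 6 * (2 - h1 / h2)
    k <- k + 2L
  }
  if (k < n) {  # one interval left: trapezoid
    h <- x[n] - x[n - 1L]
    w[n - 1L] <- w[n - 1L] + h / 2
    w[n]      <- w[n]      + h / 2
  }
  w
}

#' Composite Simpson integration of sampled values over an energy grid
#'
#' Integrates `values` over `energies` by the composite Simpson rule (pairs of
#' intervals fitted by a quadratic; a trailing odd interval by the
#' trapezoidal rule).  Samples below the 1 keV cutoff are discarded before
#' integration.  The result is linear in the integrand.
#'
#' @param values numeric samples of the integrand.
#' @param energies ascending numeric grid in keV, same length.
#' @return the integral (scalar).
#' @export
integrate_spectrum <- function(values, energies) {
  if (length(values) != length(energies)) stop("values/energies length mismatch")
  keep <- energies >= ENERGY_CUTOFF_KEV * (1 - 1e-12)
  values <- values[keep]
  energies <- energies[keep]
  if (length(energies) < 3) {
    stop("Simpson integration needs at least 3 samples above the 1 keV cutoff")
  }
  sum(simpson_weights(energies) * values)
}

.rqbeam_env <- new.env(parent = emptyenv())

# Densify a table to ~n_total log-spaced nodes (allocated per smooth
# segment, segment boundaries kept exactly), mirroring the convention of
# evaluating interaction data on a fine logarithmic energy grid.  Values on
# the dense grid come from the log-log quadratic interpolant of the source
# nodes, so the physics content is unchanged; downstream interpolation then
# operates in a regime where quadratic and linear log-log schemes agree
# closely.
densify_table <- function(table, n_total = 2000) {
  segs <- unique(table$segment)
  spans <- vapply(segs, function(s) {
    e <- table$energies[table$segment == s]
    log(max(e)) - log(min(e))
  }, numeric(1))
  e_out <- numeric(0)
  v_out <- numeric(0)
  for (k in seq_along(segs)) {
    idx <- table$segment == segs[k]
    e <- table$energies[idx]
    v <- table$values[idx]
    n_seg <- max(length(e), round(n_total * spans[k] / sum(spans)))
    sub <- coefficient_table(e, v, kind = table$kind)
    grid <- exp(seq(log(e[1]), log(e[length(e)]), length.out = n_seg))
    grid[1] <- e[1]
    grid[n_seg] <- e[length(e)]
    e_out <- c(e_out, grid)
    v_out <- c(v_out, interpolate_coefficient(sub, grid))
  }
  coefficient_table(e_out, v_out, kind = table$kind)
}

read_coefficient_file <- function(path, kind) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  dat <- utils::read.table(text = body, col.names = c("energy", "value"))
  values <- dat$value
  # A stated density in the header means the file carries mass attenuation
  # coefficients (cm^2/g) to be converted to linear attenuation (1/mm).
  m <- regmatches(header, regexpr("density_g_cm3: [0-9.]+", header))
  m <- unlist(m)
  if (length(m)) {
    density <- as.numeric(sub("density_g_cm3: ", "", m[1]))
    values <- values * density * 0.1  # cm^2/g * g/cm^3 * cm/mm -> 1/mm
  }
  densify_table(coefficient_table(dat$energy, values, kind = kind))
}

#' Packaged coefficient tables
#'
#' `air_energy_transfer()` returns the mass energy-transfer coefficient table
#' of dry air (cm^2/g); `al_attenuation()` the linear attenuation coefficient
#' of aluminium including coherent scattering (1/mm at 2.699 g/cm^3).  Both
#' are loaded once per session from the packaged plain-text compilation and
#' may be overridden by pointing `path` at a file in the same format.
#'
#' @param path optional path to an alternative table file.
#' @return A [coefficient_table()].
#' @export
air_energy_transfer <- function(path = NULL) {
  if (!is.null(path)) {
    return(read_coefficient_file(path, "mass_energy_transfer_air"))
  }
  if (is.null(.rqbeam_env$air)) {
    .rqbeam_env$air <- read_coefficient_file(
      system.file("extdata", "mutr_air.tsv", package = "rqbeam", mustWork = TRUE),
      "mass_energy_transfer_air"
    )
  }
  .rqbeam_env$air
}

#' @rdname air_energy_transfer
#' @export
al_attenuation <- function(path = NULL) {
  if (!is.null(path)) {
    return(read_coefficient_file(path, "total_attenuation_al"))
  }
  if (is.null(.rqbeam_env$al)) {
    .rqbeam_env$al <- read_coefficient_file(
      system.file("extdata", "mu_al.tsv", package = "rqbeam", mustWork = TRUE),
      "total_attenuation_al"
    )
  }
  .rqbeam_env$al
}
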