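#' Tolerance box for the influence quantities
#'
#' The IEC establishment tolerances treated as independent rectangular
#' distributions: anode angle (degrees), tube-voltage deviation delta-PPV
#' (kV) and relative reference-HVL shift (percent).  Defaults mirror the
#' standard's leeway: angle in [9, 30] degrees, delta-PPV in [-2.25, 2.25] kV
#' (the conservative reading of the 1.5 % / 1.5 kV PPV uncertainty at k = 2)
#' and HVL_ref shift in [-5, 5] %.
#'
#' @param anode_angle length-2 numeric range in degrees.
#' @param delta_ppv length-2 numeric range in kV.
#' @param delta_hvl_ref length-2 numeric range in percent.
#' @return An object of class `variation_box`.
#' @export
variation_box <- function(anode_angle = c(9, 30),
                          delta_ppv = c(-2.25, 2.25),
                          delta_hvl_ref = c(-5, 5)) {
  for (r in list(anode_angle, delta_ppv, delta_hvl_ref)) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      stop("each range must be a finite length-2 vector with lower <= upper")
    }
  }
  structure(
    list(anode_angle = as.numeric(anode_angle),
         delta_ppv = as.numeric(delta_ppv),
         delta_hvl_ref = as.numeric(delta_hvl_ref),
         distribution = "rectangular"),
    class = "variation_box"
  )
}

check_in_box <- function(box, anode_angle, delta_ppv, delta_hvl_ref) {
  tol <- 1e-9
  inside <- anode_angle >= box$anode_angle[1] - tol &&
    anode_angle <= box$anode_angle[2] + tol &&
    delta_ppv >= box$delta_ppv[1] - tol &&
    delta_ppv <= box$delta_ppv[2] + tol &&
    delta_hvl_ref >= box$delta_hvl_ref[1] - tol &&
    delta_hvl_ref <= box$delta_hvl_ref[2] + tol
  if (!inside) {
    stop("establishment parameters outside the tolerance box; pass enforce_box = FALSE to override")
  }
  invisible(TRUE)
}

# Wrap a provider with an exact-key cache honouring its declared parameter
# resolution.  With resolution 0 only bit-identical repeats hit the cache,
# so cached and uncached runs are identical.
cached_provider <- function(provider) {
  res <- attr(provider, "resolution") %||% 0
  cache <- new.env(parent = emptyenv())
  f <- function(tube_potential, anode_angle) {
    if (res > 0) {
      tube_potential <- round(tube_potential / res) * res
      anode_angle <- round(anode_angle / res) * res
    }
    key <- sprintf("%.17g|%.17g", tube_potential, anode_angle)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cache[[key]] <- provider(tube_potential, anode_angle)
  }
  attributes(f) <- attributes(provider)
  f
}

#' Scan the tolerance-box corners for SNR2_in extrema
#'
#' Establishes the RQA quality at all 8 corners of the box plus the
#' `delta_ppv = 0` edge midpoints at both anode-angle extremes (the extremum
#' need not sit at a corner for the qualities where the tube-voltage
#' sensitivity changes sign), and returns the argmin/argmax beams together
#' with the full evaluation table.
#'
#' @inheritParams establish_rqa
#' @param box a [variation_box()].
#' @return A list with `min` and `max` (`established_beam`s), `spread_pct`
#'   (`100 * (max - min) / min` of SNR2_in) and `table` (a data frame of all
#'   evaluated parameter triples and their SNR2_in).
#' @export
corner_scan <- function(quality, box = variation_box(),
                        provider = synthetic_provider()) {
  provider <- cached_provider(provider)
  grid <- expand.grid(
    anode_angle = box$anode_angle,
    delta_ppv = unique(c(box$delta_ppv, 0)),
    delta_hvl_ref = box$delta_hvl_ref,
    KEEP.OUT.ATTRS = FALSE
  )
  beams <- vector("list", nrow(grid))
  snr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    beams[[i]] <- establish_rqa(quality, grid$anode_angle[i],
                                grid$delta_ppv[i], grid$delta_hvl_ref[i],
                                provider = provider, box = box)
    snr[i] <- beams[[i]]$dosimetry$snr_in2
  }
  grid$snr_in2 <- snr
  i_min <- which.min(snr)
  i_max <- which.max(snr)
  list(
    min = beams[[i_min]],
    max = beams[[i_max]],
    spread_pct = 100 * (snr[i_max] - snr[i_min]) / snr[i_min],
    table = grid
  )
}

#' GUM Supplement 2 Monte Carlo propagation of the tolerance box
#'
#' Draws the three influence quantities independently from rectangular
#' distributions over the [variation_box()], establishes the RQA quality for
#' every draw and summarises the resulting SNR2_in sample: mean, standard
#' uncertainty `u` (sample standard deviation) and the probabilistically
#' symmetric 95 % coverage interval (equal 2.5 % tail masses, linear
#' interpolation between order statistics).  Fully reproducible for a given
#' seed.
#'
#' @inheritParams corner_scan
#' @param n_draws number of Monte Carlo draws (>= 1000 for reported
#'   statistics).
#' @param seed integer RNG seed.
#' @return An object of class `uncertainty_result` with fields `quality`,
#'   `n_draws`, `seed`, `samples`, `draws` (parameter triples), `mean`, `u`,
#'   `coverage_95` and `skewness`.
#' @export
propagate_uncertainty <- function(quality, box = variation_box(),
                                  n_draws = 10000, seed = 1,
                                  provider = synthetic_provider()) {
  q <- if (inherits(quality, "quality_definition")) quality else rqbeam::quality(quality)
  if (n_draws < 1) stop("n_draws must be >= 1")
  provider <- cached_provider(provider)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  draws <- data.frame(
    anode_angle = runif(n_draws, box$anode_angle[1], box$anode_angle[2]),
    delta_ppv = runif(n_draws, box$delta_ppv[1], box$delta_ppv[2]),
    delta_hvl_ref = runif(n_draws, box$delta_hvl_ref[1], box$delta_hvl_ref[2])
  )
  samples <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    beam <- tryCatch(
      establish_rqa(q, draws$anode_angle[i], draws$delta_ppv[i],
                    draws$delta_hvl_ref[i], provider = provider, box = box),
      error = function(e) {
        stop(sprintf(
          "establishment failed at draw %d (angle %.4f deg, dPPV %+.4f kV, dHVL %+.4f %%): %s",
          i, draws$anode_angle[i], draws$delta_ppv[i], draws$delta_hvl_ref[i],
          conditionMessage(e)
        ), call. = FALSE)
      }
    )
    samples[i] <- beam$dosimetry$snr_in2
  }
  m <- mean(samples)
  structure(
    list(
      quality = q$name,
      n_draws = n_draws,
      seed = seed,
      samples = samples,
      draws = draws,
      mean = m,
      u = stats::sd(samples),
      coverage_95 = unname(stats::quantile(samples, c(0.025, 0.975), type = 7)),
      skewness = sample_skewness(samples)
    ),
    class = "uncertainty_result"
  )
}

# Moment-based sample skewness m3 / m2^(3/2).
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf(
    paste0("<uncertainty_result> %s, n = %d (seed %d)\n",
           "  SNR2_in = %.6g, u(y) = %.4g mm^-2 uGy^-1 (%.3g %%)\n",
           "  95 %% coverage interval [%.6g, %.6g], skewness %.3f\n"),
    x$quality, x$n_draws, x$seed, x$mean, x$u, 100 * x$u / x$mean,
    x$coverage_95[1], x$coverage_95[2], x$skewness
  ))
  invisible(x)
}

#' Histogram and summary row of a Monte Carlo result
#'
#' Bins the SNR2_in sample into `bins` equal-width classes over its range and
#' returns the binned counts alongside the summary-table row (mean, standard
#' uncertainty, coverage interval).  The histogram mass equals `n_draws`.
#'
#' @param result an `uncertainty_result`.
#' @param bins number of histogram bins.
#' @return A list with `histogram` (data frame: `lower`, `upper`, `mid`,
#'   `count`) and `summary` (one-row data frame: `quality`, `mean`, `u`,
#'   `rel_u_pct`, `ci_low`, `ci_high`, `skewness`, `n_draws`, `seed`).
#' @export
summarize_uncertainty <- function(result, bins = 30) {
  stopifnot(inherits(result, "uncertainty_result"), bins >= 1)
  rng <- range(result$samples)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # degenerate box
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(result$samples, breaks, rightmost.closed = TRUE), 1L),
         bins),
    nbins = bins
  )
  list(
    histogram = data.frame(
      lower = breaks[-(bins + 1)],
      upper = breaks[-1],
      mid = (breaks[-(bins + 1)] + breaks[-1]) / 2,
      count = counts
    ),
    summary = data.frame(
      quality = result$quality,
      mean = result$mean,
      u = result$u,
      rel_u_pct = 100 * result$u / result$mean,
      ci_low = result$coverage_95[1],
      ci_high = result$coverage_95[2],
      skewness = result$skewness,
      n_draws = result$n_draws,
      seed = result$seed,
      stringsAsFactors = FALSE
    )
  )
}
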