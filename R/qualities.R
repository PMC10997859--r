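#' IEC 61267 quality definitions
#'
#' Loads the packaged (user-editable) constants defining the RQR and RQA
#' standard radiation qualities: nominal tube voltage, reference first HVL,
#' nominal homogeneity coefficient, and for RQA members the fixed additional
#' aluminium filtration and the parent RQR quality.
#'
#' @param path optional path to an alternative YAML configuration.
#' @return A named list of `quality_definition` objects keyed by quality name
#'   (`"RQR 2"` ... `"RQA 10"`).
#' @export
quality_definitions <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rqbeam_env$qualities)) return(.rqbeam_env$qualities)
    path <- system.file("extdata", "qualities.yaml", package = "rqbeam",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  cfg <- yaml::read_yaml(path)
  defs <- list()
  for (name in names(cfg$rqr)) {
    q <- cfg$rqr[[name]]
    defs[[name]] <- structure(
      list(name = name, series = "RQR", nominal_kv = q$nominal_kv,
           hvl_ref = q$hvl_ref, nominal_h = q$nominal_h,
           rqa_added_al = NULL, parent = NULL),
      class = "quality_definition"
    )
  }
  for (name in names(cfg$rqa)) {
    q <- cfg$rqa[[name]]
    parent <- defs[[q$parent]]
    if (is.null(parent)) {
      stop(sprintf("RQA quality '%s' references unknown parent '%s'",
                   name, q$parent))
    }
    stopifnot(q$added_al > 0)
    defs[[name]] <- structure(
      list(name = name, series = "RQA", nominal_kv = parent$nominal_kv,
           hvl_ref = parent$hvl_ref, nominal_h = parent$nominal_h,
           rqa_added_al = q$added_al, parent = parent$name),
      class = "quality_definition"
    )
  }
  for (d in defs) {
    if (d$nominal_kv < 40 || d$nominal_kv > 150) {
      stop(sprintf("quality '%s': nominal kV outside [40, 150]", d$name))
    }
    if (d$hvl_ref <= 0) stop(sprintf("quality '%s': hvl_ref must be > 0", d$name))
  }
  if (cache) .rqbeam_env$qualities <- defs
  defs
}

#' @rdname quality_definitions
#' @param name quality name, e.g. `"RQA 7"` (case-insensitive, the space is
#'   optional: `"rqa7"` works).
#' @export
quality <- function(name, path = NULL) {
  defs <- quality_definitions(path)
  key <- toupper(gsub("[ _-]", "", name))
  keys <- toupper(gsub("[ _-]", "", names(defs)))
  hit <- match(key, keys)
  if (is.na(hit)) {
    stop(sprintf("unknown radiation quality '%s' (known: %s)", name,
                 paste(names(defs), collapse = ", ")))
  }
  defs[[hit]]
}

#' @export
print.quality_definition <- function(x, ...) {
  cat(sprintf(
    "<quality_definition> %s: %g kV, HVL_ref %.2f mm Al, h %.2f%s\n",
    x$name, x$nominal_kv, x$hvl_ref, x$nominal_h,
    if (!is.null(x$rqa_added_al)) {
      sprintf(", +%g mm Al on %s", x$rqa_added_al, x$parent)
    } else ""
  ))
  invisible(x)
}

#' Names of the RQA (or RQR) series in the active configuration
#'
#' @param series `"RQA"` or `"RQR"`.
#' @inheritParams quality_definitions
#' @return character vector of quality names in configuration order.
#' @export
quality_names <- function(series = c("RQA", "RQR"), path = NULL) {
  series <- match.arg(series)
  defs <- quality_definitions(path)
  names(defs)[vapply(defs, function(d) d$series == series, logical(1))]
}
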