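# Parameter registry: all method/version constants ship as data in
# inst/extdata/parameters.yaml and are accessed through default_params().

.wg_env <- new.env(parent = emptyenv())

wg_registry <- function() {
  if (is.null(.wg_env$registry)) {
    path <- system.file("extdata", "parameters.yaml", package = "wristgait")
    if (!nzchar(path)) {
      # during development (pkgload) the file sits under inst/
      path <- system.file("inst", "extdata", "parameters.yaml", package = "wristgait")
    }
    .wg_env$registry <- yaml::read_yaml(path)
  }
  .wg_env$registry
}

#' Registered methods and versions
#'
#' @param family `"gsd"`, `"icd"` or `"sl"`; NULL lists everything.
#' @return data.frame with columns family, method, version.
#' @export
list_methods <- function(family = NULL) {
  reg <- wg_registry()
  fams <- intersect(c("gsd", "icd", "sl"), names(reg))
  if (!is.null(family)) fams <- intersect(fams, family)
  rows <- do.call(rbind, lapply(fams, function(f) {
    do.call(rbind, lapply(names(reg[[f]]), function(m) {
      data.frame(family = f, method = m, version = names(reg[[f]][[m]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Default parameters for a method version
#'
#' Returns the registered constants for `(method, version)` verbatim, each
#' with its unit tag. Unknown pairs raise an error listing the available
#' versions of that method (or all methods when the method is unknown).
#'
#' @param method method identifier (e.g. `"kheirkhahan"`, `"weinberg"`).
#' @param version version identifier (e.g. `"wrist"`, `"improved"`).
#' @return an object of class `wg_params`: list with `method`, `version` and
#'   `params` (name -> list(value, unit)).
#' @export
default_params <- function(method, version) {
  reg <- wg_registry()
  for (fam in c("gsd", "icd", "sl")) {
    if (method %in% names(reg[[fam]])) {
      versions <- names(reg[[fam]][[method]])
      if (!version %in% versions) {
        stop(sprintf("unknown version '%s' for method '%s'; available: %s",
                     version, method, paste(versions, collapse = ", ")))
      }
      return(structure(
        list(method = method, version = version, family = fam,
             params = reg[[fam]][[method]][[version]]),
        class = "wg_params"
      ))
    }
  }
  all <- list_methods()
  stop(sprintf("unknown method '%s'; available: %s",
               method, paste(unique(all$method), collapse = ", ")))
}

#' @export
print.wg_params <- function(x, ...) {
  cat(sprintf("<wg_params> %s / %s (%s)\n", x$method, x$version, x$family))
  for (nm in names(x$params)) {
    p <- x$params[[nm]]
    cat(sprintf("  %s = %s [%s]\n", nm, format(p$value), p$unit))
  }
  invisible(x)
}

#' Fetch a parameter value, optionally converting its unit
#'
#' Acceleration parameters tagged `g`/`m_s2` (and squared-acceleration tags
#' `g2`/`m_s2_2`) convert via standard gravity; other tags must match.
#'
#' @param p a `wg_params` object.
#' @param name parameter name.
#' @param as_unit optional target unit.
#' @return the parameter value.
#' @export
param_value <- function(p, name, as_unit = NULL) {
  if (!name %in% names(p$params)) {
    stop(sprintf("parameter '%s' not in registry entry %s/%s", name, p$method, p$version))
  }
  entry <- p$params[[name]]
  v <- entry$value
  if (is.null(as_unit) || identical(entry$unit, as_unit)) return(v)
  key <- paste(entry$unit, as_unit, sep = "->")
  f <- switch(key,
    "g->m_s2" = WG_GRAVITY,
    "m_s2->g" = 1 / WG_GRAVITY,
    "g2->m_s2_2" = WG_GRAVITY^2,
    "m_s2_2->g2" = 1 / WG_GRAVITY^2,
    stop(sprintf("cannot convert parameter '%s' from '%s' to '%s'",
                 name, entry$unit, as_unit))
  )
  v * f
}

# Merge user overrides (named list of plain values) into a wg_params object;
# overrides must name parameters already present in the registry entry.
override_params <- function(p, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(p)
  unknown <- setdiff(names(overrides), names(p$params))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown parameter override(s) for %s/%s: %s",
                 p$method, p$version, paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) p$params[[nm]]$value <- overrides[[nm]]
  p
}
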