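#' Load a packaged or user parameter set
#'
#' Parameter sets bundle all constants of one model tier (thrombin
#' \code{generation} or spatial \code{flow}/wave modelling) together with
#' units and a source annotation for every value, so that typo-resolved and
#' calibrated constants remain distinguishable from values used as printed.
#'
#' Two sets ship with the package: \code{"table1"} (the zero-dimensional
#' thrombin-generation model) and \code{"table2"} (the spatial clot-growth
#' and reduced thrombin-wave models). A path to a JSON file with the same
#' schema is also accepted.
#'
#' @param name Name of a packaged set (\code{"table1"}, \code{"table2"}) or a
#'   path to a JSON parameter file.
#' @return An object of class \code{parameter_set}: a list with elements
#'   \code{name}, \code{version}, \code{tier}, \code{values} (named numeric),
#'   \code{units} and \code{source} (named character).
#' @examples
#' ps <- load_parameters("table1")
#' ps$values$II0
#' @export
load_parameters <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "params", paste0(name, ".json"),
                package = "thrombosim", mustWork = FALSE)
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown parameter set or missing file: ", name)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("name", "tier", "parameters")) {
    if (is.null(raw[[field]])) stop("parameter file lacks field '", field, "'")
  }
  vals <- lapply(raw$parameters, function(p) p$value)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && is.finite(v), logical(1))]
  if (length(bad)) stop("non-numeric parameter value(s): ", paste(bad, collapse = ", "))
  schema <- .tier_schema(raw$tier)
  missing_keys <- setdiff(schema, names(vals))
  extra_keys <- setdiff(names(vals), schema)
  if (length(missing_keys)) {
    stop("parameter set '", raw$name, "' is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  if (length(extra_keys)) {
    stop("parameter set '", raw$name, "' has unknown key(s): ",
         paste(extra_keys, collapse = ", "))
  }
  structure(list(
    name = raw$name,
    version = if (is.null(raw$version)) "unversioned" else raw$version,
    tier = raw$tier,
    values = lapply(vals, as.numeric),
    units = vapply(raw$parameters, function(p) as.character(p$unit), character(1)),
    source = vapply(raw$parameters, function(p) as.character(p$source), character(1))
  ), class = "parameter_set")
}

#' Save a parameter set to JSON
#'
#' Round-trips through [load_parameters()]: saving and re-loading yields an
#' identical set.
#'
#' @param ps A \code{parameter_set}.
#' @param path Output file path (JSON).
#' @return \code{path}, invisibly.
#' @export
save_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  params <- lapply(names(ps$values), function(k) {
    list(value = ps$values[[k]], unit = ps$units[[k]], source = ps$source[[k]])
  })
  names(params) <- names(ps$values)
  out <- list(name = ps$name, version = ps$version, tier = ps$tier,
              parameters = params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# required keys per tier; unknown tiers accept any keys they declare
.tier_schema <- function(tier) {
  switch(tier,
    generation = c("a1", "a2", "a3", "a4", "b1", "b2", "k3", "k4", "k5",
                   "TF", "VIIa", "X0", "II0", "ATIII0", "phi0"),
    flow = c("h", "dt", "D", "Dp", "k1", "k2", "k3", "k4", "k5", "k6", "k7",
             "k8", "k9", "k10", "K10", "k11", "k12", "k13", "alpha1", "beta1",
             "phi_max", "P0", "A0", "B0", "VII", "Fg0", "phi_f0", "phi_c0",
             "rho", "nu", "alpha", "a", "Tstar", "Ba_decay"),
    stop("unknown parameter tier: ", tier)
  )
}

#' @exportS3Method base::print
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", x$name, " (tier: ", x$tier, ", version ",
      x$version, ")\n", sep = "")
  df <- data.frame(value = unlist(x$values), unit = x$units,
                   row.names = names(x$values))
  print(df)
  invisible(x)
}

# internal: merge user overrides into a defaults list, rejecting unknown names
.merge_params <- function(defaults, overrides) {
  if (!length(overrides)) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(overrides)] <- overrides
  defaults
}
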