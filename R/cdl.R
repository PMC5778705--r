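#' Linear cochlear-duct-length equation
#'
#' CDL is estimated from the A-value by published linear relations
#' `CDL = slope * A + intercept`, fitted either at the lateral wall or at
#' the Organ of Corti. The package deliberately ships no built-in
#' coefficients: published values (e.g. the Alexiades or Koch relations)
#' must be transcribed from their sources into a configuration file or
#' registered with [register_cdl_equation()], so that the provenance of
#' every coefficient is explicit.
#'
#' @param name short identifier (used as preset key).
#' @param slope dimensionless, > 0 (CDL increases with A).
#' @param intercept mm.
#' @param site `"lateral_wall"` or `"organ_of_corti"`.
#' @param source citation text for the coefficients.
#' @return an object of class `cdl_equation`.
#' @examples
#' eq <- cdl_equation("demo", slope = 4, intercept = -5,
#'                    site = "lateral_wall", source = "synthetic example")
#' estimate_cdl(9, eq)
#' @export
cdl_equation <- function(name, slope, intercept,
                         site = c("lateral_wall", "organ_of_corti"),
                         source = "") {
  site <- match.arg(site)
  if (!is.numeric(slope) || slope <= 0)
    stop("`slope` must be > 0: CDL must increase with the A-value")
  structure(list(name = as.character(name), slope = as.numeric(slope),
                 intercept = as.numeric(intercept), site = site,
                 source = as.character(source)),
            class = "cdl_equation")
}

#' @export
print.cdl_equation <- function(x, ...) {
  cat(sprintf("<cdl_equation> %s [%s]: CDL = %.4g * A + %.4g mm (%s)\n",
              x$name, x$site, x$slope, x$intercept,
              if (nzchar(x$source)) x$source else "no source recorded"))
  invisible(x)
}

.cdl_registry <- new.env(parent = emptyenv())

#' Register, list and fetch CDL equation presets
#'
#' The preset registry starts empty; populate it from a YAML file with
#' [load_cdl_equations()] or programmatically. See
#' `system.file("extdata", "cdl_equations_example.yaml", package =
#' "cochmetric")` for the file schema (the example's coefficients are
#' synthetic placeholders, not published values).
#'
#' @param equation a [cdl_equation()].
#' @return `register_cdl_equation()` the equation invisibly;
#'   `list_cdl_equations()` a character vector of preset names;
#'   `get_cdl_equation()` the [cdl_equation()].
#' @export
register_cdl_equation <- function(equation) {
  stopifnot(inherits(equation, "cdl_equation"))
  assign(equation$name, equation, envir = .cdl_registry)
  invisible(equation)
}

#' @rdname register_cdl_equation
#' @export
list_cdl_equations <- function() sort(ls(.cdl_registry))

#' @rdname register_cdl_equation
#' @param name preset name.
#' @export
get_cdl_equation <- function(name) {
  if (!exists(name, envir = .cdl_registry, inherits = FALSE))
    stop("unknown CDL preset '", name, "'; available: ",
         if (length(list_cdl_equations())) paste(list_cdl_equations(), collapse = ", ")
         else "(none registered; see load_cdl_equations())")
  get(name, envir = .cdl_registry, inherits = FALSE)
}

#' Load CDL equations from a YAML file
#'
#' The file holds a list of mappings with keys `name`, `slope`, `intercept`,
#' `site`, `source`. Each equation is registered as a preset and returned.
#'
#' @param path YAML file path.
#' @param register also add them to the preset registry (default TRUE).
#' @return list of [cdl_equation()]s, invisibly.
#' @export
load_cdl_equations <- function(path, register = TRUE) {
  raw <- yaml::read_yaml(path)
  eqs <- lapply(raw, function(x)
    cdl_equation(x$name, x$slope, x$intercept, x$site, x$source %||% ""))
  if (register) lapply(eqs, register_cdl_equation)
  invisible(eqs)
}

#' Estimate cochlear duct length from an A-value
#'
#' @param a_value A-value in mm, > 0.
#' @param equation a [cdl_equation()] or the name of a registered preset.
#' @return CDL in mm.
#' @export
estimate_cdl <- function(a_value, equation) {
  if (is.character(equation)) equation <- get_cdl_equation(equation)
  stopifnot(inherits(equation, "cdl_equation"))
  if (!is.numeric(a_value) || any(a_value <= 0))
    stop("`a_value` must be > 0 mm")
  equation$slope * a_value + equation$intercept
}
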