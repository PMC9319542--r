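#' Pasquill stability classes
#'
#' The six Pasquill stability classes, ordered from extremely unstable (`"a"`)
#' through unstable (`"b"`), slightly unstable (`"c"`), neutral (`"d"`) and
#' slightly stable (`"e"`) to stable (`"f"`).
#'
#' @return Character vector `c("a","b","c","d","e","f")`.
#' @export
stability_classes <- function() c("a", "b", "c", "d", "e", "f")

.check_class <- function(class) {
  class <- tolower(as.character(class))
  bad <- !class %in% stability_classes()
  if (any(bad)) {
    stop("unknown stability class: ", paste(unique(class[bad]), collapse = ", "),
         " (must be one of a-f)", call. = FALSE)
  }
  class
}

# Coefficient tables are shipped as annotated CSV under inst/extdata and cached
# per session.
.scheme_cache <- new.env(parent = emptyenv())

.read_coefficients <- function(name) {
  if (!is.null(.scheme_cache[[name]])) return(.scheme_cache[[name]])
  path <- system.file("extdata", paste0(name, "_coefficients.csv"),
                      package = "nanoplume", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- stats::reshape(raw[, c("class", "coefficient", "value")],
                        idvar = "class", timevar = "coefficient",
                        direction = "wide")
  names(tab) <- sub("^value\\.", "", names(tab))
  tab <- tab[match(stability_classes(), tab$class), ]
  rownames(tab) <- tab$class
  .scheme_cache[[name]] <- tab
  tab
}

#' Dispersion parameter scheme
#'
#' Bundles a sigma-curve parametrization for the six Pasquill stability
#' classes. Two parametrizations are shipped: `"klug"`, power laws
#' \eqn{\sigma = R x^{r}} with x in metres, and `"davidson"`, modified
#' Pasquill-Gifford fits \eqn{\sigma = a x^{b + c \ln x}} with x in kilometres.
#' All public interfaces take x in metres; unit conversion is internal.
#' Vertical dispersion is capped at `sigma_z_cap` (5000 m by default, the
#' usual fully-mixed limit applied in regulatory plume models).
#'
#' @param name `"klug"` or `"davidson"`.
#' @param sigma_z_cap maximum vertical dispersion length in m (> 0).
#' @return An object of class `"dispersion_scheme"`.
#' @examples
#' sch <- dispersion_scheme("davidson")
#' sigma_y(1000, "d", sch)  # == the class-d a_y coefficient
#' @export
dispersion_scheme <- function(name = c("klug", "davidson"), sigma_z_cap = 5000) {
  name <- match.arg(name)
  stopifnot(is.numeric(sigma_z_cap), length(sigma_z_cap) == 1L, sigma_z_cap > 0)
  out <- list(name = name, coefficients = .read_coefficients(name),
              sigma_z_cap = sigma_z_cap)
  class(out) <- "dispersion_scheme"
  out
}

.as_scheme <- function(scheme) {
  if (inherits(scheme, "dispersion_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1L) return(dispersion_scheme(scheme))
  stop("'scheme' must be a dispersion_scheme or a scheme name", call. = FALSE)
}

#' @export
print.dispersion_scheme <- function(x, ...) {
  cat("Dispersion scheme:", x$name,
      sprintf("(sigma_z cap %g m)\n", x$sigma_z_cap))
  print(x$coefficients[, -1L], ...)
  invisible(x)
}

# The Davidson exponent b + c*ln(x_km) makes sigma = a exp(b ln x + c ln^2 x)
# turn over at ln(x_km) = -b/(2c): for c < 0 the raw fit would shrink with
# distance beyond the turning point, for c > 0 it would grow towards the
# source below it (both outside the fitted Pasquill-Gifford range). The curve
# is plateaued at the turning point so sigma stays nondecreasing in x.
.davidson_sigma <- function(x_m, a, b, cc) {
  xk <- x_m / 1000
  if (cc < 0) {
    xk <- pmin(xk, exp(-b / (2 * cc)))
  } else if (cc > 0) {
    xk <- pmax(xk, exp(-b / (2 * cc)))
  }
  lx <- log(xk)
  a * exp((b + cc * lx) * lx)
}

.sigma <- function(x, class, scheme, which = c("y", "z")) {
  which <- match.arg(which)
  scheme <- .as_scheme(scheme)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("downwind distance x must be finite and > 0 (m)", call. = FALSE)
  }
  class <- .check_class(class)
  if (length(class) == 1L) class <- rep(class, length.out = length(x))
  co <- scheme$coefficients
  out <- numeric(length(x))
  for (cl in unique(class)) {
    i <- class == cl
    row <- co[cl, ]
    out[i] <- if (scheme$name == "klug") {
      if (which == "y") row$Ry * x[i]^row$ry else row$Rz * x[i]^row$rz
    } else {
      if (which == "y") .davidson_sigma(x[i], row$ay, row$by, row$cy)
      else .davidson_sigma(x[i], row$az, row$bz, row$cz)
    }
  }
  if (which == "z") out <- pmin(out, scheme$sigma_z_cap)
  out
}

#' Crosswind and vertical dispersion parameters
#'
#' Evaluate the plume spread \eqn{\sigma_y(x)} and \eqn{\sigma_z(x)} for a
#' Pasquill stability class under a dispersion scheme. `sigma_z` is capped at
#' the scheme's `sigma_z_cap`.
#'
#' @param x downwind distance in m (vectorised, must be > 0).
#' @param class stability class, one of `"a"`-`"f"` (scalar or vector).
#' @param scheme a [dispersion_scheme()] or a scheme name.
#' @return Numeric vector of dispersion lengths in m.
#' @export
sigma_y <- function(x, class, scheme = dispersion_scheme("klug")) {
  .sigma(x, class, scheme, "y")
}

#' @rdname sigma_y
#' @export
sigma_z <- function(x, class, scheme = dispersion_scheme("klug")) {
  .sigma(x, class, scheme, "z")
}

#' Atmospheric state
#'
#' Wind, temperature and boundary-layer description driving the plume solver.
#'
#' @param U wind speed in m/s (> 0).
#' @param T_K air temperature in K (> 0).
#' @param Hpbl planetary boundary layer height in m (> 0); acts as a
#'   reflecting lid via image sources.
#' @param stability Pasquill class `"a"`-`"f"`.
#' @param scheme a [dispersion_scheme()] or scheme name.
#' @return An object of class `"atmosphere"`.
#' @examples
#' atmosphere(U = 2.5, T_K = 288.15, Hpbl = 1000, stability = "d",
#'            scheme = "davidson")
#' @export
atmosphere <- function(U, T_K = 288.15, Hpbl = 1000, stability = "d",
                       scheme = dispersion_scheme("klug")) {
  stopifnot(is.numeric(U), length(U) == 1L, U > 0,
            is.numeric(T_K), length(T_K) == 1L, T_K > 0,
            is.numeric(Hpbl), length(Hpbl) == 1L, Hpbl > 0)
  out <- list(U = U, T_K = T_K, Hpbl = Hpbl,
              stability = .check_class(stability)[1L],
              scheme = .as_scheme(scheme))
  class(out) <- "atmosphere"
  out
}

#' @export
print.atmosphere <- function(x, ...) {
  cat(sprintf(
    "Atmosphere: U = %g m/s, T = %g K, Hpbl = %g m, class %s (%s)\n",
    x$U, x$T_K, x$Hpbl, x$stability, x$scheme$name))
  invisible(x)
}
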