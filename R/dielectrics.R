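# Dielectric properties, complex permittivity and contrast -- the physical
# quantities the antenna ring senses. Time convention e^{+j omega t}: losses
# appear as a negative imaginary part, and the outgoing wavenumber has
# Im(k) <= 0. Every module in the package shares this convention.

#' Physical constants (vacuum permittivity, speed of light)
#' @noRd
.mw_eps0 <- 8.8541878128e-12 # F/m
.mw_c0 <- 299792458 # m/s

#' Dielectric properties of a tissue class
#'
#' Relative permittivity and conductivity jointly determine how strongly a
#' tissue interacts with the probing microwave field; the difference between a
#' lesion and the surrounding mucosa is what the imaging chain reconstructs.
#'
#' @param eps_r relative permittivity (dimensionless, \eqn{\ge 1}).
#' @param sigma conductivity in S/m (\eqn{\ge 0}).
#' @return an object of class \code{mw_props}.
#' @examples
#' dielectric_props(50, 6) # mucosa-like, high water content
#' @export
dielectric_props <- function(eps_r, sigma) {
  stopifnot(is.numeric(eps_r), length(eps_r) == 1L, is.finite(eps_r))
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (eps_r < 1) stop("eps_r must be >= 1 (vacuum bound)")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(eps_r = as.numeric(eps_r), sigma = as.numeric(sigma)),
            class = "mw_props")
}

#' @export
print.mw_props <- function(x, ...) {
  cat(sprintf("<mw_props> eps_r = %g, sigma = %g S/m\n", x$eps_r, x$sigma))
  invisible(x)
}

#' Complex relative permittivity at a working frequency
#'
#' \eqn{\varepsilon^*(\omega) = \varepsilon_r - j \sigma / (\omega
#' \varepsilon_0)}. The negative imaginary part encodes conductive loss under
#' the package's \eqn{e^{+j\omega t}} convention.
#'
#' @param props a \code{\link{dielectric_props}} object.
#' @param frequency working frequency in Hz (> 0); the device operates at
#'   7.5 GHz.
#' @return an object of class \code{mw_permittivity} with fields \code{value}
#'   (complex) and \code{frequency} (Hz).
#' @examples
#' complex_permittivity(dielectric_props(50, 6), 7.5e9)
#' @export
complex_permittivity <- function(props, frequency) {
  stopifnot(inherits(props, "mw_props"))
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0) {
    stop("frequency must be a positive finite number (Hz)")
  }
  value <- complex(real = props$eps_r,
                   imaginary = -props$sigma / (2 * pi * frequency * .mw_eps0))
  structure(list(value = value, frequency = as.numeric(frequency)),
            class = "mw_permittivity")
}

#' @export
print.mw_permittivity <- function(x, ...) {
  cat(sprintf("<mw_permittivity> %g %+gj at %g GHz\n",
              Re(x$value), Im(x$value), x$frequency / 1e9))
  invisible(x)
}

#' Dielectric contrast of an inclusion against the background
#'
#' \eqn{\chi = (\varepsilon^*_{inc} - \varepsilon^*_{bg}) /
#' \varepsilon^*_{bg}}: the relative complex-permittivity difference that
#' drives the scattered field. Zero iff inclusion and background are
#' identical; invariant under a common rescaling of both permittivities.
#'
#' @param inclusion,background \code{mw_permittivity} objects at the same
#'   frequency.
#' @return a complex scalar.
#' @examples
#' bg <- complex_permittivity(dielectric_props(50, 0), 7.5e9)
#' inc <- complex_permittivity(dielectric_props(60, 0), 7.5e9)
#' dielectric_contrast(inc, bg) # 0.2
#' @export
dielectric_contrast <- function(inclusion, background) {
  stopifnot(inherits(inclusion, "mw_permittivity"),
            inherits(background, "mw_permittivity"))
  if (inclusion$frequency != background$frequency) {
    stop("frequency mismatch between inclusion and background permittivity")
  }
  (inclusion$value - background$value) / background$value
}

#' Background wavenumber
#'
#' \eqn{k = (2\pi f / c) \sqrt{\varepsilon^*}} on the branch with
#' \eqn{\mathrm{Im}(k) \le 0}, so that the outgoing cylindrical wave decays in
#' a lossy medium.
#'
#' @param background an \code{mw_permittivity} object; its stored frequency is
#'   used.
#' @return complex wavenumber in rad/m.
#' @examples
#' k <- wavenumber(complex_permittivity(dielectric_props(50, 6), 7.5e9))
#' 2 * pi / Re(k) * 1e3 # wavelength in mm, ~5.6 mm in mucosa
#' @export
wavenumber <- function(background) {
  stopifnot(inherits(background, "mw_permittivity"))
  eps <- background$value
  if (Re(eps) < 1) stop("background permittivity must have real part >= 1")
  k <- (2 * pi * background$frequency / .mw_c0) * sqrt(eps)
  # principal sqrt of Im<=0 input already has Im<=0; guard the boundary case
  if (Im(k) > 0) k <- -k
  k
}

#' Default tissue dielectric table
#'
#' Plausible high-water-content values giving a clear lesion/mucosa contrast
#' at 7.5 GHz. These are configurable placeholders, not measured porcine or
#' human values; override them via the pipeline configuration
#' (\code{tissues.<name>.eps_r}, \code{tissues.<name>.sigma}).
#'
#' @return a named list of \code{\link{dielectric_props}}.
#' @export
default_tissues <- function() {
  list(
    mucosa = dielectric_props(50, 6),
    adenoma = dielectric_props(60, 8),
    stool = dielectric_props(40, 4)
  )
}

# Resolve a tissue class name in a tissue table, with a clear error
resolve_tissue <- function(tissues, name) {
  if (!name %in% names(tissues)) {
    stop(sprintf("tissue class '%s' is not defined (known: %s)",
                 name, paste(names(tissues), collapse = ", ")))
  }
  tissues[[name]]
}
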