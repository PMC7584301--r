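#' Build a consistent set of isotropic elastic constants
#'
#' Given exactly two independent isotropic elastic constants, returns the full
#' consistent set (Young's modulus `E`, Poisson ratio `nu`, shear modulus `G`,
#' bulk modulus `K`, Lame first parameter `lambda`) using the standard
#' isotropic relations \eqn{G = E/(2(1+\nu))}, \eqn{K = E/(3(1-2\nu))},
#' \eqn{\lambda = K - 2G/3}.
#'
#' All moduli are in kPa; `nu` is dimensionless. The physically admissible
#' range \eqn{-1 < \nu < 0.5}, \eqn{G > 0}, \eqn{K > 0} is enforced.
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson ratio.
#' @param G Shear modulus, kPa.
#' @param K Bulk modulus, kPa.
#' @param lambda Lame first parameter, kPa.
#' @return An object of class `elastic_constants`: a named list with fields
#'   `E`, `nu`, `G`, `K`, `lambda`.
#' @examples
#' # the packaged soft-tissue constants
#' elastic_constants(G = 19.254, K = 1919.022)
#' # a polyurethane foam mattress
#' elastic_constants(E = 50, nu = 0.3)
#' @export
elastic_constants <- function(E = NULL, nu = NULL, G = NULL, K = NULL,
                              lambda = NULL) {
  given <- list(E = E, nu = nu, G = G, K = K, lambda = lambda)
  given <- given[!vapply(given, is.null, logical(1))]
  if (length(given) != 2L) {
    stop("supply exactly two independent elastic constants, got ",
         length(given), call. = FALSE)
  }
  for (nm in names(given)) {
    v <- given[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("elastic constant '", nm, "' must be a finite scalar", call. = FALSE)
    }
  }
  key <- paste(sort(names(given)), collapse = "+")
  g <- function(nm) given[[nm]]

  # reduce every supported pair to (G, nu)
  Gnu <- switch(key,
    "E+nu" = c(G = g("E") / (2 * (1 + g("nu"))), nu = g("nu")),
    "G+nu" = c(G = g("G"), nu = g("nu")),
    "G+K" = c(G = g("G"),
              nu = (3 * g("K") - 2 * g("G")) / (6 * g("K") + 2 * g("G"))),
    "K+nu" = c(G = 3 * g("K") * (1 - 2 * g("nu")) / (2 * (1 + g("nu"))),
               nu = g("nu")),
    "E+G" = c(G = g("G"), nu = g("E") / (2 * g("G")) - 1),
    "E+K" = c(G = 3 * g("K") * g("E") / (9 * g("K") - g("E")),
              nu = (3 * g("K") - g("E")) / (6 * g("K"))),
    "G+lambda" = c(G = g("G"),
                   nu = g("lambda") / (2 * (g("lambda") + g("G")))),
    "K+lambda" = c(G = 3 * (g("K") - g("lambda")) / 2,
                   nu = g("lambda") / (3 * g("K") - g("lambda"))),
    stop("unsupported constant pair: ", key, call. = FALSE)
  )
  Gv <- unname(Gnu["G"])
  nuv <- unname(Gnu["nu"])
  if (!is.finite(Gv) || !is.finite(nuv) || Gv <= 0 ||
      nuv <= -1 || nuv >= 0.5) {
    stop("invalid elastic constants: require G > 0 and -1 < nu < 0.5 ",
         "(implied G = ", signif(Gv, 6), ", nu = ", signif(nuv, 6), ")",
         call. = FALSE)
  }
  Ev <- 2 * Gv * (1 + nuv)
  Kv <- Ev / (3 * (1 - 2 * nuv))
  lamv <- Kv - 2 * Gv / 3
  if (Kv <= 0) {
    stop("invalid elastic constants: implied bulk modulus K <= 0",
         call. = FALSE)
  }
  structure(list(E = Ev, nu = nuv, G = Gv, K = Kv, lambda = lamv),
            class = "elastic_constants")
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat("<elastic_constants>\n")
  cat(sprintf("  E = %.6g kPa   nu = %.6g\n", x$E, x$nu))
  cat(sprintf("  G = %.6g kPa   K = %.6g kPa   lambda = %.6g kPa\n",
              x$G, x$K, x$lambda))
  invisible(x)
}

#' @export
format.elastic_constants <- function(x, ...) {
  sprintf("E=%.4g kPa, nu=%.4g", x$E, x$nu)
}
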