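#' Sub-functions: parametric coefficient-vs-concentration laws
#'
#' A sub-function maps cell concentration C (cells/mL) to one Gaussian
#' coefficient (amplitude in absorption percent, or center/width in nm).
#' Four families are supported:
#' \describe{
#'   \item{constant}{\eqn{f(C) = k}; params `(k)`.}
#'   \item{beer_lambert_amplitude}{\eqn{f(C) = 100\,(1 - 10^{-p_1 C})};
#'     params `(p1)`, `p1 > 0`. The saturating amplitude law derived from the
#'     Beer-Lambert relation.}
#'   \item{power}{\eqn{f(C) = p_1 C^{p_2}}; params `(p1, p2)`, `p1 > 0`. An
#'     empirical width law.}
#'   \item{log_linear}{\eqn{f(C) = p_1 + p_2 \log_{10} C}; params `(p1, p2)`,
#'     requires `C > 0` at evaluation.}
#' }
#'
#' @param family one of the family names above.
#' @param params numeric parameter vector of the family's arity.
#' @return object of class `subfunction`.
#' @export
subfunction <- function(family = c("constant", "beer_lambert_amplitude",
                                   "power", "log_linear"),
                        params) {
  family <- match.arg(family)
  params <- as.numeric(params)
  arity <- c(constant = 1, beer_lambert_amplitude = 1, power = 2,
             log_linear = 2)[[family]]
  if (length(params) != arity)
    stopf("family %s takes %d parameter(s), got %d", family, arity,
          length(params))
  if (any(!is.finite(params))) stopf("non-finite sub-function parameters")
  if (family == "beer_lambert_amplitude" && params[1] <= 0)
    stopf("beer_lambert_amplitude requires p1 > 0")
  if (family == "power" && params[1] <= 0)
    stopf("power requires p1 > 0")
  structure(list(family = family, params = params), class = "subfunction")
}

#' Evaluate a sub-function at concentrations C
#'
#' Exact arithmetic per family formula; no clamping is applied here.
#'
#' @param f a [subfunction()].
#' @param C concentration(s), cells/mL; `C > 0` required for `log_linear`.
#' @return numeric vector, one value per element of `C`.
#' @export
eval_subfunction <- function(f, C) {
  C <- as.numeric(C)
  switch(f$family,
    constant = rep(f$params[1], length(C)),
    beer_lambert_amplitude = {
      if (any(C < 0)) stopf("negative concentration")
      100 * (1 - 10^(-f$params[1] * C))
    },
    power = {
      if (any(C < 0)) stopf("negative concentration")
      f$params[1] * C^f$params[2]
    },
    log_linear = {
      if (any(C <= 0)) stopf("log_linear sub-function requires C > 0")
      f$params[1] + f$params[2] * log10(C)
    })
}

#' @export
print.subfunction <- function(x, ...) {
  cat(sprintf("<subfunction> %s(%s)\n", x$family,
              paste(format(x$params, digits = 6), collapse = ", ")))
  invisible(x)
}

subfunction_to_list <- function(f) list(family = f$family, params = f$params)
subfunction_from_list <- function(l)
  subfunction(l$family, as.numeric(unlist(l$params)))
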