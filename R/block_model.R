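#' Fractional channel block from a Hill fit
#'
#' Evaluates the Hill concentration-response curve
#' \deqn{\%block = 100 \cdot \frac{C^{h}}{C^{h} + IC_{50}^{h}}}
#' at an unbound concentration `concentration` (uM). When the fit has no
#' Hill coefficient, `h = 1` is used and the flag `hill_defaulted` is
#' set; when the IC50 is a censored bound, the result is an upper bound
#' on the true block and the flag `ic50_censored_bound` is set. The
#' value is computed as `100 / (1 + (ic50/C)^h)` for numerical range and
#' clamped to `[0, 100]` to absorb rounding.
#'
#' @param concentration unbound concentration, uM; strictly positive.
#'   May be a vector.
#' @param fit a [hill_fit()].
#' @return an object of class `block_result`: a list with
#'   `percent_block` (numeric, same length as `concentration`),
#'   `concentration`, `flags` (character subset of
#'   `c("hill_defaulted", "ic50_censored_bound", "dynamic")`) and
#'   `variant` (`"static"` here).
#' @examples
#' percent_block(2, hill_fit(2, 1))$percent_block        # 50
#' percent_block(0.57, hill_fit(0.057, 0.99))$percent_block
#' @export
percent_block <- function(concentration, fit) {
  stopifnot(inherits(fit, "hill_fit"))
  check_concentration(concentration)
  h <- fit$hill
  flags <- character(0)
  if (is.na(h)) {
    h <- 1
    flags <- c(flags, "hill_defaulted")
  }
  if (fit$ic50_censored) flags <- c(flags, "ic50_censored_bound")
  pb <- 100 / (1 + (fit$ic50 / concentration)^h)
  block_result(pmin(pmax(pb, 0), 100), concentration, flags, "static")
}

#' Fractional dynamic-hERG block
#'
#' Evaluates an Emax-scaled Hill curve
#' \deqn{\%block = 100 \cdot E_{max} \cdot \frac{C^{h}}{C^{h} +
#' IC_{50,dyn}^{h}}}
#' where `Emax` is the maximal fractional inhibition: block saturates at
#' `100 * max_inhibition` rather than 100. Used to replace the static
#' hERG term in the dynamic net-block variant.
#'
#' @param concentration unbound concentration, uM; strictly positive.
#' @param fit a [dynamic_herg_fit()].
#' @return a `block_result` with the `dynamic` flag set.
#' @export
dynamic_percent_block <- function(concentration, fit) {
  stopifnot(inherits(fit, "dynamic_herg_fit"))
  check_concentration(concentration)
  h <- fit$dyn_hill
  flags <- "dynamic"
  if (is.na(h)) {
    h <- 1
    flags <- c(flags, "hill_defaulted")
  }
  pb <- 100 * fit$max_inhibition / (1 + (fit$dyn_ic50 / concentration)^h)
  block_result(pmin(pmax(pb, 0), 100), concentration, flags, "dynamic")
}

check_concentration <- function(concentration) {
  if (!is.numeric(concentration) || length(concentration) < 1L ||
      any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentration must be positive and finite (uM)", call. = FALSE)
}

block_result <- function(percent_block, concentration, flags, variant) {
  structure(list(percent_block = percent_block,
                 concentration = concentration,
                 flags = flags, variant = variant),
            class = "block_result")
}

#' @export
print.block_result <- function(x, ...) {
  cat(sprintf("<block_result> %s: %s%%block at %s uM%s\n", x$variant,
              paste(signif(x$percent_block, 4), collapse = ", "),
              paste(signif(x$concentration, 4), collapse = ", "),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}
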