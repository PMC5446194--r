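#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an Input-predictability fit
#'
#' @param x An `input_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term.
#' @method tidy input_fit
#' @export
tidy.input_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "input"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of an Input-predictability fit
#'
#' @param x An `input_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `neutral.r.squared`, `n.windows`,
#'   `frac.depleted`, `frac.enriched`.
#' @method glance input_fit
#' @export
glance.input_fit <- function(x, ...) {
  tab <- table(x$data$label)
  n <- nrow(x$data)
  tibble::tibble(
    r.squared = x$r_squared,
    neutral.r.squared = x$neutral_r_squared,
    n.windows = n,
    frac.depleted = unname(tab[["depleted"]]) / n,
    frac.enriched = unname(tab[["enriched"]]) / n)
}

#' Tidy a differential-expression result
#'
#' @param x An `nb_de` tibble.
#' @param ... Unused.
#' @return The per-gene results as a plain tibble.
#' @method tidy nb_de
#' @export
tidy.nb_de <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' One-row summary of a differential-expression result
#'
#' @param x An `nb_de` tibble.
#' @param alpha Adjusted-p cutoff used in the significance counts.
#' @param ... Unused.
#' @return One-row tibble with test/reference conditions, tested and
#'   significant gene counts.
#' @method glance nb_de
#' @export
glance.nb_de <- function(x, alpha = 0.05, ...) {
  ct <- attr(x, "contrast") %||% c(NA, NA)
  sig <- !is.na(x$padj) & x$padj < alpha
  tibble::tibble(
    test = ct[1], reference = ct[2],
    n.genes = nrow(x),
    n.tested = sum(!is.na(x$padj)),
    n.signif = sum(sig),
    n.up = sum(sig & x$log2fc > 0),
    n.down = sum(sig & x$log2fc < 0))
}
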