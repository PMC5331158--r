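#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-group scores of a collective fit
#'
#' One row per group and shared component, with the score
#' \eqn{\alpha_{ik}} -- the low-dimensional representation of each density
#' used for visualization and clustering.
#'
#' @param x a [fit_collective()] object.
#' @param ... unused.
#' @return tibble with columns `group`, `component`, `score`.
#' @export
tidy.collective_fit <- function(x, ...) {
  tibble::tibble(
    group = rep(x$groups, times = x$K),
    component = rep(seq_len(x$K), each = length(x$groups)),
    score = as.vector(x$A)
  )
}

#' One-row summary of a collective fit
#'
#' @param x a [fit_collective()] object.
#' @param ... unused.
#' @return tibble with `logLik`, `df`, `AIC`, `lambda`, `penalty`,
#'   `iterations`, `converged`, `K`, `L`, `m`, `n`.
#' @export
glance.collective_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, df = x$df, AIC = x$aic, lambda = x$lambda,
    penalty = penalty_trace(x$Theta, x$basis$D),
    iterations = x$iterations, converged = x$converged,
    K = x$K, L = x$L, m = length(x$groups), n = sum(x$n_i)
  )
}

#' Diagnostic plots for a collective fit
#'
#' `type = "scree"` shows the component energies
#' \eqn{g(k) = \sum_i \alpha_{ik}^2} as percentage shares (to choose K);
#' `type = "trace"` shows the penalized criterion and smoothing parameter
#' across iterations; `type = "scores"` scatters the first two components'
#' scores per group.
#'
#' @param object a [fit_collective()] object.
#' @param type one of `"scree"`, `"trace"`, `"scores"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.collective_fit <- function(object, type = c("scree", "trace", "scores"),
                                    ...) {
  type <- match.arg(type)
  if (type == "scree") {
    en <- component_energy(object)
    ggplot2::ggplot(en, ggplot2::aes(.data$component, .data$share)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "component k", y = "energy share g(k) [%]")
  } else if (type == "trace") {
    tr <- tidyr::pivot_longer(
      object$trace[, c("iter", "criterion_end", "lambda")],
      cols = c("criterion_end", "lambda"))
    ggplot2::ggplot(tr, ggplot2::aes(.data$iter, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = "iteration", y = NULL)
  } else {
    if (object$K < 2) stop("scores plot needs K >= 2")
    df <- tibble::tibble(group = object$groups,
                         s1 = object$A[, 1], s2 = object$A[, 2])
    ggplot2::ggplot(df, ggplot2::aes(.data$s1, .data$s2, label = .data$group)) +
      ggplot2::geom_text(size = 3) +
      ggplot2::labs(x = "component 1 score", y = "component 2 score")
  }
}
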