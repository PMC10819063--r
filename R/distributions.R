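#' @title Distribution gallery for percentile-matching fits
#' @description Internal registry of the six supported families. Each entry
#'   provides a quantile function, a random sampler, a closed-form or
#'   method-of-quantiles initializer, and a bijection between natural and
#'   unconstrained parameter scales for the optimizer.
#' @noRd
NULL

.qtri <- function(p, min, mode, max) {
  if (max < mode || mode < min) return(rep(NaN, length(p)))
  w <- max - min
  if (w <= 0) return(rep(min, length(p)))
  fc <- (mode - min) / w
  lower <- min + sqrt(pmax(p, 0) * w * (mode - min))
  upper <- max - sqrt(pmax(1 - p, 0) * w * (max - mode))
  ifelse(p <= fc, lower, upper)
}

.rtri <- function(n, min, mode, max) .qtri(stats::runif(n), min, mode, max)

.gallery <- list(
  gamma = list(
    npar = 2L,
    q = function(p, par) stats::qgamma(p, shape = par[1], rate = par[2]),
    r = function(n, par) stats::rgamma(n, shape = par[1], rate = par[2]),
    positive_support = TRUE,
    init = function(p, v) {
      z <- stats::qnorm(p)
      s <- (v[3] - v[1]) / (z[3] - z[1])
      shape <- max((v[2] / s)^2, 1e-3)
      c(shape = shape, rate = shape / max(v[2], 1e-12))
    },
    to_free = function(par) log(par),
    from_free = function(f) {
      stats::setNames(exp(f), c("shape", "rate"))
    }
  ),
  lognormal = list(
    npar = 2L,
    q = function(p, par) stats::qlnorm(p, meanlog = par[1], sdlog = par[2]),
    r = function(n, par) stats::rlnorm(n, meanlog = par[1], sdlog = par[2]),
    positive_support = TRUE,
    init = function(p, v) {
      z <- stats::qnorm(p)
      c(meanlog = log(v[2]),
        sdlog = (log(v[3]) - log(v[1])) / (z[3] - z[1]))
    },
    to_free = function(par) c(par[1], log(par[2])),
    from_free = function(f) {
      stats::setNames(c(f[1], exp(f[2])), c("meanlog", "sdlog"))
    }
  ),
  weibull = list(
    npar = 2L,
    q = function(p, par) stats::qweibull(p, shape = par[1], scale = par[2]),
    r = function(n, par) stats::rweibull(n, shape = par[1], scale = par[2]),
    positive_support = TRUE,
    init = function(p, v) {
      ll <- log(-log(1 - p))
      shape <- (ll[3] - ll[1]) / (log(v[3]) - log(v[1]))
      shape <- max(shape, 1e-3)
      c(shape = shape, scale = v[2] / (-log(0.5))^(1 / shape))
    },
    to_free = function(par) log(par),
    from_free = function(f) {
      stats::setNames(exp(f), c("shape", "scale"))
    }
  ),
  normal = list(
    npar = 2L,
    q = function(p, par) stats::qnorm(p, mean = par[1], sd = par[2]),
    r = function(n, par) stats::rnorm(n, mean = par[1], sd = par[2]),
    positive_support = FALSE,
    init = function(p, v) {
      z <- stats::qnorm(p)
      c(mean = v[2], sd = (v[3] - v[1]) / (z[3] - z[1]))
    },
    to_free = function(par) c(par[1], log(par[2])),
    from_free = function(f) {
      stats::setNames(c(f[1], exp(f[2])), c("mean", "sd"))
    }
  ),
  uniform = list(
    npar = 2L,
    q = function(p, par) stats::qunif(p, min = par[1], max = par[2]),
    r = function(n, par) stats::runif(n, min = par[1], max = par[2]),
    positive_support = FALSE,
    init = function(p, v) {
      width <- (v[3] - v[1]) / (p[3] - p[1])
      c(min = v[1] - p[1] * width, max = v[1] + (1 - p[1]) * width)
    },
    to_free = function(par) c(par[1], log(par[2] - par[1])),
    from_free = function(f) {
      stats::setNames(c(f[1], f[1] + exp(f[2])), c("min", "max"))
    }
  ),
  triangular = list(
    npar = 3L,
    q = function(p, par) .qtri(p, par[1], par[2], par[3]),
    r = function(n, par) .rtri(n, par[1], par[2], par[3]),
    positive_support = FALSE,
    init = function(p, v) {
      c(min = v[1] - (v[2] - v[1]), mode = v[2], max = v[3] + (v[3] - v[2]))
    },
    to_free = function(par) {
      c(par[1], log(max(par[2] - par[1], 1e-9)),
        log(max(par[3] - par[2], 1e-9)))
    },
    from_free = function(f) {
      a <- f[1]
      m <- a + exp(f[2])
      stats::setNames(c(a, m, m + exp(f[3])), c("min", "mode", "max"))
    }
  )
)

#' Supported distribution families
#'
#' Names of the gallery families available to [fit_from_percentiles()], in
#' the fixed order used to break ties between equally good fits. The
#' three-parameter triangular is deliberately last: it can interpolate three
#' anchors of almost any shape, so it only wins when no simpler family fits
#' exactly.
#'
#' @return Character vector of family names.
#' @export
gallery_families <- function() names(.gallery)

new_fitted_distribution <- function(family, params, fit_error, anchors) {
  structure(
    list(family = family, params = params, fit_error = fit_error,
         anchors = anchors),
    class = "fitted_distribution"
  )
}

#' Degenerate (point-mass) distribution
#'
#' A distribution concentrated on a single value, usable wherever a
#' [fit_from_percentiles()] result is accepted (notably [run_monte_carlo()]);
#' turns the stochastic pipeline into the deterministic one.
#'
#' @param value The point of support.
#' @return A `fitted_distribution` of family `"point"`.
#' @export
point_distribution <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  new_fitted_distribution("point", c(value = value), 0,
                          tibble::tibble(rank = 50, value = value))
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat("<fitted_distribution> ", x$family, "(",
      paste(sprintf("%s = %.6g", names(x$params), x$params), collapse = ", "),
      ")\n  fit error (sum sq. rel.): ", format(x$fit_error, digits = 4),
      "\n  anchors: ",
      paste(sprintf("p%g = %.6g", x$anchors$rank, x$anchors$value),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Quantile function of a fitted distribution
#'
#' @param fit A `fitted_distribution`.
#' @param p Probabilities in \[0, 1\].
#' @return Quantiles.
#' @export
dist_quantile <- function(fit, p) {
  if (fit$family == "point") return(rep(unname(fit$params["value"]), length(p)))
  .gallery[[fit$family]]$q(p, fit$params)
}

#' Draw a random sample from a fitted distribution
#'
#' @param fit A `fitted_distribution`.
#' @param n Sample size.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(fit, n) {
  if (fit$family == "point") return(rep(unname(fit$params["value"]), n))
  .gallery[[fit$family]]$r(n, fit$params)
}

.fit_objective <- function(free, fam, p, v, denom) {
  par <- fam$from_free(free)
  q <- fam$q(p, par)
  if (any(!is.finite(q))) return(1e10)
  sum(((q - v) / denom)^2)
}

.fit_family <- function(fam, p, v, denom) {
  free0 <- fam$to_free(fam$init(p, v))
  if (any(!is.finite(free0))) stop("initializer failed")
  obj <- function(f) .fit_objective(f, fam, p, v, denom)
  opt <- stats::optim(free0, obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-14))
  # restart: Nelder-Mead benefits from a fresh simplex around the optimum
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-14))
  best <- if (opt2$value < opt$value) opt2 else opt
  list(params = fam$from_free(best$par), value = best$value)
}

#' Fit a distribution to reported percentiles
#'
#' Reconstructs a full distribution from a small set of reported percentiles
#' (typically three: 5/50/95 for population levels, 10/50/90 for contribution
#' percentages). For every candidate family, parameters are chosen by bounded
#' numerical optimization of the sum of squared *relative* quantile
#' deviations at the anchors,
#' \deqn{\sum_i \left(\frac{Q(p_i;\theta) - v_i}{v_i}\right)^2,}
#' so that heavy-tailed levels are not dominated by the uppermost anchor
#' (squared absolute deviations are available via `objective = "absolute"`).
#' The family with the smallest objective wins; objectives below `1e-12` are
#' treated as exact and ties are broken by the fixed gallery order
#' (see [gallery_families()]).
#'
#' Three anchors do not always identify the family: any symmetric anchor
#' triple is reproduced exactly by every symmetric location-scale family
#' (normal and uniform), and the three-parameter triangular can interpolate
#' most anchor triples exactly. The tie-break order resolves such cases
#' deterministically (normal before uniform, triangular last).
#'
#' @param values Anchor values, strictly increasing, same length as `ranks`.
#' @param ranks Percentile ranks of the anchors, strictly increasing, in
#'   (0, 100).
#' @param families Subset of [gallery_families()] to consider.
#' @param objective `"relative"` (default) or `"absolute"` deviations.
#' @param nonnegative If `TRUE` (default) and the best fit is a triangular
#'   with negative minimum, the fit is repeated with the minimum pinned to
#'   zero (with a warning): the fitted quantity (a concentration or a
#'   percentage) cannot be negative.
#' @return A `fitted_distribution`: `family`, `params`, `fit_error` (the
#'   minimized objective), `anchors`.
#' @examples
#' fit <- fit_from_percentiles(qlnorm(c(.05, .5, .95), 1, 0.5) , c(5, 50, 95))
#' fit$family  # "lognormal"
#' @export
fit_from_percentiles <- function(values, ranks = c(5, 50, 95),
                                 families = gallery_families(),
                                 objective = c("relative", "absolute"),
                                 nonnegative = TRUE) {
  objective <- match.arg(objective)
  families <- match.arg(families, gallery_families(), several.ok = TRUE)
  if (length(values) != length(ranks) || length(values) < 3) {
    stop("need at least 3 anchor (rank, value) pairs", call. = FALSE)
  }
  if (any(diff(ranks) <= 0) || any(ranks <= 0) || any(ranks >= 100)) {
    stop("ranks must be strictly increasing and inside (0, 100)",
         call. = FALSE)
  }
  rel_spread <- diff(range(values)) / max(abs(values))
  if (any(diff(values) <= 0) || rel_spread < 1e-9) {
    stop("anchor values must be strictly increasing (degenerate or ",
         "non-monotone anchors)", call. = FALSE)
  }
  p <- ranks / 100
  denom <- if (objective == "relative") values else rep(1, length(values))
  fits <- list()
  for (name in families) {
    fam <- .gallery[[name]]
    if (fam$positive_support && values[1] <= 0) next
    fit <- tryCatch(.fit_family(fam, p, values, denom),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) {
      warning("family '", name, "' skipped: optimizer did not converge",
              call. = FALSE)
      next
    }
    fits[[name]] <- fit
  }
  if (length(fits) == 0) stop("no family could be fitted", call. = FALSE)
  errors <- vapply(fits, `[[`, numeric(1), "value")
  errors[errors < 1e-12] <- 0  # exact ties resolved by gallery order
  best_name <- names(fits)[which.min(errors)]
  best <- fits[[best_name]]
  anchors <- tibble::tibble(rank = ranks, value = values)
  if (nonnegative && best_name == "triangular" && best$params["min"] < 0) {
    warning("fitted triangular minimum ", format(best$params["min"],
            digits = 4), " < 0 for a nonnegative quantity; truncating the ",
            "minimum at 0 and refitting", call. = FALSE)
    obj0 <- function(f) {
      par <- c(0, exp(f[1]), exp(f[1]) + exp(f[2]))
      q <- .qtri(p, par[1], par[2], par[3])
      if (any(!is.finite(q))) return(1e10)
      sum(((q - values) / values)^2)
    }
    start <- log(pmax(c(values[2], values[3] - values[2]), 1e-9))
    opt <- stats::optim(start, obj0, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-14))
    best$params <- stats::setNames(
      c(0, exp(opt$par[1]), exp(opt$par[1]) + exp(opt$par[2])),
      c("min", "mode", "max"))
    best$value <- opt$value
  }
  new_fitted_distribution(best_name, best$params, best$value, anchors)
}
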