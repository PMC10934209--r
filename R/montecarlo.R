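# Probabilistic risk assessment: lognormal moment matching, best-fit
# distribution selection (Anderson-Darling + chi-squared), the seeded
# Monte Carlo ILCR engine, percentile reporting and contribution-to-
# variance sensitivity analysis.

#' Lognormal parameters from arithmetic moments
#'
#' Converts the arithmetic mean and sd of a lognormal variable to its
#' log-scale parameters: `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`. This is the convention under
#' which probabilistic risk tables report lognormal "Mean" and "SD".
#'
#' @param mean Arithmetic mean (> 0).
#' @param sd Arithmetic standard deviation (> 0).
#' @return List with `meanlog`, `sdlog`.
#' @seealso [lognormal_moments()] for the inverse.
#' @examples
#' lognormal_from_moments(2e-5, 5.66e-5)  # meanlog -11.9189, sdlog 1.4827
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0) stop("`mean` must be > 0")
  if (!is.numeric(sd) || sd < 0) stop("`sd` must be >= 0")
  s2 <- log1p((sd / mean)^2)  # log1p keeps the round trip at ~1e-16
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Arithmetic moments of a lognormal distribution
#'
#' Inverse of [lognormal_from_moments()]:
#' `mean = exp(meanlog + sdlog^2/2)`,
#' `sd = mean * sqrt(exp(sdlog^2) - 1)`.
#'
#' @param meanlog,sdlog Log-scale parameters.
#' @return List with `mean`, `sd`.
#' @export
lognormal_moments <- function(meanlog, sdlog) {
  m <- exp(meanlog + sdlog^2 / 2)
  list(mean = m, sd = m * sqrt(expm1(sdlog^2)))
}

# Anderson-Darling statistic for a fitted continuous CDF.
ad_statistic <- function(x, cdf) {
  n <- length(x)
  u <- cdf(sort(x))
  eps <- .Machine$double.eps
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

# Pearson chi-squared GOF statistic on equiprobable bins under the fitted
# CDF (k chosen so expected counts are >= 5).
chi2_statistic <- function(x, cdf) {
  n <- length(x)
  k <- max(4L, min(50L, floor(n / 5)))
  u <- cdf(x)
  obs <- tabulate(pmin(pmax(ceiling(u * k), 1L), k), nbins = k)
  e <- n / k
  sum((obs - e)^2 / e)
}

#' Fit candidate distributions and select the best
#'
#' Fits each candidate family by maximum likelihood, computes the
#' Anderson--Darling (AD) and chi-squared goodness-of-fit statistics, and
#' selects the candidate with the smallest AD statistic (ties broken by
#' the chi-squared statistic, then candidate order). Candidates whose
#' support excludes the data (e.g. lognormal with non-positive samples)
#' are skipped with a message; degenerate (constant) samples are an error.
#'
#' @param samples Numeric vector, length >= 20.
#' @param candidates Character vector of families among `"normal"`,
#'   `"lognormal"`, `"uniform"`, `"triangular"`.
#' @return List of per-candidate fit results (`family`, `params`,
#'   `ad_stat`, `chi2_stat`, `selected`), with exactly one `selected`.
#' @export
fit_distribution <- function(samples,
                             candidates = c("normal", "lognormal",
                                            "uniform")) {
  if (length(samples) < 20) stop("need at least 20 samples")
  if (!length(candidates)) stop("need at least one candidate family")
  if (stats::sd(samples) == 0) {
    stop("constant samples: no continuous family is fittable")
  }
  n <- length(samples)
  fits <- list()
  for (fam in candidates) {
    fit <- switch(fam,
      normal = {
        p <- list(mean = mean(samples),
                  sd = stats::sd(samples) * sqrt((n - 1) / n))
        list(params = p,
             cdf = function(x) stats::pnorm(x, p$mean, p$sd))
      },
      lognormal = {
        if (any(samples <= 0)) {
          message("fit_distribution: skipping lognormal ",
                  "(non-positive samples)")
          NULL
        } else {
          lx <- log(samples)
          p <- list(meanlog = mean(lx),
                    sdlog = stats::sd(lx) * sqrt((n - 1) / n))
          list(params = p,
               cdf = function(x) stats::plnorm(x, p$meanlog, p$sdlog))
        }
      },
      uniform = {
        p <- list(low = min(samples), high = max(samples))
        list(params = p,
             cdf = function(x) stats::punif(x, p$low, p$high))
      },
      triangular = {
        # MLE of the mode with endpoints just outside the sample range
        pad <- diff(range(samples)) * 1e-3
        a <- min(samples) - pad
        b <- max(samples) + pad
        nll <- function(cc) -sum(log(dtri(samples, a, cc, b)))
        opt <- stats::optimize(nll, c(a, b))
        p <- list(low = a, mode = opt$minimum, high = b)
        list(params = p, cdf = function(x) ptri(x, p$low, p$mode, p$high))
      },
      stop("unknown candidate family: ", fam)
    )
    if (is.null(fit)) next
    fits[[length(fits) + 1L]] <- list(
      family = fam, params = fit$params,
      ad_stat = ad_statistic(samples, fit$cdf),
      chi2_stat = chi2_statistic(samples, fit$cdf),
      selected = FALSE)
  }
  if (!length(fits)) stop("no candidate family is valid for these samples")
  ad <- vapply(fits, `[[`, 0, "ad_stat")
  chi <- vapply(fits, `[[`, 0, "chi2_stat")
  best <- order(ad, chi, seq_along(fits))[1]
  fits[[best]]$selected <- TRUE
  fits
}

dtri <- function(x, a, c, b) {
  out <- numeric(length(x))
  i <- x >= a & x < c
  out[i] <- 2 * (x[i] - a) / ((b - a) * (c - a))
  j <- x >= c & x <= b
  out[j] <- 2 * (b - x[j]) / ((b - a) * (b - c))
  pmax(out, .Machine$double.xmin)
}

#' Linear-interpolation percentiles
#'
#' Quantiles by linear interpolation between order statistics (the
#' standard `type = 7` rule), on the 0--100 percentile scale.
#'
#' @param draws Non-empty numeric vector.
#' @param probs Percentile levels in \[0, 100\] (default 10, 50, 90).
#' @return Named numeric vector of percentiles.
#' @examples
#' percentiles(1:100)  # 10.9, 50.5, 90.1
#' @export
percentiles <- function(draws, probs = c(10, 50, 90)) {
  if (!length(draws)) stop("`draws` must be non-empty")
  if (any(probs < 0 | probs > 100)) stop("probs must lie in [0, 100]")
  q <- stats::quantile(draws, probs / 100, type = 7, names = FALSE)
  stats::setNames(q, paste0("p", probs))
}

#' Contribution-to-variance sensitivity shares
#'
#' For each stochastic input column, the signed share of the output's
#' variability: `share_i = sign(rho_i) * rho_i^2 / sum_j rho_j^2 * 100`,
#' where `rho_i` is the Spearman rank correlation between input i and the
#' output. Constant input columns get share 0 and are excluded from the
#' normalization; absolute shares always sum to 100% over the stochastic
#' inputs. A positive share means the factor drives risk up.
#'
#' @param input_draws Numeric matrix, n draws x k inputs (named columns).
#' @param output_draws Numeric vector of n output draws (non-constant).
#' @return Named numeric vector of signed percentage shares.
#' @export
sensitivity <- function(input_draws, output_draws) {
  if (!is.matrix(input_draws)) input_draws <- as.matrix(input_draws)
  n <- nrow(input_draws)
  if (n < 10) stop("need at least 10 draws")
  if (length(output_draws) != n) stop("draw counts disagree")
  if (stats::sd(output_draws) == 0) stop("constant output: no sensitivity")
  rho <- apply(input_draws, 2, function(col) {
    if (stats::sd(col) == 0) return(0)
    stats::cor(col, output_draws, method = "spearman")
  })
  denom <- sum(rho^2)
  if (denom == 0) stop("all inputs constant or uncorrelated by rank")
  sign(rho) * rho^2 / denom * 100
}

#' Seeded Monte Carlo ILCR simulation
#'
#' Draws `n` independent joint samples of the TEQ and the six exposure
#' factors (each point-valued or a [dist_spec()], sampled independently),
#' applies the risk model `ILCR = TEQ * DR * CSF * EF * ED / (BW * AT)`
#' row-wise, and reports moments, the 10/50/90th percentiles, a lognormal
#' fit of the output and contribution-to-variance sensitivity shares over
#' the stochastic inputs. Fully reproducible from `seed`.
#'
#' @param teq_spec The TEQ input: a number, a `teq_result`, or a
#'   [dist_spec()].
#' @param factors An [exposure_factors()] (factors may be stochastic).
#' @param n Number of iterations (default 10000).
#' @param seed Integer seed (required; recorded in the result).
#' @param probs Percentile levels to report.
#' @return Object of class `mc_result`: `draws`, `n`, `seed`, `mean`,
#'   `sd`, `percentiles`, `sensitivity`, `fitted` (lognormal fit of the
#'   output, `NULL` when the output is constant), `group`.
#' @export
simulate_ilcr <- function(teq_spec, factors, n = 10000, seed,
                          probs = c(10, 50, 90)) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  if (inherits(teq_spec, "teq_result")) teq_spec <- teq_spec$teq
  if (!inherits(factors, "exposure_factors")) {
    stop("`factors` must be an exposure_factors object")
  }
  specs <- c(list(teq = teq_spec),
             lapply(c(dr = "dr", csf = "csf", ef = "ef", ed = "ed",
                      bw = "bw", at = "at"),
                    function(k) factors[[k]]))
  draws_in <- with_seed(seed, function() {
    m <- vapply(specs, function(s) sample_spec(s, n), numeric(n))
    dim(m) <- c(n, length(specs))
    colnames(m) <- names(specs)
    m
  })
  out <- draws_in[, "teq"] * draws_in[, "dr"] * draws_in[, "csf"] *
    draws_in[, "ef"] * draws_in[, "ed"] /
    (draws_in[, "bw"] * draws_in[, "at"])
  stochastic <- !vapply(specs, is_point, TRUE)
  sens <- if (any(stochastic) && stats::sd(out) > 0) {
    sensitivity(draws_in[, stochastic, drop = FALSE], out)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  fitted <- if (stats::sd(out) > 0 && all(out > 0)) {
    fit_distribution(out, "lognormal")[[1]]
  }
  structure(
    list(draws = out, n = n, seed = as.integer(seed),
         mean = mean(out), sd = stats::sd(out),
         percentiles = percentiles(out, probs),
         sensitivity = sens, fitted = fitted, group = factors$group),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result [%s]: n = %d, seed = %d\n",
              x$group, x$n, x$seed))
  cat(sprintf("  mean = %.3g, sd = %.3g\n", x$mean, x$sd))
  cat("  percentiles:",
      paste(names(x$percentiles), signif(x$percentiles, 3),
            sep = " = ", collapse = ", "), "\n")
  if (length(x$sensitivity)) {
    cat("  sensitivity (% contribution to variance):\n")
    for (k in names(sort(-abs(x$sensitivity)))) {
      cat(sprintf("    %-4s %+6.1f%%\n", k, x$sensitivity[[k]]))
    }
  }
  invisible(x)
}

#' @export
write_report.mc_result <- function(x, path,
                                   format = c("delimited", "structured")) {
  format <- match.arg(format)
  payload <- list(
    group = x$group, n = x$n, seed = x$seed, mean = x$mean, sd = x$sd,
    percentiles = as.list(x$percentiles),
    sensitivity = as.list(x$sensitivity),
    fitted = if (!is.null(x$fitted)) {
      x$fitted[c("family", "params", "ad_stat", "chi2_stat")]
    }
  )
  if (format == "delimited") {
    flat <- unlist(payload)
    utils::write.csv(data.frame(key = names(flat),
                                value = as.character(flat)),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
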