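# Exposure-factor configuration: distribution specs, validation, JSON I/O,
# and sampling from specs (used by the synthetic generators and the Monte
# Carlo engine).

#' Specify a stochastic (or point) model input
#'
#' A distribution spec describes one scalar input to the risk model as a
#' point value or a parametric distribution, optionally truncated.
#' Lognormal specs are parameterized by their ARITHMETIC mean and sd and
#' converted internally to log-scale parameters via
#' [lognormal_from_moments()] — the convention under which probabilistic
#' risk tables report "Mean" and "SD".
#'
#' @param family One of `"point"`, `"normal"`, `"lognormal"`, `"uniform"`,
#'   `"triangular"`.
#' @param ... Family parameters: `value` (point); `mean`, `sd`
#'   (normal/lognormal, arithmetic scale); `low`, `high` (uniform);
#'   `low`, `mode`, `high` (triangular).
#' @param truncation Optional length-2 numeric `c(low, high)` restricting
#'   the support.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", mean = 5, sd = 2)
#' dist_spec("point", value = 60)
#' @export
dist_spec <- function(family = c("point", "normal", "lognormal",
                                 "uniform", "triangular"),
                      ..., truncation = NULL) {
  family <- match.arg(family)
  p <- list(...)
  num1 <- function(key) {
    v <- p[[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("%s spec requires numeric parameter '%s'", family, key))
    }
    v
  }
  params <- switch(family,
    point = list(value = num1("value")),
    normal = {
      out <- list(mean = num1("mean"), sd = num1("sd"))
      if (out$sd <= 0) stop("normal spec requires sd > 0")
      out
    },
    lognormal = {
      out <- list(mean = num1("mean"), sd = num1("sd"))
      if (out$mean <= 0) stop("lognormal spec requires mean > 0")
      if (out$sd <= 0) stop("lognormal spec requires sd > 0")
      out
    },
    uniform = {
      out <- list(low = num1("low"), high = num1("high"))
      if (out$low >= out$high) stop("uniform spec requires low < high")
      out
    },
    triangular = {
      out <- list(low = num1("low"), mode = num1("mode"),
                  high = num1("high"))
      if (out$low >= out$high || out$mode < out$low || out$mode > out$high) {
        stop("triangular spec requires low <= mode <= high, low < high")
      }
      out
    }
  )
  if (!is.null(truncation)) {
    if (!is.numeric(truncation) || length(truncation) != 2 ||
        truncation[1] >= truncation[2]) {
      stop("`truncation` must be numeric c(low, high) with low < high")
    }
  }
  structure(list(family = family, params = params, truncation = truncation),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("dist_spec:", x$family, "(",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      ")")
  if (!is.null(x$truncation)) {
    cat(" truncated to [", x$truncation[1], ",", x$truncation[2], "]")
  }
  cat("\n")
  invisible(x)
}

is_point <- function(spec) {
  !inherits(spec, "dist_spec") || spec$family == "point"
}

spec_point_value <- function(spec) {
  if (inherits(spec, "dist_spec")) spec$params$value else spec
}

# CDF / quantile pair for a spec's base family (no truncation).
spec_cdf <- function(spec) {
  p <- spec$params
  switch(spec$family,
    normal = function(x) stats::pnorm(x, p$mean, p$sd),
    lognormal = {
      lp <- lognormal_from_moments(p$mean, p$sd)
      function(x) stats::plnorm(x, lp$meanlog, lp$sdlog)
    },
    uniform = function(x) stats::punif(x, p$low, p$high),
    triangular = function(x) ptri(x, p$low, p$mode, p$high),
    stop("no cdf for family ", spec$family)
  )
}

spec_quantile <- function(spec) {
  p <- spec$params
  switch(spec$family,
    normal = function(q) stats::qnorm(q, p$mean, p$sd),
    lognormal = {
      lp <- lognormal_from_moments(p$mean, p$sd)
      function(q) stats::qlnorm(q, lp$meanlog, lp$sdlog)
    },
    uniform = function(q) stats::qunif(q, p$low, p$high),
    triangular = function(q) qtri(q, p$low, p$mode, p$high),
    stop("no quantile for family ", spec$family)
  )
}

# Triangular distribution (closed-form CDF and quantile).
ptri <- function(x, a, c, b) {
  out <- numeric(length(x))
  out[x >= b] <- 1
  i <- x > a & x < c
  out[i] <- (x[i] - a)^2 / ((b - a) * (c - a))
  j <- x >= c & x < b
  out[j] <- 1 - (b - x[j])^2 / ((b - a) * (b - c))
  out
}

qtri <- function(q, a, c, b) {
  fc <- (c - a) / (b - a)
  ifelse(q < fc,
         a + sqrt(q * (b - a) * (c - a)),
         b - sqrt((1 - q) * (b - a) * (b - c)))
}

#' Draw samples from a distribution spec
#'
#' Inverse-transform sampling; truncation is honoured exactly by mapping
#' uniforms into the CDF mass between the truncation bounds (no rejection
#' loop, so draws are reproducible and the per-draw RNG cost is constant).
#'
#' @param spec A [dist_spec()] or a bare number (treated as a point).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_spec <- function(spec, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  if (is_point(spec)) return(rep(spec_point_value(spec), n))
  cdf <- spec_cdf(spec)
  qf <- spec_quantile(spec)
  lo <- 0
  hi <- 1
  if (!is.null(spec$truncation)) {
    lo <- cdf(spec$truncation[1])
    hi <- cdf(spec$truncation[2])
    if (hi - lo <= 0) {
      stop("truncation bounds exclude all probability mass")
    }
  }
  qf(lo + (hi - lo) * stats::runif(n))
}

#' Construct a validated exposure-factor set for one age group
#'
#' Holds the six multiplicative factors of the lifetime cancer risk model:
#' daily herbal intake DR (g/day), cancer slope factor CSF
#' ((mg/kg/day)^-1), exposure frequency EF (days/year, default 365),
#' exposure duration ED (years), body weight BW (kg) and averaging time
#' AT (days). Each may be a point value or a [dist_spec()].
#'
#' @param group Age-group label.
#' @param dr,csf,ef,ed,bw,at Point value or [dist_spec()]; all strictly
#'   positive, `ef <= 366`.
#' @return An object of class `exposure_factors`.
#' @export
exposure_factors <- function(group, dr, csf, ef = 365, ed, bw, at) {
  fac <- list(dr = dr, csf = csf, ef = ef, ed = ed, bw = bw, at = at)
  for (key in names(fac)) {
    v <- fac[[key]]
    if (is_point(v)) {
      pv <- spec_point_value(v)
      if (!is.numeric(pv) || length(pv) != 1 || !is.finite(pv) || pv <= 0) {
        stop(sprintf("exposure factor '%s' must be strictly positive", key))
      }
    } else if (!inherits(v, "dist_spec")) {
      stop(sprintf("exposure factor '%s' must be a number or dist_spec", key))
    }
  }
  if (is_point(fac$ef) && spec_point_value(fac$ef) > 366) {
    stop("exposure factor 'ef' must be <= 366 days/year")
  }
  structure(c(list(group = as.character(group)), fac),
            class = "exposure_factors")
}

#' @export
print.exposure_factors <- function(x, ...) {
  cat("exposure_factors for group:", x$group, "\n")
  for (key in c("dr", "csf", "ef", "ed", "bw", "at")) {
    v <- x[[key]]
    cat(" ", key, ": ",
        if (is_point(v)) format(spec_point_value(v)) else
          paste0(v$family, "(",
                 paste(names(v$params), unlist(v$params),
                       sep = "=", collapse = ", "), ")"),
        "\n", sep = "")
  }
  invisible(x)
}

parse_spec_node <- function(node, where) {
  if (is.numeric(node) && length(node) == 1) return(node)
  if (is.list(node) && !is.null(node$family)) {
    args <- node[setdiff(names(node), c("family", "truncation"))]
    trunc <- if (!is.null(node$truncation)) unlist(node$truncation)
    out <- try(do.call(dist_spec,
                       c(list(family = node$family), args,
                         list(truncation = trunc))),
               silent = TRUE)
    if (inherits(out, "try-error")) {
      stop(sprintf("invalid distribution spec at %s: %s", where,
                   attr(out, "condition")$message))
    }
    return(out)
  }
  stop("malformed value at ", where,
       ": expected a number or {family: ..., <params>}")
}

#' Read an exposure-factor configuration
#'
#' Parses a JSON document with one block per age group, e.g.
#' `[{"group": "adult", "dr": 5, "csf": 7.3, "ef": 365, "ed": 30,
#' "bw": 60, "at": 25550}]`. Any factor may instead be an object
#' `{"family": "lognormal", "mean": 5, "sd": 2}` (optionally with
#' `"truncation": [low, high]`), parsed into a [dist_spec()].
#'
#' @param path Path to the JSON config.
#' @return A list of [exposure_factors()], one per age group.
#' @export
read_exposure_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(doc$groups)) doc <- doc$groups
  if (!length(doc)) stop("exposure config contains no age-group blocks")
  lapply(seq_along(doc), function(i) {
    block <- doc[[i]]
    label <- if (!is.null(block$group)) block$group else sprintf("group %d", i)
    need <- c("group", "dr", "csf", "ef", "ed", "bw", "at")
    missing <- setdiff(need, names(block))
    if (length(missing)) {
      stop(sprintf("block '%s': missing required key(s): %s", label,
                   paste(missing, collapse = ", ")))
    }
    parsed <- lapply(c("dr", "csf", "ef", "ed", "bw", "at"), function(key) {
      parse_spec_node(block[[key]], sprintf("%s/%s", label, key))
    })
    names(parsed) <- c("dr", "csf", "ef", "ed", "bw", "at")
    out <- try(do.call(exposure_factors, c(list(group = block$group), parsed)),
               silent = TRUE)
    if (inherits(out, "try-error")) {
      stop(sprintf("block '%s': %s", label, attr(out, "condition")$message))
    }
    out
  })
}

#' Write a template exposure-factor configuration
#'
#' The risk model needs population-specific intake and body-weight data
#' that must be supplied by the analyst; this writes a documented JSON
#' starting point with one adult block (EF fixed at 365 days/year, the
#' convention for habitual consumption). The template's DR and CSF values
#' are placeholders, not recommendations.
#'
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_exposure_template <- function(path) {
  template <- list(
    comment = paste("Template exposure factors. Units: dr g/day,",
                    "csf (mg/kg/day)^-1, ef days/year, ed years, bw kg,",
                    "at days. Replace placeholders with survey values."),
    groups = list(list(
      group = "adult",
      dr = list(family = "lognormal", mean = 5, sd = 2),
      csf = 7.3,
      ef = 365,
      ed = 30,
      bw = list(family = "normal", mean = 60, sd = 10,
                truncation = c(30, 120)),
      at = 25550
    ))
  )
  jsonlite::write_json(template, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
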