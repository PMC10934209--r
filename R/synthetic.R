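# Seeded synthetic-data generators: lognormal contamination with hard
# LOD censoring, and exposure-factor populations.

# Evaluate fn with a local, restored RNG state so seeded generators do not
# disturb the caller's random stream.
with_seed <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer `seed` is required for reproducible generation")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

#' Describe a synthetic contamination regime
#'
#' The generator's model of a surveyed concentration table: each cell's
#' true level is lognormal with per-analyte median `location` (ug/kg)
#' scaled by a plant-part multiplier, and geometric standard deviation
#' `spread`; cells whose true level falls below the per-analyte LOD are
#' reported as non-detects.
#'
#' Defaults emulate a market survey of the 16 priority PAHs: low-ring
#' analytes dominate (median 30 ug/kg for 2--3 rings, 10 for 4 rings,
#' 3 for 5 rings, 0.5 for 6 rings), geometric sd 2.5, part multipliers
#' root_stem 3 > flower 2 > fruit_seed 1 (roots accumulate soil-borne
#' PAHs longest), and the instrument LODs of [pah_registry()]
#' (4.96--8.14 ug/kg).
#'
#' @param location Named per-analyte median of the true level, ug/kg (> 0).
#' @param spread Named per-analyte geometric sd (> 1); scalars recycle.
#' @param part_multiplier Named multiplier per plant-part class.
#' @param lod Named per-analyte limit of detection, ug/kg (>= 0).
#' @return Object of class `contamination_profile`.
#' @export
contamination_profile <- function(location = NULL, spread = 2.5,
                                  part_multiplier = c(root_stem = 3,
                                                      flower = 2,
                                                      fruit_seed = 1),
                                  lod = NULL) {
  reg <- pah_registry()
  ana <- reg$abbreviation
  if (is.null(location)) {
    location <- stats::setNames(
      c(30, 10, 3, 0.5)[match(reg$ring_count, c(3, 4, 5, 6), nomatch = 1)],
      ana)
    location["Naph"] <- 30  # 2-ring grouped with low-ring dominance
  }
  expand <- function(x, what, lower, strict) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(ana)), ana)
    }
    miss <- setdiff(ana, names(x))
    if (length(miss)) {
      stop("`", what, "` missing analyte(s): ", paste(miss, collapse = ", "))
    }
    x <- x[ana]
    ok <- if (strict) all(x > lower) else all(x >= lower)
    if (any(!is.finite(x)) || !ok) {
      stop("`", what, "` must be finite and ",
           if (strict) "> " else ">= ", lower)
    }
    x
  }
  location <- expand(location, "location", 0, TRUE)
  spread <- expand(spread, "spread", 1, TRUE)
  if (is.null(lod)) lod <- stats::setNames(reg$lod, ana)
  lod <- expand(lod, "lod", 0, FALSE)
  need_parts <- c("root_stem", "flower", "fruit_seed")
  if (!all(need_parts %in% names(part_multiplier)) ||
      any(part_multiplier <= 0)) {
    stop("`part_multiplier` must name positive multipliers for: ",
         paste(need_parts, collapse = ", "))
  }
  structure(list(location = location, spread = spread,
                 part_multiplier = part_multiplier, lod = lod),
            class = "contamination_profile")
}

#' Generate a synthetic censored concentration table
#'
#' Draws each cell's true level lognormally
#' (`median = location * part_multiplier`, geometric sd `spread`), then
#' censors cells below the analyte's LOD to non-detects. The uncensored
#' truth matrix is returned alongside the table so downstream results can
#' be checked against ground truth.
#'
#' @param profile A [contamination_profile()].
#' @param herbs Named character vector: herb id -> plant-part class.
#' @param seed Integer seed; required (generation must be reproducible).
#' @return List with `table` (a [concentration_table()]) and `truth`
#'   (numeric herb x analyte matrix of uncensored true levels).
#' @examples
#' herbs <- c(rootA = "root_stem", flowerB = "flower")
#' g <- generate_concentration_table(contamination_profile(), herbs, seed = 1)
#' @export
generate_concentration_table <- function(profile, herbs, seed) {
  if (!inherits(profile, "contamination_profile")) {
    stop("`profile` must be a contamination_profile")
  }
  if (!length(herbs)) stop("empty herb list")
  if (is.null(names(herbs))) {
    stop("`herbs` must be a named vector: herb id -> part class")
  }
  if (!all(herbs %in% names(profile$part_multiplier))) {
    stop("unknown plant-part class in `herbs`")
  }
  ana <- names(profile$location)
  truth <- with_seed(seed, function() {
    t(vapply(seq_along(herbs), function(i) {
      mult <- profile$part_multiplier[[herbs[[i]]]]
      stats::rlnorm(length(ana),
                    meanlog = log(profile$location * mult),
                    sdlog = log(profile$spread))
    }, numeric(length(ana))))
  })
  dimnames(truth) <- list(names(herbs), ana)
  detected <- sweep(truth, 2, profile$lod, ">=")
  values <- ifelse(detected, truth, NA_real_)
  list(
    table = concentration_table(values, detected, parts = unname(herbs)),
    truth = truth
  )
}

#' Generate a population of exposure-factor draws
#'
#' Draws `n` joint samples of the six risk-model factors for one age
#' group, sampling each stochastic factor independently from its
#' [dist_spec()] (truncation respected); point factors yield constant
#' columns.
#'
#' @param factors An [exposure_factors()] (or a list of them; each gets
#'   its own matrix).
#' @param n Number of draws (> 0).
#' @param seed Integer seed.
#' @return Numeric matrix `n x 6` with columns `dr, csf, ef, ed, bw, at`
#'   (or a named list of such matrices for a list input).
#' @export
generate_exposure_population <- function(factors, n, seed) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) stop("`n` must be > 0")
  if (inherits(factors, "exposure_factors")) {
    keys <- c("dr", "csf", "ef", "ed", "bw", "at")
    return(with_seed(seed, function() {
      m <- vapply(keys, function(k) sample_spec(factors[[k]], n), numeric(n))
      dim(m) <- c(as.integer(n), length(keys))  # vapply drops dim at n = 1
      colnames(m) <- keys
      m
    }))
  }
  out <- lapply(seq_along(factors), function(i) {
    generate_exposure_population(factors[[i]], n, seed + i - 1)
  })
  stats::setNames(out, vapply(factors, `[[`, "", "group"))
}
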