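# Deterministic risk scoring: BaP toxic equivalents and the incremental
# lifetime cancer risk (ILCR) chain.

#' BaP toxic-equivalent concentration (TEQ) of a PAH mixture
#'
#' Expresses a 16-analyte concentration vector as an equivalent
#' benzo\[a\]pyrene concentration: `TEQ = sum(C_i * TEF_i) / divisor`,
#' with non-detects imputed per policy before weighting. The conventional
#' divisor of 1000 is carried by the [tef_scheme()] and recorded in the
#' result, because the unit of the TEQ (and hence the CSF convention any
#' downstream ILCR must use) depends on it: ug/kg inputs with divisor
#' 1000 yield mg/kg equivalents.
#'
#' @param concentrations Named numeric vector over all 16 analytes, ug/kg;
#'   `NA` for non-detects.
#' @param detected Named logical vector of detection flags; defaults to
#'   `!is.na(concentrations)`.
#' @param tefs A [tef_scheme()].
#' @param nd_policy Non-detect imputation policy (see [total_pahs()]).
#' @param lods Optional LODs for LOD-based policies.
#' @param herb Optional identifier carried into the result.
#' @return Object of class `teq_result` with `herb`, `teq`,
#'   `contributions` (per analyte, same unit) and `unit_note`.
#' @examples
#' x <- setNames(rep(0, 16), pah_analytes()); x["BaP"] <- 39.928
#' teq_bap(x)$teq  # 0.039928
#' @export
teq_bap <- function(concentrations, detected = !is.na(concentrations),
                    tefs = tef_scheme(),
                    nd_policy = c("zero", "half_lod", "lod"),
                    lods = NULL, herb = NA_character_) {
  if (!inherits(tefs, "tef_scheme")) stop("`tefs` must be a tef_scheme")
  need <- pah_analytes()
  miss <- setdiff(need, names(concentrations))
  if (length(miss)) {
    stop("concentration vector missing analyte(s): ",
         paste(miss, collapse = ", "))
  }
  concentrations <- concentrations[need]
  detected <- detected[need]
  x <- impute_nd(concentrations, detected, nd_policy, lods)
  contrib <- x * tefs$tefs[need] / tefs$scale_divisor
  structure(
    list(herb = herb, teq = sum(contrib), contributions = contrib,
         unit_note = sprintf(
           "TEQ = sum(C[ug/kg] * TEF) / %g; with divisor 1000 the TEQ is in mg/kg BaP-equivalents",
           tefs$scale_divisor)),
    class = "teq_result"
  )
}

#' TEQ for every herb of a concentration table
#'
#' @param table A [concentration_table()].
#' @inheritParams teq_bap
#' @return Named list of `teq_result`, one per herb.
#' @export
teq_table <- function(table, tefs = tef_scheme(), nd_policy = "zero",
                      lods = NULL) {
  out <- lapply(table$herbs, function(h) {
    i <- herb_row(table, h)
    teq_bap(table$values[i, ], table$detected[i, ], tefs, nd_policy,
            lods, herb = h)
  })
  stats::setNames(out, table$herbs)
}

#' @export
print.teq_result <- function(x, ...) {
  cat(sprintf("teq_result [%s]: TEQ = %g (%s)\n",
              x$herb, x$teq, x$unit_note))
  invisible(x)
}

#' Incremental lifetime cancer risk (ILCR)
#'
#' The multiplicative dietary risk model
#' `ILCR = TEQ * DR * CSF * EF * ED / (BW * AT)` evaluated at point-valued
#' exposure factors, with the resulting risk banded by [band()].
#'
#' @param teq A `teq_result` from [teq_bap()], or a bare TEQ value.
#' @param factors An [exposure_factors()] whose six factors are all
#'   point-valued.
#' @return Object of class `ilcr_result` with `herb`, `group`, `ilcr`,
#'   `band`.
#' @export
ilcr <- function(teq, factors) {
  teq_value <- if (inherits(teq, "teq_result")) teq$teq else teq
  if (!inherits(factors, "exposure_factors")) {
    stop("`factors` must be an exposure_factors object")
  }
  vals <- lapply(c(dr = "dr", csf = "csf", ef = "ef", ed = "ed",
                   bw = "bw", at = "at"),
                 function(k) {
    v <- factors[[k]]
    if (!is_point(v)) {
      stop("exposure factor '", k,
           "' is stochastic; use simulate_ilcr() for distributions")
    }
    spec_point_value(v)
  })
  if (vals$bw <= 0 || vals$at <= 0) stop("bw and at must be positive")
  risk <- teq_value * vals$dr * vals$csf * vals$ef * vals$ed /
    (vals$bw * vals$at)
  structure(
    list(herb = if (inherits(teq, "teq_result")) teq$herb else NA_character_,
         group = factors$group, ilcr = risk, band = band(risk)),
    class = "ilcr_result"
  )
}

#' @export
print.ilcr_result <- function(x, ...) {
  cat(sprintf("ilcr_result [%s, %s]: ILCR = %.3g (%s)\n",
              x$herb, x$group, x$ilcr, x$band))
  invisible(x)
}

#' Risk band of an ILCR value
#'
#' Lifetime risks below 1e-6 are negligible; risks in \[1e-6, 1e-4\]
#' (both boundaries included, "between") are potential cancer risks;
#' risks above 1e-4 are unacceptable.
#'
#' @param ilcr_value Finite non-negative risk value (vectorized).
#' @return Character vector over `{"negligible", "potential",
#'   "unacceptable"}`.
#' @examples
#' band(c(9.99e-7, 2.25e-6, 1.37e-3))
#' @export
band <- function(ilcr_value) {
  if (any(!is.finite(ilcr_value)) || any(ilcr_value < 0)) {
    stop("ILCR values must be finite and >= 0")
  }
  ifelse(ilcr_value < 1e-6, "negligible",
         ifelse(ilcr_value <= 1e-4, "potential", "unacceptable"))
}

#' Deterministic per-herb, per-group risk table
#'
#' Runs the TEQ -> ILCR chain over every herb and every age group with
#' point exposure factors.
#'
#' @param table A [concentration_table()].
#' @param factor_list List of [exposure_factors()] (one per age group).
#' @inheritParams teq_bap
#' @return data.frame with columns `herb`, `group`, `teq`, `ilcr`, `band`.
#' @export
risk_table <- function(table, factor_list, tefs = tef_scheme(),
                       nd_policy = "zero", lods = NULL) {
  teqs <- teq_table(table, tefs, nd_policy, lods)
  rows <- list()
  for (tq in teqs) {
    for (fac in factor_list) {
      r <- ilcr(tq, fac)
      rows[[length(rows) + 1L]] <- data.frame(
        herb = tq$herb, group = fac$group, teq = tq$teq, ilcr = r$ilcr,
        band = r$band, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
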