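# Contamination screening: detection rates, total burdens, per-analyte
# extremes, ring-class distribution, regulatory flags, cross-herb test.

herb_row <- function(table, herb) {
  i <- match(herb, table$herbs)
  if (is.na(i)) stop("unknown herb: ", herb)
  i
}

# Impute non-detects according to a policy; returns a full numeric vector.
impute_nd <- function(values, detected, nd_policy = c("zero", "half_lod",
                                                      "lod"),
                      lods = NULL) {
  nd_policy <- match.arg(nd_policy)
  out <- values
  if (nd_policy == "zero") {
    out[!detected] <- 0
    return(out)
  }
  if (is.null(lods)) {
    lods <- stats::setNames(pah_registry()$lod, pah_registry()$abbreviation)
  }
  miss <- setdiff(names(values)[!detected], names(lods))
  if (length(miss)) {
    stop("nd policy '", nd_policy, "' requires LODs for: ",
         paste(miss, collapse = ", "))
  }
  sub <- lods[names(values)]
  if (nd_policy == "half_lod") sub <- sub / 2
  out[!detected] <- sub[!detected]
  out
}

#' Per-herb detection (contamination) rate
#'
#' Fraction of the 16 priority PAHs detected in one herb.
#'
#' @param table A [concentration_table()].
#' @param herb Herb identifier.
#' @return Fraction in \[0, 1\].
#' @examples
#' detection_rate(chm_pah_table(), "glycyrrhizae")  # 11/16 = 0.6875
#' @export
detection_rate <- function(table, herb) {
  i <- herb_row(table, herb)
  mean(table$detected[i, ])
}

#' Total PAH burden of a herb
#'
#' Sum of the 16 analyte concentrations with non-detects imputed per
#' policy: `"zero"` (exclude, the tabulation convention), `"half_lod"`,
#' or `"lod"` (substitute half or the full limit of detection).
#'
#' @inheritParams detection_rate
#' @param nd_policy Non-detect imputation policy.
#' @param lods Optional named vector of per-analyte LODs (ug/kg);
#'   defaults to the registry values when a LOD-based policy is used.
#' @return Total concentration, ug/kg.
#' @examples
#' total_pahs(chm_pah_table(), "honeysuckle")  # 1414.087
#' @export
total_pahs <- function(table, herb, nd_policy = c("zero", "half_lod", "lod"),
                       lods = NULL) {
  i <- herb_row(table, herb)
  sum(impute_nd(table$values[i, ], table$detected[i, ], nd_policy, lods))
}

#' Concentration extremes of one analyte across herbs
#'
#' Minimum and maximum over detected cells only; with zero detections the
#' extremes are undefined (`NA`) and `n_detected` is 0.
#'
#' @param table A [concentration_table()].
#' @param analyte Analyte abbreviation.
#' @return List with `min`, `max` (ug/kg, `NA` if never detected) and
#'   `n_detected`.
#' @export
analyte_extremes <- function(table, analyte) {
  j <- match(analyte, table$analytes)
  if (is.na(j)) stop("unknown analyte: ", analyte)
  det <- table$detected[, j]
  vals <- table$values[det, j]
  list(
    min = if (length(vals)) min(vals) else NA_real_,
    max = if (length(vals)) max(vals) else NA_real_,
    n_detected = sum(det)
  )
}

#' Ring-class distribution of a herb's PAH burden
#'
#' Shares of the total over the ring-number classes 2--3, 4 and 5--6, on
#' the concentration basis or the toxic-equivalent (TEQ) basis
#' (concentration x TEF). Non-detects contribute zero. A herb whose total
#' is zero has undefined shares (`NA`) and `defined = FALSE`.
#'
#' @inheritParams detection_rate
#' @param basis `"concentration"` or `"teq"`.
#' @param tefs A [tef_scheme()]; used for the TEQ basis.
#' @return List with `shares` (named fractions summing to 1 over
#'   `rings_2_3`, `rings_4`, `rings_5_6`) and `defined`.
#' @export
ring_class_shares <- function(table, herb,
                              basis = c("concentration", "teq"),
                              tefs = tef_scheme()) {
  basis <- match.arg(basis)
  i <- herb_row(table, herb)
  x <- impute_nd(table$values[i, ], table$detected[i, ], "zero")
  if (basis == "teq") x <- x * tefs$tefs[table$analytes]
  reg <- pah_registry()
  rings <- reg$ring_count[match(table$analytes, reg$abbreviation)]
  cls <- cut(rings, breaks = c(1, 3, 4, 6),
             labels = c("rings_2_3", "rings_4", "rings_5_6"))
  sums <- c(tapply(x, cls, sum, default = 0))  # named vector, no dim
  total <- sum(sums)
  if (total <= 0) {
    return(list(shares = stats::setNames(rep(NA_real_, 3), levels(cls)),
                defined = FALSE))
  }
  list(shares = sums / total, defined = TRUE)
}

#' Regulatory exceedance flags for one herb
#'
#' `bap_exceeds` is `TRUE` iff detected BaP strictly exceeds the BaP limit;
#' `pah4_exceeds` iff the PAH4 marker sum (BaA + Chry + BbF + BaP, nd -> 0)
#' strictly exceeds the PAH4 limit. Comparisons are strict because the
#' regulatory language is "exceeded".
#'
#' @inheritParams detection_rate
#' @param limits List with `bap_limit` and `pah4_limit` (ug/kg);
#'   defaults to [regulatory_limits()].
#' @return List with logicals `bap_exceeds`, `pah4_exceeds` and the
#'   computed `pah4_sum` (ug/kg).
#' @export
regulatory_flags <- function(table, herb, limits = regulatory_limits()) {
  i <- herb_row(table, herb)
  x <- impute_nd(table$values[i, ], table$detected[i, ], "zero")
  reg <- pah_registry()
  pah4 <- reg$abbreviation[reg$in_pah4]
  pah4_sum <- sum(x[intersect(pah4, table$analytes)])
  bap <- if ("BaP" %in% table$analytes) x[["BaP"]] else 0
  list(
    bap_exceeds = bap > limits$bap_limit,
    pah4_exceeds = pah4_sum > limits$pah4_limit,
    pah4_sum = pah4_sum
  )
}

#' Chi-squared test of detection-rate heterogeneity across herbs
#'
#' Pearson chi-squared statistic on the herbs x (detected, not-detected)
#' counts table, df = number of herbs - 1, without continuity correction.
#'
#' @param table A [concentration_table()] with at least 2 herbs.
#' @return List with `statistic`, `df`, `p_value`, and the `counts` table.
#' @export
detection_chi2 <- function(table) {
  if (length(table$herbs) < 2) stop("need at least 2 herbs")
  det <- rowSums(table$detected)
  nd <- rowSums(!table$detected)
  counts <- cbind(detected = det, not_detected = nd)
  if (any(rowSums(counts) == 0)) stop("herb with zero analytes")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), counts = counts)
}

#' Full contamination screening report
#'
#' Applies every screening operation to each herb and returns a tidy
#' per-herb data frame plus per-analyte extremes and the cross-herb
#' chi-squared test.
#'
#' @param table A [concentration_table()].
#' @param tefs A [tef_scheme()] for the TEQ-basis ring shares.
#' @param limits Regulatory limits, see [regulatory_flags()].
#' @param nd_policy Non-detect policy for the totals.
#' @param lods Optional LODs for LOD-based policies.
#' @return List of class `screening_report` with elements `herbs`
#'   (data.frame), `analytes` (data.frame of extremes), `chi2`.
#' @export
screen_table <- function(table, tefs = tef_scheme(),
                         limits = regulatory_limits(),
                         nd_policy = "zero", lods = NULL) {
  per_herb <- do.call(rbind, lapply(table$herbs, function(h) {
    shares_c <- ring_class_shares(table, h, "concentration", tefs)$shares
    shares_t <- ring_class_shares(table, h, "teq", tefs)$shares
    fl <- regulatory_flags(table, h, limits)
    data.frame(
      herb = h, part = unname(table$parts[h]),
      detection_rate = detection_rate(table, h),
      total = total_pahs(table, h, nd_policy, lods),
      conc_share_2_3 = shares_c[["rings_2_3"]],
      conc_share_4 = shares_c[["rings_4"]],
      conc_share_5_6 = shares_c[["rings_5_6"]],
      teq_share_2_3 = shares_t[["rings_2_3"]],
      teq_share_4 = shares_t[["rings_4"]],
      teq_share_5_6 = shares_t[["rings_5_6"]],
      bap_exceeds = fl$bap_exceeds,
      pah4_exceeds = fl$pah4_exceeds,
      stringsAsFactors = FALSE
    )
  }))
  per_analyte <- do.call(rbind, lapply(table$analytes, function(a) {
    ex <- analyte_extremes(table, a)
    data.frame(analyte = a, min = ex$min, max = ex$max,
               n_detected = ex$n_detected, stringsAsFactors = FALSE)
  }))
  structure(list(herbs = per_herb, analytes = per_analyte,
                 chi2 = detection_chi2(table)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening report:", nrow(x$herbs), "herbs\n")
  print(x$herbs[c("herb", "detection_rate", "total",
                  "bap_exceeds", "pah4_exceeds")], row.names = FALSE)
  cat(sprintf("chi-squared heterogeneity: X2 = %.3f, df = %d, p = %.4g\n",
              x$chi2$statistic, x$chi2$df, x$chi2$p_value))
  invisible(x)
}

#' @export
write_report.screening_report <- function(x, path,
    format = c("delimited", "structured")) {
  format <- match.arg(format)
  if (format == "delimited") {
    utils::write.csv(x$herbs, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(herbs = x$herbs, analytes = x$analytes,
           chi2 = x$chi2[c("statistic", "df", "p_value")]),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
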