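# Canonical registry of the 16 EPA priority PAHs.

#' The 16 EPA priority PAHs
#'
#' Canonical registry of the sixteen U.S. EPA priority polycyclic aromatic
#' hydrocarbons in conventional elution order, with ring counts, default
#' Nisbet--LaGoy toxic equivalency factors (TEFs, benzo\[a\]pyrene = 1),
#' membership in the EU "PAH4" regulatory marker set
#' (BaA, Chry, BbF, BaP), and representative GC-MS limits of detection
#' (LOD, ug/kg) used as defaults by the synthetic-data generator and the
#' LOD-based non-detect imputation policies.
#'
#' @return A data.frame with 16 rows and columns `name`, `abbreviation`,
#'   `cas`, `ring_count`, `tef`, `in_pah4`, `lod`.
#' @examples
#' reg <- pah_registry()
#' sum(reg$in_pah4)      # 4
#' reg$tef[reg$abbreviation == "BaP"]  # 1
#' @export
pah_registry <- function() {
  data.frame(
    name = c(
      "Naphthalene", "Acenaphthylene", "Acenaphthene", "Fluorene",
      "Phenanthrene", "Anthracene", "Fluoranthene", "Pyrene",
      "Benz[a]anthracene", "Chrysene", "Benzo[b]fluoranthene",
      "Benzo[k]fluoranthene", "Benzo[a]pyrene",
      "Indeno[1,2,3-c,d]pyrene", "Dibenz[a,h]anthracene",
      "Benzo[g,h,i]perylene"
    ),
    abbreviation = c(
      "Naph", "Acy", "Ace", "Flu", "Phe", "Ant", "Flt", "Pyr",
      "BaA", "Chry", "BbF", "bkF", "BaP", "Ind(cd)P", "DahA", "BghiP"
    ),
    cas = c(
      "91-20-3", "208-96-8", "83-32-9", "86-73-7", "85-01-8", "120-12-7",
      "206-44-0", "129-00-0", "56-55-3", "218-01-9", "205-99-2",
      "207-08-9", "50-32-8", "193-39-5", "53-70-3", "191-24-2"
    ),
    ring_count = c(2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L,
                   6L, 5L, 6L),
    # Nisbet & LaGoy (1992) potency weights relative to BaP = 1
    tef = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.01, 0.001, 0.001,
            0.1, 0.01, 0.1, 0.1, 1, 0.1, 1, 0.01),
    in_pah4 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    # S/N >= 3 instrument LODs, ug/kg
    lod = c(6.81, 5.20, 5.68, 5.14, 6.35, 4.96, 5.13, 5.33,
            5.60, 5.54, 6.99, 6.75, 8.14, 5.72, 6.25, 7.70),
    stringsAsFactors = FALSE
  )
}

#' Abbreviations of the 16 priority PAHs in canonical order
#' @return Character vector of length 16.
#' @export
pah_analytes <- function() pah_registry()$abbreviation

#' Construct a TEF scheme
#'
#' A TEF scheme maps each analyte abbreviation to its toxic equivalency
#' factor and carries the scale divisor applied by [teq_bap()]
#' (the conventional form divides the TEF-weighted sum by 1000).
#'
#' @param tefs Named numeric vector of TEFs covering all 16 analytes;
#'   defaults to the Nisbet--LaGoy values from [pah_registry()].
#' @param scale_divisor Positive divisor applied to the TEF-weighted sum
#'   (default 1000). The unit of the resulting TEQ depends on this choice;
#'   it is recorded verbatim in every [teq_bap()] result.
#' @return An object of class `tef_scheme`.
#' @examples
#' sc <- tef_scheme()
#' sc$tefs[["BaP"]]  # 1
#' @export
tef_scheme <- function(tefs = NULL, scale_divisor = 1000) {
  reg <- pah_registry()
  if (is.null(tefs)) {
    tefs <- stats::setNames(reg$tef, reg$abbreviation)
  }
  if (!is.numeric(tefs) || is.null(names(tefs))) {
    stop("`tefs` must be a named numeric vector")
  }
  missing <- setdiff(reg$abbreviation, names(tefs))
  if (length(missing)) {
    stop("TEF scheme does not cover analyte(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(tefs)) || any(tefs <= 0)) {
    stop("all TEFs must be finite and > 0")
  }
  if (!is.numeric(scale_divisor) || length(scale_divisor) != 1 ||
      !is.finite(scale_divisor) || scale_divisor <= 0) {
    stop("`scale_divisor` must be a single positive number")
  }
  structure(
    list(tefs = tefs[reg$abbreviation], scale_divisor = scale_divisor),
    class = "tef_scheme"
  )
}

#' @export
print.tef_scheme <- function(x, ...) {
  cat("TEF scheme (", length(x$tefs), " analytes, divisor ",
      x$scale_divisor, ")\n", sep = "")
  print(x$tefs)
  invisible(x)
}

#' Default regulatory limits for PAHs in food
#'
#' BaP limit 5 ug/kg (China GB 2762-2017 cereal-product class) and PAH4
#' limit 35 ug/kg (EU Regulation 835/2011 class applied in screening).
#'
#' @return Named list with `bap_limit` and `pah4_limit` (ug/kg).
#' @export
regulatory_limits <- function() list(bap_limit = 5, pah4_limit = 35)
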