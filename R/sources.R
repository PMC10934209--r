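# Source apportionment via diagnostic isomer ratios.

#' Default diagnostic-ratio classification bands
#'
#' Conventional literature cut points for the three isomer-pair ratios.
#' Intervals are lower-closed: a ratio exactly on a cut point falls into
#' the band whose lower edge it is.
#'
#' * `Flt/(Flt+Pyr)`: < 0.4 petroleum; 0.4--0.5 fossil-fuel combustion;
#'   > 0.5 biomass/coal combustion.
#' * `Ant/(Ant+Phe)`: < 0.1 petroleum; >= 0.1 combustion.
#' * `BaA/(BaA+Chr)`: < 0.2 petroleum; 0.2--0.35 mixed; > 0.35 combustion.
#'
#' @return Nested list of cut points and labels, overridable in
#'   [classify_source()].
#' @export
ratio_thresholds <- function() {
  list(
    flt = list(cuts = c(0.4, 0.5),
               labels = c("petroleum", "fossil-fuel combustion",
                          "biomass/coal combustion")),
    ant = list(cuts = 0.1,
               labels = c("petroleum", "combustion")),
    baa = list(cuts = c(0.2, 0.35),
               labels = c("petroleum", "mixed", "combustion"))
  )
}

#' Diagnostic isomer ratios for one herb
#'
#' Computes `Flt/(Flt+Pyr)`, `Ant/(Ant+Phe)` and `BaA/(BaA+Chr)` from
#' policy-imputed concentrations. A ratio whose denominator is zero
#' (e.g. both isomers non-detected under the zero policy) is undefined
#' (`NA`), never 0/0.
#'
#' @inheritParams total_pahs
#' @return An object of class `ratio_profile` with `herb`, `flt_ratio`,
#'   `ant_ratio`, `baa_ratio`.
#' @examples
#' diagnostic_ratios(chm_pah_table(), "glycyrrhizae")
#' @export
diagnostic_ratios <- function(table, herb,
                              nd_policy = c("zero", "half_lod", "lod"),
                              lods = NULL) {
  i <- herb_row(table, herb)
  x <- impute_nd(table$values[i, ], table$detected[i, ], nd_policy, lods)
  ratio <- function(num, den) {
    tot <- x[[num]] + x[[den]]
    if (tot <= 0) NA_real_ else x[[num]] / tot
  }
  structure(
    list(herb = herb,
         flt_ratio = ratio("Flt", "Pyr"),
         ant_ratio = ratio("Ant", "Phe"),
         baa_ratio = ratio("BaA", "Chry")),
    class = "ratio_profile"
  )
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf(
    "ratio_profile [%s]: Flt/(Flt+Pyr)=%s  Ant/(Ant+Phe)=%s  BaA/(BaA+Chr)=%s\n",
    x$herb, format(x$flt_ratio, digits = 4),
    format(x$ant_ratio, digits = 4), format(x$baa_ratio, digits = 4)))
  invisible(x)
}

band_label <- function(value, cuts, labels) {
  if (is.na(value)) return("indeterminate")
  # lower-closed bands: value on a cut point belongs to the upper band
  labels[[findInterval(value, cuts) + 1L]]
}

#' Classify pollution sources from a ratio profile
#'
#' Pure function of the profile and the threshold bands: assigns each
#' defined ratio its source label and a composite description (the
#' conjunction of defined labels). Undefined ratios are labelled
#' `"indeterminate"`.
#'
#' @param profile A `ratio_profile` from [diagnostic_ratios()].
#' @param thresholds Band definitions, see [ratio_thresholds()].
#' @return List with `flt`, `ant`, `baa` labels and `composite`.
#' @export
classify_source <- function(profile, thresholds = ratio_thresholds()) {
  for (key in c("flt", "ant", "baa")) {
    th <- thresholds[[key]]
    if (is.null(th$cuts) || is.unsorted(th$cuts, strictly = TRUE) ||
        length(th$labels) != length(th$cuts) + 1) {
      stop("malformed thresholds for ratio '", key,
           "': cuts must be strictly increasing with one more label")
    }
  }
  labels <- list(
    flt = band_label(profile$flt_ratio, thresholds$flt$cuts,
                     thresholds$flt$labels),
    ant = band_label(profile$ant_ratio, thresholds$ant$cuts,
                     thresholds$ant$labels),
    baa = band_label(profile$baa_ratio, thresholds$baa$cuts,
                     thresholds$baa$labels)
  )
  defined <- unlist(labels)[unlist(labels) != "indeterminate"]
  labels$composite <- if (length(defined)) {
    paste(unique(defined), collapse = " + ")
  } else {
    "indeterminate"
  }
  labels
}

#' Crossplot coordinates for diagnostic-ratio panels
#'
#' Long-format plotting table: each herb contributes up to two points,
#' `(x = Flt/(Flt+Pyr), y = BaA/(BaA+Chr))` and
#' `(x = Flt/(Flt+Pyr), y = Ant/(Ant+Phe))`. Points with an undefined
#' coordinate are omitted (with a message naming the herb and panel).
#'
#' @param profiles List of `ratio_profile` objects.
#' @return data.frame with columns `herb`, `panel`, `x`, `y`.
#' @export
crossplot_coordinates <- function(profiles) {
  rows <- list()
  for (p in profiles) {
    for (panel in c("baa", "ant")) {
      y <- if (panel == "baa") p$baa_ratio else p$ant_ratio
      if (is.na(p$flt_ratio) || is.na(y)) {
        message("crossplot: omitting ", p$herb, " from panel '", panel,
                "' (undefined ratio)")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        herb = p$herb, panel = panel, x = p$flt_ratio, y = y,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(herb = character(), panel = character(),
                      x = numeric(), y = numeric()))
  }
  do.call(rbind, rows)
}
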