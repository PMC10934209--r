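# Censored herb x analyte concentration tables: construction, I/O, fixture.

#' Construct a censored concentration table
#'
#' The central data container: a herb x analyte matrix of mean
#' concentrations (ug/kg) together with a logical detection matrix.
#' Non-detects carry no stored numeric value (the `values` cell is `NA`);
#' every downstream operation imputes them explicitly via its `nd_policy`
#' argument, so censoring decisions are never baked into the container.
#'
#' @param values Numeric herb x analyte matrix, ug/kg; `NA` where not
#'   detected. Columns must be named with analyte abbreviations from
#'   [pah_analytes()]; rows with herb identifiers.
#' @param detected Logical matrix of the same shape; `FALSE` exactly where
#'   `values` is `NA`.
#' @param parts Character vector, one plant-part class per herb, each one
#'   of `"root_stem"`, `"flower"`, `"fruit_seed"`.
#' @param rsd Optional numeric matrix of relative standard deviations
#'   (fractions) with the same shape.
#' @return An object of class `concentration_table` with elements
#'   `values`, `detected`, `herbs`, `parts`, `analytes`, `rsd`.
#' @seealso [read_concentration_table()], [chm_pah_table()]
#' @export
concentration_table <- function(values, detected, parts, rsd = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  herbs <- rownames(values)
  analytes <- colnames(values)
  if (is.null(herbs) || is.null(analytes)) {
    stop("`values` must have herb rownames and analyte colnames")
  }
  if (anyDuplicated(herbs)) {
    stop("duplicate herb identifier: ",
         paste(unique(herbs[duplicated(herbs)]), collapse = ", "))
  }
  unknown <- setdiff(analytes, pah_analytes())
  if (length(unknown)) {
    stop("unknown analyte abbreviation: ", paste(unknown, collapse = ", "))
  }
  if (!is.matrix(detected) || !is.logical(detected) ||
      !identical(dim(detected), dim(values))) {
    stop("`detected` must be a logical matrix matching `values`")
  }
  if (!identical(is.na(values), !detected)) {
    stop("`values` must be NA exactly where `detected` is FALSE")
  }
  obs <- values[detected]
  if (length(obs) && (any(!is.finite(obs)) || any(obs < 0))) {
    bad <- which(detected & (!is.finite(values) | values < 0),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite or negative concentration at [%s, %s]",
                 herbs[bad[1]], analytes[bad[2]]))
  }
  part_classes <- c("root_stem", "flower", "fruit_seed")
  if (length(parts) != length(herbs) || !all(parts %in% part_classes)) {
    stop("`parts` must assign each herb one of: ",
         paste(part_classes, collapse = ", "))
  }
  if (!is.null(rsd) &&
      (!is.matrix(rsd) || !identical(dim(rsd), dim(values)))) {
    stop("`rsd` must be a matrix matching `values`")
  }
  structure(
    list(values = values, detected = detected, herbs = herbs,
         parts = stats::setNames(parts, herbs), analytes = analytes,
         rsd = rsd),
    class = "concentration_table"
  )
}

#' @export
print.concentration_table <- function(x, ...) {
  cat("concentration_table: ", length(x$herbs), " herbs x ",
      length(x$analytes), " analytes (ug/kg); ",
      sum(!x$detected), " non-detects\n", sep = "")
  shown <- ifelse(x$detected, format(x$values, trim = TRUE), "nd")
  dimnames(shown) <- dimnames(x$values)
  print(shown, quote = FALSE)
  invisible(x)
}

#' Read a censored concentration table from delimited text
#'
#' Expects a CSV with header `herb,part,<analyte abbreviations...>`; data
#' cells are non-negative numbers or the non-detect token. Row and column
#' order are preserved. Unknown analyte columns, duplicate herb ids and
#' negative concentrations are rejected with the offending coordinate.
#'
#' @param path Path to the CSV file.
#' @param nd_token Token marking a non-detect cell (default `"nd"`).
#' @param rsd_path Optional path to a companion CSV of the same layout
#'   holding per-cell relative standard deviations (fractions; nd cells
#'   may carry the nd token or be empty).
#' @return A [concentration_table()].
#' @export
read_concentration_table <- function(path, nd_token = "nd",
                                     rsd_path = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  need <- c("herb", "part")
  if (!all(need %in% names(raw)[1:2])) {
    stop("header must start with 'herb,part'")
  }
  analytes <- setdiff(names(raw), need)
  unknown <- setdiff(analytes, pah_analytes())
  if (length(unknown)) {
    stop("unknown analyte abbreviation in header: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(raw$herb)) {
    stop("duplicate herb id: ",
         paste(unique(raw$herb[duplicated(raw$herb)]), collapse = ", "))
  }
  parse_cells <- function(df, what) {
    cells <- as.matrix(df[analytes])
    dimnames(cells) <- list(df$herb, analytes)
    det <- cells != nd_token & nzchar(cells) & !is.na(cells)
    vals <- matrix(NA_real_, nrow(cells), ncol(cells),
                   dimnames = dimnames(cells))
    suppressWarnings(vals[det] <- as.numeric(cells[det]))
    bad <- det & is.na(vals)
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("unparseable %s cell at [%s, %s]: '%s'", what,
                   rownames(cells)[ij[1]], analytes[ij[2]],
                   cells[ij[1], ij[2]]))
    }
    neg <- det & vals < 0
    if (any(neg)) {
      ij <- which(neg, arr.ind = TRUE)[1, ]
      stop(sprintf("negative concentration at [%s, %s]",
                   rownames(cells)[ij[1]], analytes[ij[2]]))
    }
    list(values = vals, detected = det)
  }
  conc <- parse_cells(raw, "concentration")
  rsd <- NULL
  if (!is.null(rsd_path)) {
    rraw <- utils::read.csv(rsd_path, check.names = FALSE,
                            colClasses = "character", strip.white = TRUE)
    rsd <- parse_cells(rraw, "RSD")$values
    dimnames(rsd) <- dimnames(conc$values)
  }
  concentration_table(conc$values, conc$detected, parts = raw$part,
                      rsd = rsd)
}

#' Packaged survey of PAH residues in seven Chinese herbal medicines
#'
#' The packaged fixture: mean concentrations (ug/kg, n = 3 replicates,
#' RSD <= 15%) of the 16 priority PAHs in seven marketed Chinese herbal
#' medicines, with non-detects censored at the instrument LOD.
#'
#' @return A [concentration_table()] with 7 herbs x 16 analytes.
#' @examples
#' tab <- chm_pah_table()
#' detection_rate(tab, "honeysuckle")  # 0.625
#' @export
chm_pah_table <- function() {
  dir <- system.file("extdata", package = "pahrisk", mustWork = TRUE)
  read_concentration_table(
    file.path(dir, "chm_pah_concentrations.csv"),
    rsd_path = file.path(dir, "chm_pah_rsd.csv")
  )
}

#' Write an analysis product to disk
#'
#' Generic reporting writer. Data-frame-like products go to delimited
#' text (`format = "delimited"`); list-like products, including
#' [simulate_ilcr()] results with their seed and iteration provenance,
#' go to structured JSON (`format = "structured"`). Numbers are written
#' at full precision so a written table re-reads to equal values.
#'
#' @param x The product to write.
#' @param path Output path.
#' @param format `"delimited"` (CSV) or `"structured"` (JSON).
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = c("delimited", "structured")) {
  UseMethod("write_report")
}

#' @export
write_report.data.frame <- function(x, path,
                                    format = c("delimited", "structured")) {
  format <- match.arg(format)
  if (format == "delimited") {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.concentration_table <- function(x, path,
    format = c("delimited", "structured")) {
  format <- match.arg(format)
  cells <- ifelse(x$detected,
                  vapply(x$values, function(v) {
                    base::format(v, digits = 15, trim = TRUE)
                  }, ""),
                  "nd")
  dim(cells) <- dim(x$values)
  df <- data.frame(herb = x$herbs, part = unname(x$parts), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("herb", "part", x$analytes)
  if (format == "delimited") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.default <- function(x, path,
                                 format = c("delimited", "structured")) {
  format <- match.arg(format)
  if (format == "delimited" && is.list(x) &&
      all(vapply(x, function(e) is.atomic(e) || is.data.frame(e), TRUE))) {
    # flatten a simple list to two-column key,value rows
    flat <- unlist(x)
    df <- data.frame(key = names(flat), value = as.character(flat))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}
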