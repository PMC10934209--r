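# Shared fixture builders.

# Build a concentration_table from a named list herb -> named numeric
# vector over a subset of analytes (unlisted analytes are non-detects;
# NA cells are non-detects too).
toy_table <- function(rows, parts = NULL) {
  ana <- pah_analytes()
  values <- matrix(NA_real_, length(rows), length(ana),
                   dimnames = list(names(rows), ana))
  for (h in names(rows)) {
    values[h, names(rows[[h]])] <- rows[[h]]
  }
  if (is.null(parts)) parts <- rep("root_stem", length(rows))
  concentration_table(values, !is.na(values), parts = parts)
}

# Write a table's CSV representation to a temp file and return the path.
write_temp_table <- function(tab) {
  path <- withr_local_tempfile()
  write_report(tab, path, "delimited")
  path
}

# Minimal local tempfile helper (cleaned up by R's tempdir lifecycle).
withr_local_tempfile <- function() tempfile(fileext = ".csv")

point_factors <- function(group = "adult", dr = 1, csf = 1, ef = 365,
                          ed = 1, bw = 1, at = 365) {
  exposure_factors(group, dr = dr, csf = csf, ef = ef, ed = ed,
                   bw = bw, at = at)
}
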