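# Screening operations, checked against the packaged survey and against
# independent brute-force oracles.

tab <- chm_pah_table()

test_that("detection rates reproduce the survey's contamination rates", {
  expected <- c(glycyrrhizae = 11, honeysuckle = 10, coix_lacryma = 6,
                ginseng = 6, lotus_seed = 8, sterculia_lychnophora = 9,
                lycium_chinense = 6) / 16
  for (h in names(expected)) {
    expect_equal(detection_rate(tab, h), unname(expected[h]), info = h)
  }
  expect_error(detection_rate(tab, "nope"), "unknown herb")
})

test_that("detection rate is zero for an all-nd herb", {
  t0 <- toy_table(list(empty = numeric(0)))
  expect_equal(detection_rate(t0, "empty"), 0)
})

test_that("total_pahs under the zero policy reproduces printed totals", {
  expect_equal(total_pahs(tab, "honeysuckle"), 1414.087)
  expect_equal(total_pahs(tab, "lycium_chinense"), 176.906)
  expect_equal(total_pahs(tab, "coix_lacryma"), 326.448)
  t0 <- toy_table(list(empty = numeric(0)))
  expect_equal(total_pahs(t0, "empty"), 0)
})

test_that("total_pahs equals the direct sum of detected cells (property)", {
  for (h in tab$herbs) {
    i <- match(h, tab$herbs)
    oracle <- sum(tab$values[i, tab$detected[i, ]])
    expect_equal(total_pahs(tab, h, "zero"), oracle, info = h)
  }
})

test_that("LOD-based nd policies impute the registry LODs", {
  t1 <- toy_table(list(h = c(Naph = 10)))
  lods <- setNames(pah_registry()$lod, pah_analytes())
  expect_equal(total_pahs(t1, "h", "lod"), 10 + sum(lods) - lods[["Naph"]])
  expect_equal(total_pahs(t1, "h", "half_lod"),
               10 + (sum(lods) - lods[["Naph"]]) / 2)
  # custom LODs must cover the censored analytes
  expect_error(total_pahs(t1, "h", "lod", lods = c(Naph = 1)),
               "requires LODs")
})

test_that("analyte extremes use detected cells only", {
  phe <- analyte_extremes(tab, "Phe")
  expect_equal(phe$min, 47.045)
  expect_equal(phe$max, 168.640)
  expect_equal(phe$n_detected, 7)
  bbf <- analyte_extremes(tab, "BbF")
  expect_equal(bbf$max, 941.504)
  expect_equal(bbf$n_detected, 3)
  bghip <- analyte_extremes(tab, "BghiP")
  expect_equal(bghip$n_detected, 0)
  expect_true(is.na(bghip$min) && is.na(bghip$max))
  expect_error(analyte_extremes(tab, "XYZ"), "unknown analyte")
})

test_that("ring-class shares match hand-summed values and normalize", {
  sh <- ring_class_shares(tab, "coix_lacryma", "concentration")
  hand_23 <- (21.666 + 22.913 + 24.754 + 82.388 + 147.707) / 326.448
  expect_equal(unname(sh$shares[["rings_2_3"]]), hand_23, tolerance = 1e-12)
  expect_equal(unname(sh$shares[["rings_4"]]), 27.020 / 326.448,
               tolerance = 1e-12)
  expect_equal(unname(sh$shares[["rings_5_6"]]), 0)
  for (h in tab$herbs) {
    for (basis in c("concentration", "teq")) {
      s <- ring_class_shares(tab, h, basis)
      expect_equal(sum(s$shares), 1, info = paste(h, basis))
    }
  }
})

test_that("single-analyte table gives shares (1, 0, 0) on both bases", {
  t1 <- toy_table(list(h = c(Naph = 5)))
  for (basis in c("concentration", "teq")) {
    s <- ring_class_shares(t1, "h", basis)
    expect_equal(unname(s$shares), c(1, 0, 0))
  }
})

test_that("all-ones TEF scheme makes TEQ-basis shares equal concentration
           shares, and shares are column-order invariant (property)", {
  ones <- tef_scheme(setNames(rep(1, 16), pah_analytes()))
  for (h in tab$herbs) {
    a <- ring_class_shares(tab, h, "concentration")$shares
    b <- ring_class_shares(tab, h, "teq", ones)$shares
    expect_equal(a, b, info = h)
  }
  perm <- sample(16)
  shuffled <- concentration_table(tab$values[, perm],
                                  tab$detected[, perm],
                                  parts = unname(tab$parts))
  for (h in tab$herbs) {
    expect_equal(ring_class_shares(shuffled, h, "teq")$shares,
                 ring_class_shares(tab, h, "teq")$shares, info = h)
  }
})

test_that("zero-total herb has undefined, flagged shares", {
  t0 <- toy_table(list(empty = numeric(0)))
  s <- ring_class_shares(t0, "empty")
  expect_false(s$defined)
  expect_true(all(is.na(s$shares)))
})

test_that("regulatory flags reproduce the survey's exceedances", {
  hs <- regulatory_flags(tab, "honeysuckle")
  expect_true(hs$bap_exceeds)
  expect_true(hs$pah4_exceeds)
  expect_equal(hs$pah4_sum, 76.563 + 941.504 + 39.928)
  cx <- regulatory_flags(tab, "coix_lacryma")
  expect_false(cx$bap_exceeds)
  expect_false(cx$pah4_exceeds)
  # boundary convention is strict: exactly at the limit does not exceed
  tb <- toy_table(list(h = c(BaP = 5)))
  expect_false(regulatory_flags(tb, "h")$bap_exceeds)
})

test_that("detection chi-squared matches a textbook recomputation", {
  res <- detection_chi2(tab)
  expect_equal(res$df, 6)
  # independent oracle: direct sum((O-E)^2/E) on the 7x2 counts table
  counts <- res$counts
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  oracle <- sum((counts - E)^2 / E)
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(oracle, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("chi-squared degenerate and hand-computed cases", {
  same <- toy_table(list(h1 = c(Naph = 1, Acy = 2),
                         h2 = c(Naph = 3, Acy = 4)))
  res <- detection_chi2(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  split <- toy_table(c(list(h1 = setNames(rep(1, 16), pah_analytes())),
                       list(h2 = numeric(0))))
  expect_equal(detection_chi2(split)$statistic, 32)
  expect_error(detection_chi2(toy_table(list(h = c(Naph = 1)))),
               "at least 2 herbs")
})

test_that("detection rate is invariant under monotone rescaling (property)", {
  scaled <- concentration_table(tab$values * 1000, tab$detected,
                                parts = unname(tab$parts))
  for (h in tab$herbs) {
    expect_equal(detection_rate(scaled, h), detection_rate(tab, h))
  }
})

test_that("screen_table assembles a coherent report and writes it", {
  rep <- screen_table(tab)
  expect_equal(nrow(rep$herbs), 7)
  expect_equal(nrow(rep$analytes), 16)
  expect_equal(rep$herbs$total[rep$herbs$herb == "honeysuckle"], 1414.087)
  expect_true(all(rep$herbs$detection_rate >= 0 &
                  rep$herbs$detection_rate <= 1))
  path <- tempfile(fileext = ".csv")
  write_report(rep, path, "delimited")
  back <- utils::read.csv(path)
  expect_equal(back$total, rep$herbs$total)
})
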