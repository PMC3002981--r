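reg <- default_registry()

test_that("integration handles degenerate traces by flagging, not failing", {
  tt <- seq(1, 4, by = 0.0133)
  zero <- data.frame(time = tt, intensity = rep(0, length(tt)))
  m <- integrate_peak(zero, expected_rt = 1.9)
  expect_true(has_flag <- grepl("not_detected", m$flags))
  expect_equal(m$area, 0)

  m2 <- integrate_peak(data.frame(time = numeric(0), intensity = numeric(0)),
                       expected_rt = 1.9)
  expect_match(m2$flags, "not_detected")

  bad <- data.frame(time = c(1, 3, 2), intensity = c(0, 1, 0))
  expect_error(integrate_peak(bad, 2), "strictly increasing")
})

test_that("noiseless Gaussian peaks are recovered within 1% of true area", {
  for (area in c(500, 2e4, 1.5e5)) {
    tt <- seq(1, 4, by = 0.0133)
    tr <- data.frame(time = tt, intensity = area * dnorm(tt, 1.9, 0.05))
    m <- integrate_peak(tr, expected_rt = 1.9)
    expect_lt(abs(m$area - area) / area, 0.01)
    expect_equal(m$apex_rt, tt[which.max(tr$intensity)])
  }
})

test_that("integration is linear: scaling intensities scales area", {
  tt <- seq(4, 7, by = 0.03)
  tr <- data.frame(time = tt, intensity = 1000 * dnorm(tt, 5.7, 0.05))
  m1 <- integrate_peak(tr, 5.7)
  tr3 <- tr; tr3$intensity <- 3 * tr$intensity
  m3 <- integrate_peak(tr3, 5.7)
  expect_equal(m3$area, 3 * m1$area, tolerance = 1e-12)
  expect_equal(m3$apex_rt, m1$apex_rt)
})

test_that("quantify_sample measures every transition and flags tentatives", {
  spec <- simulation_spec(
    c(default_abundances(reg), "15N5-dA" = 5e4), seed = 10)
  cs <- simulate_chromatograms(spec, reg)
  m <- quantify_sample(cs, reg)
  expect_equal(nrow(m), 25L)
  expect_equal(sum(m$role == "internal_standard"), 1L)
  expect_match(m$flags[m$short_name == "ncm5Um"], "tentative")
})

test_that("a missing internal-standard peak is a hard error", {
  spec <- simulation_spec(default_abundances(reg), seed = 11)  # no IS area
  cs <- simulate_chromatograms(spec, reg)
  expect_error(quantify_sample(cs, reg), "internal-standard peak not detected")
})

test_that("normalization follows area / IS area / tRNA mass", {
  meas <- data.frame(
    short_name = c("m5C", "15N5-dA"),
    role = c("analyte", "internal_standard"),
    apex_rt = c(3.3, 14.4), area = c(1200, 600), height = c(1, 1),
    baseline = 0, noise = 0, flags = "", stringsAsFactors = FALSE)
  v <- normalize_sample(meas, list(trna_mass = 6, is_amount = 6))
  expect_equal(unname(v["m5C"]), 1200 / 600 / 6)

  meas2 <- meas; meas2$area[2] <- 1200
  v2 <- normalize_sample(meas2, list(trna_mass = 6, is_amount = 6))
  expect_equal(unname(v2["m5C"]), unname(v["m5C"]) / 2)

  # uniform intensity scaling cancels in the ratio
  meas3 <- meas; meas3$area <- meas$area * 7.3
  v3 <- normalize_sample(meas3, list(trna_mass = 6, is_amount = 6))
  expect_equal(v3, v)

  expect_error(normalize_sample(meas, list(is_amount = 6)), "trna_mass")
})

test_that("end-to-end response is linear over 0.1x-2x abundance", {
  scales <- c(0.1, 0.25, 0.5, 1, 1.5, 2)
  ab <- default_abundances(reg)
  vals <- vapply(scales, function(s) {
    spec <- simulation_spec(c(ab * s, "15N5-dA" = 5e4), seed = 21)
    cs <- simulate_chromatograms(spec, reg,
                                 metadata = list(trna_mass = 6, is_amount = 6,
                                                 group = "lin"))
    m <- quantify_sample(cs, reg)
    v <- normalize_sample(m, cs$metadata)
    unname(v["m5C"])
  }, numeric(1))
  expect_gt(cor(vals, scales)^2, 0.999)
})

test_that("internal-standard normalization removes injection-scale variance", {
  d <- experiment_design(injection_cv = 0.15, biological_cv = 0,
                         rt_jitter_sd = 0, baseline_level = 0,
                         baseline_noise_sd = 0, n_replicates = 6, seed = 31)
  ex <- simulate_experiment(d)
  ctrl <- ex$samples[grep("^control", names(ex$samples))]
  raw <- vapply(ctrl, function(cs)
    quantify_sample(cs, reg)$area[1], numeric(1))
  tab <- intensity_table(ctrl, reg)
  norm <- tab[[intensity_columns(tab)[1]]]
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(norm), cv(raw))
})

test_that("isobaric m5C and m3C are separated chromatographically", {
  # only m3C present: the m5C transition must come up empty, and vice versa
  for (present in c("m3C", "m5C")) {
    absent <- setdiff(c("m3C", "m5C"), present)
    spec <- simulation_spec(
      setNames(c(2e4, 5e4), c(present, "15N5-dA")), seed = 12)
    cs <- simulate_chromatograms(spec, reg)
    m <- quantify_sample(cs, reg, rt_tolerance = 0.5)
    expect_gt(m$area[m$short_name == present], 1e4)
    expect_match(m$flags[m$short_name == absent], "not_detected")
  }
})

test_that("intensity summary ranks analytes and bins them into decade tiers", {
  tab <- data.frame(sample_id = "s1", group = "g",
                    A = 1000, B = 900, C = 50, D = 5, E = 0.4,
                    check.names = FALSE)
  class(tab) <- c("intensity_table", "data.frame")
  s <- summarize_intensities(tab)
  expect_equal(s$short_name, c("A", "B", "C", "D", "E"))
  # brute-force decade binning oracle
  mx <- 1000
  oracle <- ifelse(c(1000, 900, 50, 5, 0.4) >= mx / 10, "high",
                   ifelse(c(1000, 900, 50, 5, 0.4) >= mx / 100,
                          "medium", "low"))
  expect_equal(s$tier, oracle)

  one <- tab[, c("sample_id", "group", "A")]
  class(one) <- c("intensity_table", "data.frame")
  s1 <- summarize_intensities(one)
  expect_equal(s1$rank, 1L)
  expect_equal(s1$tier, "high")

  tie <- data.frame(sample_id = "s1", group = "g", X = 10, Y = 10,
                    check.names = FALSE)
  class(tie) <- c("intensity_table", "data.frame")
  expect_equal(summarize_intensities(tie)$short_name, c("X", "Y"))
})
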