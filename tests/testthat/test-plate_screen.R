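make_plate_files <- function(raw, desc) {
  rp <- tempfile(fileext = ".csv"); dp <- tempfile(fileext = ".csv")
  write.csv(raw, rp, row.names = FALSE)
  write.csv(desc, dp, row.names = FALSE)
  list(raw = rp, desc = dp)
}

small_descriptor <- function(wells, variants = "V1") {
  data.frame(well = wells, variant = rep_len(variants, length(wells)),
             metal = "Ni", conc_uM = 0, edta = 0,
             replicate = seq_along(wells), blank = 0)
}

test_that("raw and descriptor CSVs join into traces; mismatches are caught", {
  raw <- data.frame(time_s = c(0, 60, 120, 180, 240),
                    A01 = 1:5, A02 = 2:6, A03 = 3:7, A04 = 4:8)
  desc <- small_descriptor(c("A01", "A02", "A03", "A04"))
  f <- make_plate_files(raw, desc)
  traces <- read_plate_csvs(f$raw, f$desc)
  expect_length(traces, 4)
  expect_equal(traces[[2]]$signal, 2:6)
  expect_equal(traces[[2]]$well$well, "A02")

  # descriptor referencing a missing well -> error naming it
  desc_bad <- rbind(desc, data.frame(well = "B07", variant = "V1",
                                     metal = "Ni", conc_uM = 0, edta = 0,
                                     replicate = 5, blank = 0))
  fb <- make_plate_files(raw, desc_bad)
  expect_error(read_plate_csvs(fb$raw, fb$desc), "B07")

  # duplicate well id -> error
  fd <- make_plate_files(raw, rbind(desc, desc[1, ]))
  expect_error(read_plate_csvs(fd$raw, fd$desc), "duplicate")

  # undescribed raw well -> warning + skip
  fs <- make_plate_files(raw, desc[1:3, ])
  expect_warning(tr <- read_plate_csvs(fs$raw, fs$desc), "A04")
  expect_length(tr, 3)
})

test_that("simulated plates round-trip through the CSV reader", {
  spec <- plate_sim_spec(variants = c(X = "inhibited", Y = "unresponsive"),
                         n_blanks = 2, seed = 4)
  sim <- simulate_plate(spec, dir = tempfile())
  traces <- read_plate_csvs(sim$raw_csv, sim$descriptor_csv)
  expect_length(traces, nrow(sim$descriptor))
  for (k in c(1, 5, length(traces))) {
    w <- traces[[k]]$well$well
    expect_equal(traces[[k]]$signal, sim$raw[[w]])
    expect_equal(traces[[k]]$times, sim$raw$time_s)
  }
})

test_that("sliding-window regression finds the maximum slope", {
  # exactly linear: slope recovered anywhere, earliest window reported
  t <- seq(0, 540, by = 60)
  r <- sliding_window_max_slope(t, 0.01 * t, window_size = 5)
  expect_equal(r$max_slope, 0.01, tolerance = 1e-12)
  expect_equal(r$window_start_time, 0)

  # quadratic, unit spacing: OLS slope of t^2 over {5..9} is 2 * mean(t) = 14
  tq <- 0:9
  rq <- sliding_window_max_slope(tq, tq^2, window_size = 5,
                                 saturation_ceiling = Inf)
  expect_equal(rq$max_slope, 14.0, tolerance = 1e-12)
  expect_equal(rq$window_start_time, 5)

  expect_error(sliding_window_max_slope(0:3, (0:3)^2, window_size = 5),
               "too short")
})

test_that("concave initial-rate traces give the earliest window and saturated tails are trimmed", {
  t <- seq(0, 1900, by = 100)
  conc <- 3 * (1 - exp(-t / 500))  # monotone increasing, concave
  r <- sliding_window_max_slope(t, conc, saturation_ceiling = Inf)
  expect_equal(r$window_index, 1)

  # a plateau clamped at the detector ceiling must not mask the kinetics
  sat <- pmin(0.004 * t, 3.6)
  rs <- sliding_window_max_slope(t, sat, saturation_ceiling = 3.5)
  expect_equal(rs$max_slope, 0.004, tolerance = 1e-12)

  # missing values are dropped pairwise before windowing
  y <- 0.01 * t; y[4] <- NA
  rn <- sliding_window_max_slope(t, y, saturation_ceiling = Inf)
  expect_equal(rn$max_slope, 0.01, tolerance = 1e-12)
})

test_that("replicate aggregation uses mean and sample standard deviation", {
  rates <- data.frame(variant = "V", metal = "Ni", conc_uM = 0, edta = 0,
                      replicate = 1:3, blank = 0,
                      slope = c(1, 2, 3) / 60, well = c("A1", "A2", "A3"))
  agg <- aggregate_condition(rates)
  expect_equal(agg$mean_slope_per_min, 2.0)
  expect_equal(agg$sd_slope * 60, 1.0)
  expect_equal(agg$n_replicates, 3)

  same <- rates; same$slope <- 1 / 60
  expect_equal(aggregate_condition(same)$sd_slope, 0)

  single <- rates[1, ]
  a1 <- aggregate_condition(single)
  expect_equal(a1$sd_slope, 0)
  expect_equal(a1$n_replicates, 1)
})

test_that("dose-response classification follows the 50%/150% apo-activity rules", {
  mk_agg <- function(rates, conc = c(0, 10, 100)) {
    data.frame(variant = "V", metal = "Ni", conc_uM = conc, edta = 0,
               mean_slope = rates, sd_slope = 0, n_replicates = 3)
  }
  inh <- classify_dose_response(mk_agg(c(1.0, 0.8, 0.4)), "V", "Ni")
  expect_equal(inh$classification, "inhibited")
  expect_equal(inh$fold_change_low_high, 2.5)
  expect_equal(inh$normalized[1], 1.0)

  act <- classify_dose_response(mk_agg(c(1.0, 1.2, 1.6)), "V", "Ni")
  expect_equal(act$classification, "activated")

  flat <- classify_dose_response(mk_agg(c(1.0, 1.0, 1.0)), "V", "Ni")
  expect_equal(flat$classification, "unresponsive")
  expect_equal(flat$fold_change_low_high, 1.0)

  # classification is invariant to uniform rescaling of the variant's rates
  for (f in c(0.01, 7, 1000)) {
    expect_equal(classify_dose_response(mk_agg(f * c(1, 0.8, 0.4)),
                                        "V", "Ni")$classification,
                 "inhibited")
  }

  # apo rate below the floor (5% of the reference) -> inactive
  dead <- classify_dose_response(mk_agg(c(0.02, 0.02, 0.02)), "V", "Ni",
                                 reference_rate = 1.0)
  expect_equal(dead$classification, "inactive")

  expect_error(classify_dose_response(mk_agg(c(1, 1), conc = c(1, 10)),
                                      "V", "Ni"), "apo")
})

test_that("EDTA recovery fraction spans full reversal to Fe(II)-like irreversibility", {
  expect_equal(reversibility_recovery(0.05, 1.0, 1.0)$recovery, 1.0)
  expect_equal(reversibility_recovery(0.05, 0.05, 1.0)$recovery, 0.0)
  expect_equal(reversibility_recovery(0.2, 0.6, 1.0)$recovery, 0.5)

  # non-responder: apo ~ metal rate -> undefined with flag
  nr <- reversibility_recovery(1.0, 1.0, 1.0 + 1e-9)
  expect_false(nr$defined)
  expect_true(is.na(nr$recovery))
})

test_that("the full pipeline recovers planted phenotypes on a noiseless plate", {
  spec <- plate_sim_spec(variants = c(WT = "unresponsive", I1 = "inhibited",
                                      A1 = "activated", D1 = "inactive"),
                         noise_sd = 0, seed = 2)
  sim <- simulate_plate(spec, dir = tempfile())
  rates <- plate_rates(read_plate_csvs(sim$raw_csv, sim$descriptor_csv))
  cls <- classify_plate(aggregate_condition(rates),
                        reference_variant = "WT")
  truth <- unique(sim$truth[sim$truth$blank == 0,
                            c("variant", "phenotype")])
  m <- merge(cls, truth)
  expect_equal(m$classification, m$phenotype)
})

test_that("blank correction requires blanks and removes a common offset", {
  spec <- plate_sim_spec(variants = c(WT = "unresponsive"), n_blanks = 4,
                         noise_sd = 0, seed = 6)
  sim <- simulate_plate(spec, dir = tempfile())
  traces <- read_plate_csvs(sim$raw_csv, sim$descriptor_csv)
  plain <- plate_rates(traces)
  corr <- plate_rates(traces, blank_correct = TRUE)
  # noiseless blanks have zero slope, so correction changes nothing
  expect_equal(corr$slope, plain$slope, tolerance = 1e-12)

  spec0 <- plate_sim_spec(variants = c(WT = "unresponsive"), n_blanks = 0,
                          seed = 6)
  sim0 <- simulate_plate(spec0, dir = tempfile())
  tr0 <- read_plate_csvs(sim0$raw_csv, sim0$descriptor_csv)
  expect_error(plate_rates(tr0, blank_correct = TRUE), "blank")
})
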