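# Protocols, synthetic trace sets, fixtures and trace I/O.

test_that("standard protocols match the published step families", {
  p <- standard_protocol()
  expect_equal(p$v_hold, -60)
  expect_length(p$step_voltages, 10)
  expect_equal(p$step_voltages[1], -60)
  expect_equal(p$step_voltages[10], -150)
  expect_equal(unique(diff(p$step_voltages)), -10)
  expect_equal(p$v_post, -60)
  rec <- standard_protocol("recorded")
  expect_length(rec$step_voltages, 11)
  expect_equal(rec$step_voltages[11], -160)
  expect_warning(clamp_protocol(t_step = 500), "steady state")
  expect_error(clamp_protocol(step_voltages = numeric(0)), "non-empty")
})

test_that("benchmark fixture tables carry the published parameter values", {
  p <- table1_params()
  slow <- p[p$component == "slow", ]
  fast <- p[p$component == "fast", ]
  expect_equal(unlist(slow[, -1]),
    c(Vh = -100, k = -6, M = -80, S = 80, A = 1000, B = 60, G = 3)
  )
  expect_equal(unlist(fast[, -1]),
    c(Vh = -130, k = -9, M = -80, S = 40, A = 250, B = 40, G = 4)
  )
})

test_that("recorded-cell fixture exposes both width assignments", {
  a <- fig3_params("results_text")
  b <- fig3_params("fig3c_legend")
  expect_equal(a$Vh, c(-108.6, -130.6))
  expect_equal(a$k, c(-9.6, -5.1))
  # peak time constants are preserved under either assignment
  expect_equal(a$A + a$B, c(995, 244))
  expect_equal(b$A + b$B, c(995, 244))
  expect_equal(sort(a$S), sort(b$S))
  expect_false(isTRUE(all.equal(a$S, b$S)))
})

test_that("synthesis is reproducible, unbiased, and exact when noiseless", {
  p <- table1_params()
  proto <- coarse_protocol(sample_interval = 10)
  clean <- synthesize_traces(p, proto, noise_sd = 0, seed = 1)
  # noiseless synthesis equals the closed form
  ref <- ih_step_current(seq(0, proto$t_step, 10), p, Vps = -60, Vs = -150)
  expect_equal(
    clean$current[clean$Vs == -150 & clean$segment == "activation"],
    ref$current
  )
  # determinism under a fixed seed
  n1 <- synthesize_traces(p, proto, noise_sd = 10, seed = 7)
  n2 <- synthesize_traces(p, proto, noise_sd = 10, seed = 7)
  expect_identical(n1$current, n2$current)
  expect_false(identical(
    n1$current,
    synthesize_traces(p, proto, noise_sd = 10, seed = 8)$current
  ))
  # noise SD close to nominal and mean close to the clean trace
  resid <- n1$current - clean$current
  expect_equal(sd(resid), 10, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 0.5)
  expect_error(synthesize_traces(p, proto, noise_sd = -1), "non-negative")
})

test_that("many-realization mean converges to the noiseless trace", {
  p <- table1_params()
  proto <- clamp_protocol(step_voltages = -150, t_step = 4000, sample_interval = 20)
  clean <- synthesize_traces(p, proto, noise_sd = 0, seed = 1)$current
  acc <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    acc <- acc + synthesize_traces(p, proto, noise_sd = 10, seed = s)$current
  }
  avg <- acc / n_rep
  # pointwise SE is 10/sqrt(40) ~ 1.6 pA
  expect_lt(max(abs(avg - clean)), 6 * 10 / sqrt(n_rep))
})

test_that("trace sets round-trip through CSV + JSON sidecar", {
  p <- table1_params()
  proto <- coarse_protocol(sample_interval = 50)
  ts <- synthesize_traces(p, proto, noise_sd = 10, seed = 3, segment = "both")
  path <- file.path(withr::local_tempdir(), "traces.csv")
  write_traces(ts, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_traces(path)
  expect_equal(back$current, ts$current)
  expect_equal(back$t, ts$t)
  expect_equal(back$Vs, ts$Vs)
  expect_equal(traces_protocol(back)$step_voltages, proto$step_voltages)
  expect_equal(attr(back, "noise_sd"), 10)
  expect_equal(traces_eh(back), -36)
  # missing sidecar is an explicit error
  file.remove(paste0(path, ".json"))
  expect_error(read_traces(path), "sidecar")
})

test_that("malformed trace files are rejected", {
  p <- table1_params()
  proto <- coarse_protocol(sample_interval = 100)
  ts <- synthesize_traces(p, proto, noise_sd = 0, seed = 1)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "traces.csv")
  write_traces(ts, path)
  # tamper: drop a trace column so counts disagree with the sidecar
  df <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(df[, -2], path)
  expect_error(read_traces(path), "step_voltages")
})

test_that("the shipped synthetic example trace set loads", {
  path <- system.file("extdata", "synthetic_two_component_traces.csv",
    package = "ihtrace"
  )
  ts <- read_traces(path)
  expect_s3_class(ts, "ih_traces")
  expect_length(traces_protocol(ts)$step_voltages, 10)
  expect_equal(attr(ts, "provenance"), "synthetic")
  expect_equal(dplyr::n_distinct(ts$Vs), 10)
})
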