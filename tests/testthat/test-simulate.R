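test_that("half-sine kernel matches its closed form", {
  times <- seq(-300, 800, by = 1000 / 512)
  k <- make_erp_kernel(1, 200, 600, 512, times)
  # closed form evaluated independently of the implementation grid
  expect_equal(k$waveform[which.min(abs(times - 400))],
               sin(pi * (times[which.min(abs(times - 400))] - 200) / 400),
               tolerance = 1e-12)
  expect_equal(k$waveform[which.min(abs(times - 300))],
               sin(pi * (times[which.min(abs(times - 300))] - 200) / 400),
               tolerance = 1e-12)
  expect_lt(abs(k$waveform[which.min(abs(times - 300))] - sin(pi / 4)), 0.01)
  expect_true(all(k$waveform[times < 200 | times > 600] == 0))
  expect_lte(max(k$waveform), 1)
  expect_gt(max(k$waveform), 0.9999)
  # single interior maximum at the midpoint region
  expect_equal(times[which.max(k$waveform)], 400, tolerance = 2)
})

test_that("zero-amplitude kernel is identically zero", {
  k <- make_erp_kernel(0, 200, 600, 512)
  expect_true(all(k$waveform == 0))
})

test_that("kernel window outside the epoch grid errors", {
  expect_error(make_erp_kernel(1, 200, 900, 512,
                               seq(-300, 800, by = 1000 / 512)),
               "outside the epoch")
  expect_error(make_erp_kernel(1, 600, 200, 512), "exceed")
})

phi_coef <- function(a, b) {
  n11 <- as.numeric(sum(a & b)); n00 <- as.numeric(sum(!a & !b))
  n10 <- as.numeric(sum(a & !b)); n01 <- as.numeric(sum(!a & b))
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

test_that("presence draws realize the injected correlation structure", {
  pos <- draw_presence("positive", 512, seed = 4)
  expect_equal(sum(pos$erp_present_h & pos$erp_present_v), 256)
  expect_equal(sum(!pos$erp_present_h & !pos$erp_present_v), 256)
  expect_equal(phi_coef(pos$erp_present_h, pos$erp_present_v), 1)

  neg <- draw_presence("negative", 512, seed = 4)
  expect_equal(sum(neg$erp_present_h & neg$erp_present_v), 0)
  expect_equal(sum(neg$erp_present_h), 256)
  expect_equal(sum(neg$erp_present_v), 256)
  expect_equal(phi_coef(neg$erp_present_h, neg$erp_present_v), -1)

  nul <- draw_presence("null", 100000, seed = 4)
  expect_lt(abs(phi_coef(nul$erp_present_h, nul$erp_present_v)), 0.02)

  expect_error(draw_presence("positive", 511), "even")
  expect_error(draw_presence("sideways", 512), "unknown")
})

test_that("noise respects the configured SNR bound exactly", {
  cfg <- small_config(snr = 4, seed = 11)
  ep <- generate_dataset(cfg)
  # non-signal channels are pure noise, bounded by amplitude / snr
  noise_ch <- setdiff(seq_len(cfg$n_channels), cfg$split$signal_channels)
  mx <- max(abs(ep$data[, noise_ch, ]))
  expect_lte(mx, cfg$amplitude / cfg$snr)
  expect_gt(mx, 0.95 * cfg$amplitude / cfg$snr) # bound is tight
  expect_equal(cfg$amplitude / cfg$noise_amplitude, cfg$snr)
})

test_that("noise-free contra-minus-ipsi reproduces twice the kernel", {
  cfg <- noiseless_config(mode = "positive", seed = 2)
  ep <- generate_dataset(cfg)
  times <- ep$times_ms
  k <- make_erp_kernel(1, 200, 600, cfg$sample_rate, times)
  pres <- ep$trials$erp_present_h
  left <- pres & ep$trials$h_class == "left"
  contra <- apply(ep$data[left, cfg$split$h_contra, , drop = FALSE],
                  3, mean)
  ipsi <- apply(ep$data[left, cfg$split$h_ipsi, , drop = FALSE], 3, mean)
  expect_equal(contra - ipsi, 2 * k$waveform, tolerance = 1e-12)
})

test_that("negative mode never puts both patterns on one trial", {
  cfg <- noiseless_config(mode = "negative", seed = 5)
  ep <- generate_dataset(cfg)
  ph <- numeric(cfg$n_channels)
  ph[cfg$split$h_contra] <- 1; ph[cfg$split$h_ipsi] <- -1
  pv <- numeric(cfg$n_channels)
  pv[cfg$split$v_contra] <- 1; pv[cfg$split$v_ipsi] <- -1
  energy <- function(pat) apply(ep$data, 1, function(tr)
    sum((crossprod(tr, pat))^2))
  eh <- energy(ph); ev <- energy(pv)
  expect_true(all(pmin(eh, ev) < 1e-20))
  expect_true(all(pmax(eh, ev) > 1e-6)) # every trial carries exactly one
})

test_that("the two spatial patterns are orthogonal channel vectors", {
  split <- make_channel_split()
  ph <- numeric(64); ph[split$h_contra] <- 1; ph[split$h_ipsi] <- -1
  pv <- numeric(64); pv[split$v_contra] <- 1; pv[split$v_ipsi] <- -1
  expect_equal(sum(ph * pv), 0)
  expect_equal(length(intersect(split$h_contra, split$v_contra)),
               length(intersect(split$h_contra, split$v_ipsi)))
})

test_that("generation is bit-reproducible and seed-sensitive", {
  cfg <- small_config(seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$trials, b$trials)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(generate_dataset(cfg2)$data, a$data))
})

test_that("cohorts derive distinct, reproducible child seeds", {
  cfg <- small_config(n_trials = 16, n_channels = 8, seed = 1)
  co1 <- generate_cohort(cfg, 3, seed = 1)
  co2 <- generate_cohort(cfg, 3, seed = 1)
  expect_identical(co1[[2]]$data, co2[[2]]$data)
  expect_false(identical(co1[[1]]$data, co1[[2]]$data))
  expect_false(identical(generate_cohort(cfg, 2, seed = 2)[[1]]$data,
                         co1[[1]]$data))
})

test_that("class labels are balanced and metadata aligned", {
  cfg <- small_config(seed = 3)
  ep <- generate_dataset(cfg)
  expect_equal(sum(ep$trials$h_class == "left"), cfg$n_trials / 2)
  expect_equal(sum(ep$trials$v_class == "top"), cfg$n_trials / 2)
  expect_equal(nrow(ep$trials), dim(ep$data)[1])
  expect_equal(diff(ep$times_ms)[1], 1000 / cfg$sample_rate)
})

test_that("epochs round-trip through serialization bit-exactly", {
  ep <- generate_dataset(small_config(n_trials = 8, n_channels = 8,
                                      seed = 2))
  path <- tempfile(fileext = ".rds")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_identical(back$data, ep$data)
  expect_identical(back$trials, ep$trials)
  expect_true(file.exists(paste0(path, ".trials.csv")))
  unlink(c(path, paste0(path, ".trials.csv")))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(snr = 0), "snr")
  expect_error(simulation_config(n_trials = 7), "even")
  expect_error(simulation_config(onset_ms = -400), "contain the kernel")
})
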