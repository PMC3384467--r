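test_that("direct metric formulas: rcm, content, productivity", {
  s <- data.frame(t_h = c(0, 10), cdw_gL = c(2, 10), phb_gL = c(0.5, 4))
  m <- compute_metrics(s)
  expect_equal(m$rcm_gL, c(1.5, 6))
  expect_equal(m$phb_content_wtpct[2L], 40)
  expect_equal(m$max_phb_gL, 4)
  expect_equal(m$volumetric_productivity_gLh, 0.4)
})

test_that("a PHB-free culture yields rcm = cdw and zero productivity", {
  s <- data.frame(t_h = 0:5, cdw_gL = c(1, 2, 3, 4, 4, 4),
                  phb_gL = numeric(6))
  m <- compute_metrics(s)
  expect_equal(m$rcm_gL, s$cdw_gL)
  expect_true(all(m$phb_content_wtpct == 0))
  expect_equal(m$volumetric_productivity_gLh, 0)
})

test_that("metrics equal a pointwise oracle on a simulated series", {
  s <- simulate_batch_culture()
  m <- compute_metrics(s)
  expect_equal(m$rcm_gL, s$cdw_gL - s$phb_gL)
  expect_equal(m$phb_content_wtpct, 100 * s$phb_gL / s$cdw_gL)
  i <- which.max(s$phb_gL)
  expect_equal(m$max_phb_gL, s$phb_gL[i])
  expect_equal(m$volumetric_productivity_gLh,
               s$phb_gL[i] / (s$t_h[i] - s$t_h[1L]))
})

test_that("productivity scales inversely with uniform time dilation", {
  s <- simulate_batch_culture(horizon = 24)
  m1 <- compute_metrics(s)
  s2 <- s; s2$t_h <- 2 * s2$t_h
  m2 <- compute_metrics(s2)
  expect_equal(m2$volumetric_productivity_gLh,
               m1$volumetric_productivity_gLh / 2)
  # end-basis uses the total run time
  m_end <- compute_metrics(s, productivity_basis = "end")
  expect_equal(m_end$volumetric_productivity_gLh,
               m1$max_phb_gL / (s$t_h[nrow(s)] - s$t_h[1L]))
})

test_that("metric preconditions are enforced", {
  expect_error(compute_metrics(data.frame(t_h = 0, cdw_gL = 1,
                                          phb_gL = 0)), "2 time points")
  expect_error(compute_metrics(data.frame(t_h = c(0, 0), cdw_gL = 1:2,
                                          phb_gL = c(0, 0))), "increasing")
  expect_error(compute_metrics(data.frame(t_h = 0:1, cdw_gL = c(1, 2),
                                          phb_gL = c(0, 3))), "exceeds")
  expect_error(compute_metrics(data.frame(t_h = 0:1, cdw_gL = c(0, 0),
                                          phb_gL = c(0, 0.5))), "exceeds")
})

test_that("empty media give a flat culture with PHB at its start value", {
  p <- culture_params(glucose0 = 0, sucrose0 = 0)
  s <- simulate_batch_culture(p, horizon = 10)
  expect_lt(max(s$phb_gL) - min(s$phb_gL), 1e-6)
  expect_lt(max(s$cdw_gL) - min(s$cdw_gL), 1e-6)
})

test_that("growth is monotone until glutamate depletion on glucose alone", {
  p <- culture_params(sucrose0 = 0, glucose0 = 20, msg0 = 3)
  s <- simulate_batch_culture(p, horizon = 30)
  dep <- which(s$msg_gL < 1e-3)[1L]
  expect_false(is.na(dep))
  expect_true(all(diff(s$cdw_gL[seq_len(dep)]) > -1e-9))
})

test_that("the diauxic course holds: sucrose flat while glucose is high", {
  s <- simulate_batch_culture()
  hi <- s$glucose_gL > 1
  expect_gt(sum(hi), 5L)                 # a real glucose-rich interval
  # glucose declines over that interval while sucrose barely moves
  expect_gt(s$glucose_gL[1L] - s$glucose_gL[max(which(hi))], 5)
  expect_lt(max(s$sucrose_gL[hi]) - min(s$sucrose_gL[hi]), 1)
  # afterwards sucrose declines substantially
  expect_gt(s$sucrose_gL[max(which(hi))] - s$sucrose_gL[nrow(s)], 2)
})

test_that("state variables stay non-negative and CDW = RCM + PHB", {
  s <- simulate_batch_culture(horizon = 50)
  expect_true(all(as.matrix(s[, -1L]) >= 0))
  m <- compute_metrics(s)
  expect_true(all(abs(s$cdw_gL - s$phb_gL - m$rcm_gL) < 1e-12))
  expect_error(culture_params(mu_max_glc = -1), "non-negative")
})

test_that("culture series round-trip through CSV", {
  s <- simulate_batch_culture(horizon = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_culture_csv(s, path)
  expect_equal(names(read.csv(path)),
               c("t_h", "cdw_gL", "phb_gL", "glucose_gL", "sucrose_gL",
                 "msg_gL"))
  back <- read_culture_csv(path)
  expect_equal(back$cdw_gL, s$cdw_gL, tolerance = 1e-10)
})
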