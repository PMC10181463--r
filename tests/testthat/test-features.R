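# brute-force oracle: moments straight from the definition
brute_moments <- function(x, orders, kind) {
  n <- length(x)
  mu <- sum(x) / n
  vapply(orders, function(k) {
    if (k == 1) return(mu)
    switch(kind,
           raw = sum(x^k) / n,
           central = sum((x - mu)^k) / n,
           standardized = (sum((x - mu)^k) / n) /
             (sum((x - mu)^2) / n)^(k / 2))
  }, 0)
}

test_that("moments of simple hand-checked series are exact", {
  expect_equal(unname(statistical_moments(rep(7, 50))),
               c(7, rep(0, 9)))
  m <- statistical_moments(c(1, 2, 3, 4), moment_spec(1:4, "central"))
  expect_equal(unname(m), c(2.5, 1.25, 0, 2.5625))
  # odd standardized moment of symmetric data is zero
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(statistical_moments(sym, moment_spec(3, "standardized"))[["m3"]], 0)
  expect_error(statistical_moments(5), "at least 2")
  expect_error(statistical_moments(rep(1, 10), moment_spec(kind = "standardized")),
               "zero-variance")
})

test_that("fast-path moments match the brute-force definition on random windows", {
  set.seed(101)
  for (kind in c("raw", "central", "standardized")) {
    worst <- 0
    for (i in 1:1000) {
      x <- rnorm(sample(16:64, 1), mean = runif(1, -5, 5),
                 sd = runif(1, 0.5, 3))
      got <- statistical_moments(x, moment_spec(1:10, kind))
      want <- brute_moments(x, 1:10, kind)
      worst <- max(worst, max(abs(got - want) / pmax(abs(want), 1e-12)))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("central moments are shift-invariant and standardized moments scale-invariant", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(128)
    mc <- statistical_moments(x, moment_spec(2:10, "central"))
    mc_shift <- statistical_moments(x + 1e3 * i, moment_spec(2:10, "central"))
    expect_equal(mc, mc_shift, tolerance = 1e-7)
    ms <- statistical_moments(x, moment_spec(2:10, "standardized"))
    ms_scale <- statistical_moments(x * runif(1, 0.1, 50),
                                    moment_spec(2:10, "standardized"))
    expect_equal(ms, ms_scale, tolerance = 1e-9)
  }
  x <- rnorm(64)
  expect_identical(statistical_moments(x, moment_spec(1, "raw")),
                   statistical_moments(x, moment_spec(1, "central")))
})

test_that("feature tables have channel-major moment columns and full provenance", {
  ep16 <- task_epoch(matrix(rnorm(2 * 512 * 16), ncol = 16,
                            dimnames = list(NULL, montage_labels <- c(
                              "Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3",
                              "C4", "Cz", "P3", "P4", "Pz", "O1", "O2", "T8"))),
                     512, "hand", "left", "imagery")
  w <- window_epoch(ep16, 1, 0)
  tab <- build_feature_table(w)
  expect_equal(length(feature_columns(tab)), 160)   # 16 channels x 10 orders
  expect_identical(feature_columns(tab)[1:3], c("Fp1_m1", "Fp1_m2", "Fp1_m3"))
  expect_identical(feature_columns(tab)[11], "Fp2_m1")
  expect_false(anyNA(tab))
  expect_true(all(tab$label %in% protocol_classes()))
  # single-channel montage: 10 columns
  ep1 <- task_epoch(matrix(rnorm(1024), ncol = 1,
                           dimnames = list(NULL, "FP1")),
                    512, "ankle", "right", "real")
  tab1 <- build_feature_table(window_epoch(ep1, 1, 0))
  expect_equal(length(feature_columns(tab1)), 10)
  expect_error(build_feature_table(list()), "empty")
  expect_error(build_feature_table(c(w, list(window_epoch(ep1, 1, 0)[[1]]))),
               "heterogeneous")
})

test_that("feature values agree with direct per-window computation", {
  ep <- task_epoch(matrix(rnorm(2048), ncol = 2,
                          dimnames = list(NULL, c("C3", "C4"))),
                   512, "hand", "right", "real")
  w <- window_epoch(ep, 1, 0)
  tab <- build_feature_table(w, moment_spec(1:10, "central"))
  expect_equal(unname(unlist(tab[2, paste0("C4_m", 1:10)])),
               unname(brute_moments(w[[2]]$signals[, "C4"], 1:10, "central")))
})
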