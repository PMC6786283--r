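test_that("densitometry normalization maps the reference mean to 1", {
  df <- data.frame(group = rep(c("am", "pm"), each = 3),
                   replicate = 1:6,
                   target = c(2, 2.2, 1.8, 1.4, 1.5, 1.3),
                   loading1 = c(1, 1.1, 0.9, 1, 1, 1))
  out <- normalize_densitometry(df, "am")
  expect_equal(mean(out$normalized[out$group == "am"]), 1)
  # target equal to loading everywhere collapses to all-ones
  same <- data.frame(group = "a", replicate = 1:4, target = c(1, 2, 3, 4),
                     loading1 = c(1, 2, 3, 4))
  expect_equal(normalize_densitometry(same, "a")$normalized, rep(1, 4))
  # per-sample rescaling of both channels cancels
  df2 <- df; df2$target[1] <- df$target[1] * 5; df2$loading1[1] <- df$loading1[1] * 5
  expect_equal(normalize_densitometry(df2, "am")$normalized,
               normalize_densitometry(df, "am")$normalized)
  # two loading controls combine as a geometric mean
  df3 <- df; df3$loading2 <- 4 * df$loading1
  expect_equal(normalize_densitometry(df3, "am")$normalized,
               normalize_densitometry(df, "am")$normalized)
  bad <- df; bad$loading1[2] <- 0
  expect_error(normalize_densitometry(bad, "am"), "loading")
})

test_that("exact branch equals full enumeration for all n1+n2 <= 12", {
  withr::local_seed(5)
  sizes <- subset(expand.grid(n1 = 1:11, n2 = 1:11), n1 + n2 <= 12)
  for (i in seq_len(nrow(sizes))) {
    x <- rnorm(sizes$n1[i])
    y <- rnorm(sizes$n2[i])
    got <- mann_whitney_u(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_two_sided, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("U statistic identities and invariances hold", {
  withr::local_seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(2:9, 1)); y <- rnorm(sample(2:9, 1))
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p_two_sided, b$p_two_sided)
    # rank test: any strictly monotone transform leaves p unchanged
    expect_equal(mann_whitney_u(exp(x), exp(y))$p_two_sided, a$p_two_sided)
  }
  # frozen enumerations
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_two_sided, 0.1)
  sep <- mann_whitney_u(1:7, 8:15)
  expect_equal(sep$U, 0)
  expect_equal(sep$p_two_sided, 2 / 6435)
  # cross-check against the reference implementation on tie-free data
  withr::local_seed(7)
  x <- rnorm(7); y <- rnorm(8)
  expect_equal(mann_whitney_u(x, y)$p_two_sided,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("ties route to the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5); y <- c(2, 4, 4, 6, 7)
  got <- mann_whitney_u(x, y)
  expect_identical(got$method, "normal-approximation")
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 0.05)
  # identical multisets sit at the null mean: p = 1
  z <- c(1, 1, 2, 3)
  expect_identical(mann_whitney_u(z, z)$p_two_sided, 1)
})

test_that("type-I error is nominal for the exact test at n = 7 vs 8", {
  withr::local_seed(11)
  rej <- logical(10000)
  for (i in seq_along(rej)) {
    rej[i] <- mann_whitney_u(rnorm(7), rnorm(8))$p_two_sided < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("diurnal comparison reports percent change of the reference mean", {
  a <- c(0.95, 1.05, 1.0, 1.0); b <- a * 0.7
  got <- diurnal_change(a, b)
  expect_equal(got$percent_change, -30)
  up <- diurnal_change(c(1, 1), c(1.2, 1.3))
  expect_equal(up$percent_change, 25)
  same <- diurnal_change(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$percent_change, 0)
  expect_identical(same$p_two_sided, 1)
  expect_error(diurnal_change(numeric(0), 1), "empty")
  expect_error(diurnal_change(c(-1, 1), c(1, 2)), "zero")
})
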