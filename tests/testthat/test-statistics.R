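vec_df <- function(vx, vy, x = NULL, y = NULL) {
  n <- length(vx)
  data.frame(x_um = if (is.null(x)) seq_len(n) else x,
             y_um = if (is.null(y)) rep(1, n) else y,
             vx_um_s = vx, vy_um_s = vy)
}

test_that("median speed is the median vector norm with midpoint convention", {
  r <- median_speed(vec_df(rep(3, 5), rep(4, 5)))
  expect_equal(r$median_speed, 5)
  expect_identical(r$n_vectors, 5L)
  r2 <- median_speed(vec_df(c(1, 2, 3, 4), rep(0, 4)))
  expect_equal(r2$median_speed, 2.5)
  expect_error(median_speed(vec_df(1, 1), subregion = circle_polygon(c(100, 100), 1)),
               "empty region")
})

test_that("median speed is rotation-invariant and scales linearly", {
  set.seed(61)
  vx <- rnorm(31); vy <- rnorm(31)
  base <- median_speed(vec_df(vx, vy))$median_speed
  th <- 0.7
  rot <- median_speed(vec_df(cos(th) * vx - sin(th) * vy,
                             sin(th) * vx + cos(th) * vy))$median_speed
  expect_equal(rot, base, tolerance = 1e-12)
  expect_equal(median_speed(vec_df(3.2 * vx, 3.2 * vy))$median_speed,
               3.2 * base, tolerance = 1e-12)
})

test_that("region areas come from pixel counts times pixel area", {
  m <- matrix(0L, 20, 20)
  m[1:10, 1:10] <- 2L
  r <- region_area(m, 2, pixel_size = 2)
  expect_identical(r$pixel_count, 100L)
  expect_equal(r$area, 400)
  expect_error(region_area(m, 7, 2), "not present")
  ## rasterized disk of radius 25 um at 1 um/px is within 2% of pi r^2
  mask <- compartments_mask(list(compartment_spec("disk", "static",
                                                  center = c(30, 30), radius = 25)),
                            c(60, 60), pixel_size = 1)
  a <- region_area(mask, "disk", 1)
  expect_equal(a$area, pi * 25^2, tolerance = 0.02)
})

test_that("the paired test matches exhaustive sign-pattern enumeration", {
  before <- c(1, 2, 3, 4, 5, 6)
  after <- c(2, 3, 4, 5, 6, 7)
  got <- compare_paired(before, after)
  expect_equal(got$p, enumerate_signed_rank_p(after - before))
  expect_equal(got$p, 2 / 2^6)
  expect_false(got$significant)
  set.seed(62)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d[d == 0] <- 0.11 # keep pairs informative
    got <- compare_paired(rep(0, n), d)
    expect_equal(got$p, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("the paired test agrees with the classical exact distribution when untied", {
  ## distribution cross-check against dsignrank (no ties)
  r2 <- as.integer(2 * rank(1:7))
  dist <- ptvflow:::signed_rank_exact_dist(r2)
  ws <- seq(0, sum(1:7))
  expect_equal(dist[2 * ws + 1], dsignrank(ws, 7), tolerance = 1e-12)
  set.seed(63)
  for (i in 1:6) {
    n <- sample(6:10, 1)
    before <- rnorm(n); after <- before + rnorm(n, 0.5)
    got <- compare_paired(before, after)
    want <- wilcox.test(after, before, paired = TRUE, exact = TRUE)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
    expect_equal(unname(got$statistic), unname(want$statistic))
  }
})

test_that("degenerate paired inputs are rejected", {
  x <- c(1, 2, 3, 4, 5)
  expect_error(compare_paired(x, x), "degenerate")
  expect_error(compare_paired(1:4, 2:5), "at least 5")
})

test_that("the unpaired test matches exhaustive labeling enumeration", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  got <- compare_unpaired(a, b)
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)
  expect_equal(got$p, enumerate_mann_whitney_p(a, b))
  set.seed(64)
  for (i in 1:8) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.8)
    got <- compare_unpaired(a, b)
    expect_equal(got$p, enumerate_mann_whitney_p(a, b), tolerance = 1e-12)
  }
})

test_that("the unpaired test agrees with the classical exact distribution when untied", {
  dist <- ptvflow:::rank_sum_exact_dist(9, 4)
  ## shift rank sums to U statistics: U = Ra - na(na+1)/2
  us <- 0:20
  expect_equal(dist[us + 10 + 1], dwilcox(us, 4, 5), tolerance = 1e-12)
  set.seed(65)
  for (i in 1:6) {
    a <- rnorm(6); b <- rnorm(7, 0.5)
    got <- compare_unpaired(a, b)
    want <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
    expect_equal(unname(got$U), unname(want$statistic))
  }
})

test_that("identical groups give U = n1 n2 / 2 and p = 1", {
  x <- c(4, 4, 4, 4)
  got <- compare_unpaired(x, x)
  expect_equal(got$U, 8)
  expect_equal(got$p, 1)
  expect_false(got$significant)
})

test_that("both tests are invariant under strictly monotone transforms", {
  set.seed(66)
  before <- rnorm(8); after <- before + rnorm(8, 0.4)
  f <- function(z) exp(z) # strictly increasing
  p1 <- compare_paired(before, after)
  ## signed ranks are not transform-invariant in general, but the unpaired
  ## test is purely rank-based:
  a <- rnorm(7); b <- rnorm(6, 1)
  expect_equal(compare_unpaired(a, b)$p, compare_unpaired(f(a), f(b))$p, tolerance = 1e-12)
  expect_equal(compare_unpaired(a, b)$U, compare_unpaired(f(a), f(b))$U)
  ## paired test is invariant under common shifts and positive scalings
  expect_equal(compare_paired(before, after)$p,
               compare_paired(3 * before + 2, 3 * after + 2)$p, tolerance = 1e-12)
})

test_that("tied data take the corrected normal approximation path", {
  a <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6)
  b <- c(2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7)
  got <- compare_unpaired(a, b)
  want <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_match(got$method, "tie correction")
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
})
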