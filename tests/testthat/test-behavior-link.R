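test_that("d-prime matches inverse-normal evaluation with log-linear correction", {
  expect_equal(compute_dprime(50, 50, 50, 100), 0)
  # H = 0.84, F = 0.16: qnorm(0.84) - qnorm(0.16) ~ 1.9889
  expect_equal(compute_dprime(84, 16, 16, 100),
               stats::qnorm(0.84) - stats::qnorm(0.16), tolerance = 1e-12)
  # perfect hit rate triggers the correction on every cell
  d <- compute_dprime(20, 0, 2, 100)
  expect_equal(d, stats::qnorm(20.5 / 21) - stats::qnorm(2.5 / 101), tolerance = 1e-12)
  expect_true(is.finite(d))
  # antisymmetry under swapping hit and false-alarm rates
  expect_equal(compute_dprime(30, 10, 10, 40), -compute_dprime(10, 30, 30, 40),
               tolerance = 1e-12)
  expect_error(compute_dprime(0, 0, 1, 10), "no targets")
  expect_error(compute_dprime(-1, 2, 1, 10), "non-negative")
})

test_that("behavioral summary separates validity conditions with sensible d-prime ordering", {
  gen <- big_session()
  bs <- behavioral_summary(gen$session)
  valid <- bs$by_condition[bs$by_condition$validity == "valid", ]
  # detectability grows with the orientation change magnitude
  expect_true(all(diff(valid$dprime[order(valid$delta)]) > 0) ||
                stats::cor(valid$delta, valid$dprime) > 0.8)
  expect_true(bs$fa_rate >= 0 && bs$fa_rate < 0.1)
  expect_true(all(bs$rt$mean_rt_ms > 100, na.rm = TRUE))
})

make_records <- function(a_pre, a_post, hit) {
  n <- length(a_pre)
  flashes <- data.frame(
    trial_id = rep(seq_len(n), each = 2), flash_index = rep(1:2, n),
    is_target = rep(c(FALSE, TRUE), n),
    target_location = rep(c("none", "RF"), n),
    outcome = rep("none", 2 * n), is_cue_trial = FALSE,
    stringsAsFactors = FALSE
  )
  flashes$outcome[seq(2, 2 * n, 2)] <- ifelse(hit, "hit", "miss")
  records <- data.frame(
    trial_id = flashes$trial_id, flash_index = flashes$flash_index,
    a_pre = rep(a_pre, each = 2), a_post = rep(a_post, each = 2)
  )
  list(records = records, flashes = flashes)
}

test_that("quintile binning balances cells and is rank invariant", {
  set.seed(3)
  a_pre <- rnorm(25); a_post <- rnorm(25)
  fx <- make_records(a_pre, a_post, rep(TRUE, 25))
  map <- bin_projections_quintiles(fx$records, fx$flashes)
  # 25 distinct projections -> 5 per quintile on each axis
  expect_true(all(tapply(map$cells$n, map$cells$pre_q, sum) == 5))
  expect_true(all(tapply(map$cells$n, map$cells$post_q, sum) == 5))
  # all hits: every defined cell's normalized hit rate is 1
  expect_true(all(map$cells$norm_hit_rate[map$cells$n > 0] == 1))

  # strictly monotone transform of projections leaves the map unchanged
  fx2 <- fx
  fx2$records$a_pre <- exp(fx2$records$a_pre)
  fx2$records$a_post <- atan(fx2$records$a_post)
  map2 <- bin_projections_quintiles(fx2$records, fx2$flashes)
  expect_equal(map2$cells, map$cells)

  const <- make_records(rep(1, 25), rnorm(25), rep(TRUE, 25))
  expect_error(bin_projections_quintiles(const$records, const$flashes),
               "identical")
})

test_that("count-weighted mean of normalized cell hit rates is 1", {
  set.seed(13)
  hit <- runif(60) < 0.55
  fx <- make_records(rnorm(60), rnorm(60), hit)
  map <- bin_projections_quintiles(fx$records, fx$flashes)
  def <- map$cells$n > 0
  wmean <- sum(map$cells$norm_hit_rate[def] * map$cells$n[def]) / sum(map$cells$n[def])
  expect_equal(wmean, 1, tolerance = 1e-12)
})

test_that("marginals preserve constant and affine structure", {
  cells <- expand.grid(pre_q = 1:5, post_q = 1:5)
  cells$n <- 1L
  cells$hit_rate <- 0.5
  cells$norm_hit_rate <- 0.7
  map <- structure(list(cells = cells, overall_hit_rate = 0.5, n_intervals = 25),
                   class = "performance_map")
  expect_equal(marginal_performance(map, "pre"), rep(0.7, 5))
  expect_equal(marginal_performance(map, "post"), rep(0.7, 5))

  # variation only along the post axis: pre marginal flat, post marginal linear
  cells2 <- cells
  cells2$norm_hit_rate <- 0.2 * cells2$post_q
  map2 <- structure(list(cells = cells2, overall_hit_rate = 0.5, n_intervals = 25),
                    class = "performance_map")
  expect_equal(marginal_performance(map2, "pre"), rep(0.6, 5))
  expect_equal(marginal_performance(map2, "post"), 0.2 * (1:5))
})

test_that("rank correlations aggregate with Fisher z and handle degenerate cases", {
  mk_map <- function(hr_fun) {
    cells <- expand.grid(pre_q = 1:5, post_q = 1:5)
    cells$n <- 2L
    cells$hit_rate <- hr_fun(cells)
    cells$norm_hit_rate <- cells$hit_rate / mean(cells$hit_rate)
    structure(list(cells = cells, overall_hit_rate = mean(cells$hit_rate),
                   n_intervals = 50), class = "performance_map")
  }
  # hit rate strictly increasing in pre quintile (constant within it, so
  # tied ranks align exactly) -> rho = 1 in every session, clipped before z
  inc <- replicate(4, mk_map(function(c) 0.1 + 0.1 * c$pre_q),
                   simplify = FALSE)
  rc <- rank_correlation_sessions(inc)
  expect_equal(rc$per_axis$mean_rho[rc$per_axis$axis == "pre"], 1, tolerance = 1e-6)

  # two sessions at rho = 0.5: back-transformed mean is 0.5 (fixed point)
  z_equal <- matrix(atanh(0.5), nrow = 2, ncol = 2)
  expect_equal(tanh(mean(z_equal[, 1])), 0.5, tolerance = 1e-12)

  expect_error(rank_correlation_sessions(inc[1:2]), "at least 3")
})

test_that("rank-correlation t-test is calibrated under a null behavior link", {
  set.seed(41)
  pvals <- replicate(200, {
    maps <- replicate(6, {
      hit <- runif(50) < 0.5
      fx <- make_records(rnorm(50), rnorm(50), hit)
      bin_projections_quintiles(fx$records, fx$flashes)
    }, simplify = FALSE)
    # occasional Lilliefors warnings at the nominal rate are expected here
    rc <- suppressWarnings(suppressMessages(rank_correlation_sessions(maps)))
    rc$per_axis$p_value[rc$per_axis$axis == "pre"]
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("generator's monotone behavior link yields a performance gradient", {
  gen <- big_session()
  proj <- fixture("big_proj", function() {
    cross_validated_projections(big_session()$session, n_folds = 60, seed = 81)
  })
  map <- bin_projections_quintiles(proj$records, gen$session$flashes, "RF")
  c55 <- map$cells$norm_hit_rate[map$cells$pre_q == 5 & map$cells$post_q == 5]
  c11 <- map$cells$norm_hit_rate[map$cells$pre_q == 1 & map$cells$post_q == 1]
  expect_true(is.finite(c55) && is.finite(c11))
  expect_gt(c55, c11)
})
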