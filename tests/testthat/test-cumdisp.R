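test_that("hourly pairing chains 289 five-minute frames into 24 intervals", {
  times <- (0:288) * 5 / 60
  p <- hourly_pairs(times, stats_config(cadence_min = 5))
  expect_equal(nrow(p), 24L)
  expect_equal(p$frame_a, seq(1L, 277L, by = 12L))
  expect_equal(p$frame_b, p$frame_a + 12L)
  expect_equal(p$t_b_h, 1:24)
  # hourly frames pair adjacently
  p2 <- hourly_pairs(0:24, stats_config(cadence_min = 60))
  expect_equal(nrow(p2), 24L)
  expect_equal(p2$frame_b - p2$frame_a, rep(1L, 24))
})

test_that("pairing rejects non-uniform or incompatible sampling", {
  expect_error(hourly_pairs(c(0, 1, 3), stats_config(cadence_min = 60)),
               class = "gelsense_invalid_config")
  expect_error(hourly_pairs(0:10, stats_config(cadence_min = 5)),
               class = "gelsense_invalid_config")  # cadence mismatch
  expect_error(hourly_pairs(seq(0, 2, by = 7 / 60),
                            stats_config(cadence_min = 7, pair_interval_h = 1)),
               class = "gelsense_invalid_config")  # 60 not a multiple of 7
  expect_error(hourly_pairs(0), class = "gelsense_invalid_config")
})

test_that("path and net accumulation match hand-computed values", {
  mk <- function(ux, uy, t) {
    f <- tibble::tibble(node_id = 1:2, ux_um = ux, uy_um = uy)
    attr(f, "t_b_h") <- t
    f
  }
  # node 1 moves +3 then -4 in x; node 2 moves (1,1) twice
  fields <- list(mk(c(3, 1), c(0, 1), 1), mk(c(-4, 1), c(0, 1), 2))
  path <- accumulate_displacements(fields, "path")
  net <- accumulate_displacements(fields, "net")
  expect_equal(dplyr::filter(path, node_id == 1)$cum_um, c(3, 7))
  expect_equal(dplyr::filter(net, node_id == 1)$cum_um, c(3, 1))
  expect_equal(dplyr::filter(path, node_id == 2)$cum_um, c(sqrt(2), 2 * sqrt(2)))
  expect_equal(dplyr::filter(net, node_id == 2)$cum_um, c(sqrt(2), 2 * sqrt(2)))
  expect_equal(unique(path$t_h), c(1, 2))
})

test_that("path dominates net and is nondecreasing (random fields)", {
  fields <- with_seed(77, purrr::map(1:12, function(k) {
    f <- tibble::tibble(node_id = 1:40, ux_um = rnorm(40), uy_um = rnorm(40))
    attr(f, "t_b_h") <- k
    f
  }))
  path <- accumulate_displacements(fields, "path")
  net <- accumulate_displacements(fields, "net")
  expect_true(all(path$cum_um >= net$cum_um - 1e-12))
  mono <- path |>
    dplyr::group_by(node_id) |>
    dplyr::summarise(ok = all(diff(cum_um[order(t_h)]) >= -1e-12))
  expect_true(all(mono$ok))
  # both start at the first interval magnitude
  first <- sqrt(fields[[1]]$ux_um^2 + fields[[1]]$uy_um^2)
  expect_equal(dplyr::filter(path, t_h == 1)$cum_um, first)
  expect_equal(dplyr::filter(net, t_h == 1)$cum_um, first)
})

test_that("accumulation rejects inconsistent node sets", {
  f1 <- tibble::tibble(node_id = 1:3, ux_um = 0, uy_um = 0)
  f2 <- tibble::tibble(node_id = 1:2, ux_um = 0, uy_um = 0)
  expect_error(accumulate_displacements(list(f1, f2)), class = "gelsense_data_error")
  expect_error(accumulate_displacements(list()), class = "gelsense_data_error")
})

test_that("the percentile matches a brute-force order-statistic oracle", {
  # worked example: the 90th percentile of 1..10 interpolates to 9.1
  tr <- tibble::tibble(node_id = 1:10, t_h = 1, cum_um = as.numeric(1:10))
  s <- percentile_timecourse(tr, stats_config())
  expect_equal(s$p90_um, 9.1)
  # 1000 random draws, several percentiles
  x <- with_seed(101, rexp(1000, 0.3))
  for (pct in c(50, 90, 97.5)) {
    tr2 <- tibble::tibble(node_id = seq_along(x), t_h = 1, cum_um = x)
    s2 <- percentile_timecourse(tr2, stats_config(percentile = pct))
    expect_equal(s2$p90_um, quantile_oracle(x, pct / 100), tolerance = 1e-12)
  }
})

test_that("replicate spread is the SD of per-replicate percentiles", {
  tr <- dplyr::bind_rows(
    tibble::tibble(node_id = 1:10, t_h = 1, cum_um = as.numeric(1:10), replicate = 1L),
    tibble::tibble(node_id = 1:10, t_h = 1, cum_um = as.numeric(11:20), replicate = 2L),
    tibble::tibble(node_id = 1:10, t_h = 1, cum_um = as.numeric(21:30), replicate = 3L)
  )
  s <- percentile_timecourse(tr, stats_config())
  expect_equal(s$n_replicates, 3L)
  expect_equal(s$sd_um, sd(c(9.1, 19.1, 29.1)))
  expect_equal(s$p90_um, quantile_oracle(as.numeric(1:30), 0.9))
  # single replicate: spread is 0, not NA
  s1 <- percentile_timecourse(dplyr::filter(tr, replicate == 1), stats_config())
  expect_equal(s1$sd_um, 0)
  # a list of per-replicate traces is accepted too
  s3 <- percentile_timecourse(
    list(tibble::tibble(node_id = 1:10, t_h = 1, cum_um = as.numeric(1:10)),
         tibble::tibble(node_id = 1:10, t_h = 1, cum_um = as.numeric(11:20)),
         tibble::tibble(node_id = 1:10, t_h = 1, cum_um = as.numeric(21:30))),
    stats_config())
  expect_equal(s3$p90_um, s$p90_um)
})

test_that("the window average is the inclusive mean over 8-24 h", {
  s <- tibble::tibble(t_h = 1:24, p90_um = as.numeric(1:24))
  expect_equal(window_average(s, stats_config()), mean(8:24))
  expect_equal(window_average(s, stats_config(window_start_h = 1, window_end_h = 2)), 1.5)
  expect_error(window_average(tibble::tibble(t_h = 1:3, p90_um = 1:3), stats_config()),
               class = "gelsense_data_error")
  expect_error(stats_config(window_start_h = 24, window_end_h = 8),
               class = "gelsense_invalid_config")
})

test_that("group summary reports per-condition mean, SD and n", {
  df <- tibble::tibble(condition = c("a", "a", "a", "b"),
                       window_mean_um = c(1, 2, 3, 10))
  g <- group_summary(df)
  expect_equal(g$condition, c("a", "b"))
  expect_equal(g$mean_um, c(2, 10))
  expect_equal(g$sd_um, c(1, 0))
  expect_equal(g$n, c(3L, 1L))
})
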