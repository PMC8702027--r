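make_plates <- function(responses_by_endpoint, vehicle_mean = 1, veh_n = 6,
                        dilutions = 3^-(0:4)) {
  veh <- purrr::imap_dfr(responses_by_endpoint, function(x, ep) {
    tibble::tibble(sample_id = "VEHICLE", endpoint_id = ep,
                   dilution = NA_real_, replicate = seq_len(veh_n),
                   response = vehicle_mean + c(-0.01, 0.01)[1 + seq_len(veh_n) %% 2])
  })
  trt <- purrr::imap_dfr(responses_by_endpoint, function(x, ep) {
    tibble::tibble(sample_id = "S1", endpoint_id = ep,
                   dilution = dilutions, replicate = 1L, response = x)
  })
  dplyr::bind_rows(trt, veh)
}

test_that("vehicle scaling is the identity at the control mean and linear", {
  plates <- make_plates(list(e1 = c(2, 2, 2, 2, 2)), vehicle_mean = 2)
  vs <- vehicle_stats(plates)
  expect_equal(vs$mean, 2, tolerance = 1e-2)
  scaled <- scale_to_vehicle(plates, vs)
  expect_equal(scaled$response, rep(2 / vs$mean, 5))
  plates4 <- make_plates(list(e1 = rep(4, 5)), vehicle_mean = 2)
  scaled4 <- scale_to_vehicle(plates4, vs)
  expect_equal(scaled4$response, rep(4 / vs$mean, 5), tolerance = 1e-12)
})

test_that("a zero vehicle mean raises a degenerate-control error", {
  plates <- make_plates(list(e1 = rep(1, 5)))
  vs <- vehicle_stats(plates)
  vs$mean <- 0
  expect_error(scale_to_vehicle(plates, vs), "degenerate control")
})

test_that("logistic fit recovers known parameters from noiseless data", {
  x <- rep(10^seq(-4, 0, length.out = 8), each = 3)
  y <- 0.4 + (1.0 - 0.4) / (1 + 10^(1.5 * (-2 - log10(x))))
  fit <- fit_logistic(data.frame(dilution = x, response = y))
  expect_true(fit$converged)
  expect_equal(fit$bottom, 0.4, tolerance = 1e-3)
  expect_equal(fit$top, 1.0, tolerance = 1e-3)
  expect_equal(fit$log10_ec50, -2, tolerance = 1e-3)
  expect_equal(fit$hill, 1.5, tolerance = 1e-3)
  expect_equal(predict(fit, 10^-2), 0.7, tolerance = 1e-3)
})

test_that("flat series yield a flat converged fit", {
  fit <- fit_logistic(data.frame(dilution = 3^-(0:4), response = rep(1, 5)))
  expect_true(fit$converged)
  expect_equal(fit$top, fit$bottom)
  expect_equal(fit$top, 1)
  expect_equal(fit$rss, 0)
})

test_that("mirrored series give reflected fits with equal |hill|", {
  x <- rep(3^-(0:5), each = 2)
  withr::with_seed(1, {
    up <- 1 + 0.5 / (1 + (0.05 / x)^2) + rnorm(length(x), 0, 0.01)
  })
  down <- 2 - up
  f_up <- fit_logistic(data.frame(dilution = x, response = up))
  f_dn <- fit_logistic(data.frame(dilution = x, response = down))
  expect_equal(abs(f_up$hill), abs(f_dn$hill), tolerance = 1e-2)
  expect_equal(f_up$log10_ec50, f_dn$log10_ec50, tolerance = 1e-2)
  expect_equal(f_up$top + f_dn$bottom, 2, tolerance = 1e-2)
})

test_that("POD equals the closed-form band crossing, checked by grid search", {
  # decreasing curve from 1.0 to 0.4; band 1 +/- 0.05 -> crossing at f = 0.95
  fit <- sedscreen:::new_logistic_fit(bottom = 1, top = 0.4,
                                      log10_ec50 = -2, hill = 1.5,
                                      converged = TRUE, rss = 0, n = 24)
  pod <- derive_pod(fit, vehicle_mean = 1, vehicle_sd = 0.05,
                    tested_range = c(3^-7, 1))
  expect_false(pod$censored)
  expect_equal(pod$direction, "below")
  # closed form: f(x) = 0.95
  r <- (0.4 - 1) / (0.95 - 1) - 1
  x_closed <- 10^(-2 - log10(r) / 1.5)
  expect_equal(pod$pod, x_closed, tolerance = 1e-10)
  lg <- seq(log10(3^-7), 0, by = 1e-4)
  f <- predict(fit, 10^lg)
  x_grid <- 10^lg[which(abs(f - 1) > 0.05)[1]]
  expect_lt(abs(log10(pod$pod) - log10(x_grid)), 2e-4)
})

test_that("flat and non-converged fits censor at the maximum tested dilution", {
  flat <- sedscreen:::new_logistic_fit(1, 1, -1, 0, TRUE, 0, 10)
  pod <- derive_pod(flat, 1, 0.05, c(0.001, 1))
  expect_true(pod$censored)
  expect_equal(pod$pod, 1)
  expect_equal(pod$direction, "none")
  bad <- sedscreen:::new_logistic_fit(1, 0.5, -2, 1, FALSE, 1, 10)
  pod2 <- derive_pod(bad, 1, 0.05, c(0.001, 1))
  expect_true(pod2$censored)
  expect_equal(pod2$quality, "nonconverged")
})

test_that("a zero-width band clamps to the lowest dilution as extrapolated-low", {
  fit <- sedscreen:::new_logistic_fit(1, 0.4, -2, 1.5, TRUE, 0, 24)
  pod <- derive_pod(fit, 1, 0, c(3^-7, 1))
  expect_false(pod$censored)
  expect_true(pod$extrapolated_low)
  expect_equal(pod$pod, 3^-7)
})

test_that("shrinking the vehicle band never increases the POD", {
  withr::with_seed(5, {
    for (i in 1:25) {
      fit <- sedscreen:::new_logistic_fit(
        bottom = 1, top = runif(1, 0.2, 0.8),
        log10_ec50 = runif(1, -4, 0), hill = runif(1, 0.5, 4),
        converged = TRUE, rss = 0, n = 24
      )
      sds <- sort(runif(2, 0.01, 0.3))
      p_small <- derive_pod(fit, 1, sds[1], c(3^-7, 1))$pod
      p_large <- derive_pod(fit, 1, sds[2], c(3^-7, 1))$pod
      expect_lte(p_small, p_large)
    }
  })
})

test_that("fit_pods recovers direction and censoring on a small study", {
  d <- small_design()
  st <- simulate_study(d, seed = 21)
  pods <- fit_pods(st$plates)
  expect_equal(nrow(pods), d$n_samples * nrow(d$endpoints))
  j <- dplyr::inner_join(pods, st$truth_pods,
                         by = c("sample_id", "endpoint_id"))
  acc <- mean((!j$censored) == is.finite(j$true_pod))
  expect_gte(acc, 0.9)
  act <- j[is.finite(j$true_pod) & !j$censored, ]
  ep <- d$endpoints
  planted <- ifelse(ep$direction[match(act$endpoint_id, ep$endpoint_id)] ==
                      "increase", "above", "below")
  expect_gte(mean(act$direction == planted), 0.95)
})
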