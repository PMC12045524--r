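test_that("zero net force conserves velocity exactly; thrust integrates a*t", {
  cfg <- task_config()
  s <- list(time = 0, position = 0, velocity = 0.5,
            key_left = FALSE, key_right = FALSE)
  s2 <- step_dynamics(s, 0.01, cfg)
  expect_identical(s2$velocity, 0.5)
  expect_identical(s2$position, 0.005)

  # both keys held cancel exactly
  s$key_left <- s$key_right <- TRUE
  s3 <- step_dynamics(s, 0.01, cfg)
  expect_identical(s3$velocity, 0.5)

  # right held 1.0 s from rest at a = 2: v = a t exactly under Euler
  s <- list(time = 0, position = 0, velocity = 0,
            key_left = FALSE, key_right = TRUE)
  for (i in 1:100) s <- step_dynamics(s, 0.01, cfg)
  expect_equal(s$velocity, 2.0, tolerance = 1e-12)

  expect_error(step_dynamics(list(time = 0, position = NaN, velocity = 0,
                                  key_left = FALSE, key_right = FALSE),
                             0.01, cfg),
               "non-finite")
})

test_that("thrust-then-coast position matches the closed-form kinematics", {
  # a = 2, thrust tau = 0.5 s then coast to t = 1 s:
  # x(1) = a tau^2 / 2 + a tau (1 - tau) = 0.25 + 0.5 = 0.75
  cfg <- task_config()
  dt <- 1e-3
  s <- list(time = 0, position = 0, velocity = 0,
            key_left = FALSE, key_right = TRUE)
  for (i in 1:1000) {
    s$key_right <- s$time < 0.5
    s <- step_dynamics(s, dt, cfg)
  }
  expect_equal(s$position, 0.75, tolerance = 1e-3)
  expect_equal(s$velocity, 1.0, tolerance = 1e-12)
})

test_that("the ideal bang-bang controller lands every trial with margin", {
  cfg <- task_config()
  sess <- run_session(cfg, bang_bang_controller(cfg), seed = 1)
  expect_identical(sum(sess$planets$success), 75L)
  landed <- vapply(sess$trials, function(tr) {
    tr$events$time[tr$events$event == "landed"][1]
  }, numeric(1))
  # arrival ~1.41 s after the go cue, landed ~1 s after entering the target,
  # always well before the movement window closes
  expect_true(all(landed > cfg$hold_duration + 1.3))
  expect_true(all(landed < cfg$trial_duration - 0.5))
  # trials end at the landed event: no samples after it
  expect_true(all(vapply(sess$trials, function(tr) {
    max(tr$samples$t) == tr$events$time[tr$events$event == "landed"][1]
  }, logical(1))))
})

test_that("early exits reset the trial without consuming the attempt", {
  cfg <- task_config()
  # exits the start boundary around t = 1.0 s on the first attempt only,
  # then plays the ideal strategy
  tau <- sqrt(cfg$planet_distance / cfg$force_accel)
  ctrl <- as_controller(function(t, attempt) {
    if (attempt == 1) {
      list(key_left = rep(FALSE, length(t)), key_right = t >= 0.7)
    } else {
      list(key_left = t >= cfg$hold_duration + tau &
             t < cfg$hold_duration + 2 * tau,
           key_right = t >= cfg$hold_duration & t < cfg$hold_duration + tau)
    }
  })
  log <- run_trial(cfg, ctrl)
  expect_identical(sum(log$events$event == "early_exit_reset"), 1L)
  expect_true(log$success)
  # reset soundness: post-reset timeline never outside the start planet
  # before the go cue
  final <- log$samples[log$samples$attempt == max(log$samples$attempt), ]
  pre_go <- final[final$t < cfg$hold_duration, ]
  expect_true(all(abs(pre_go$x) <= cfg$planet_radius))
  # the reset attempt is cut at the exit sample (~1.0 s: 0.7 s onset +
  # sqrt(radius / 2) of thrust)
  first <- log$samples[log$samples$attempt == 1, ]
  expect_lt(max(first$t), cfg$hold_duration)

  # a controller that always exits early terminates via the reset cap
  bad <- as_controller(function(t) {
    list(key_left = rep(FALSE, length(t)), key_right = t >= 0.5)
  })
  log2 <- run_trial(cfg, bad)
  expect_false(log2$success)
  expect_identical(sum(log2$events$event == "early_exit_reset"),
                   cfg$max_resets)
  expect_identical(tail(log2$events$event, 1), "trial_end")
})

test_that("null controller stays put and violating key contracts errors", {
  cfg <- task_config()
  log <- run_trial(cfg, null_controller())
  expect_false(log$success)
  expect_true(all(log$samples$x == 0))
  bad <- as_controller(function(t) list(key_left = as.numeric(t > 1),
                                        key_right = rep(0, length(t))))
  expect_error(run_trial(cfg, bad), "controller contract")
})

test_that("sampling grid, determinism and the planet chain all hold", {
  cfg <- task_config(n_trials = 20)
  pol <- make_policy(controller_params(timing_sd = 0.12, lapse_prob = 0.1))
  s1 <- run_session(cfg, pol, seed = 7)
  s2 <- run_session(cfg, pol, seed = 7)
  expect_identical(s1, s2)

  for (tr in s1$trials) {
    for (a in unique(tr$samples$attempt)) {
      t <- tr$samples$t[tr$samples$attempt == a]
      if (length(t) > 1) {
        expect_true(all(abs(diff(t) - 1 / cfg$sample_rate) < 1e-9))
      }
    }
  }

  p <- s1$planets
  for (i in seq_len(nrow(p) - 1)) {
    if (p$success[i]) {
      expect_identical(p$start_planet[i + 1], p$target_planet[i])
    } else {
      expect_identical(p$start_planet[i + 1], p$start_planet[i])
      expect_identical(p$target_planet[i + 1], p$target_planet[i])
    }
  }

  # an all-success session visits a fresh pair every trial
  s3 <- run_session(task_config(n_trials = 10), bang_bang_controller(), seed = 1)
  expect_identical(s3$planets$start_planet, 1:10)
  expect_identical(s3$planets$target_planet, 2:11)

  # velocity is exactly conserved over key-free intervals
  tr <- s1$trials[[1]]$samples
  idle <- which(!tr$key_left & !tr$key_right)
  runs <- split(idle, cumsum(c(1, diff(idle) != 1)))
  for (r in runs) {
    if (length(r) > 1) expect_true(all(diff(tr$v[r]) == 0))
  }
})

test_that("task config invariants are enforced", {
  expect_error(task_config(trial_duration = 5), "hold_duration \\+ movement_window")
  expect_error(task_config(landing_duration = 4), "landing_duration")
  expect_error(task_config(planet_radius = 0.6), "planet_radius")
  expect_error(task_config(sample_rate = 0), "sample_rate|numeric|finite")
})
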