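# Independent oracle: literal evaluation of the hindrance polynomial.
renkin_oracle <- function(l)
  (1 - l)^2 * (1 - 2.104 * l + 2.09 * l^3 - 0.95 * l^5)

test_that("Renkin hindrance matches direct polynomial evaluation", {
  expect_equal(renkin_hindrance(0), 1)
  lam <- 0.37 / 15  # 0.37 nm molecule in a 30 nm pore
  expect_equal(renkin_hindrance(lam), renkin_oracle(lam), tolerance = 1e-12)
  expect_equal(renkin_hindrance(lam), 0.902, tolerance = 1e-3)
  # strictly decreasing on the validity range, bounded in [0, 1]
  grid <- seq(0, 0.4, by = 0.01)
  h <- renkin_hindrance(grid)
  expect_true(all(diff(h) < 0))
  expect_true(all(h >= 0 & h <= 1))
  expect_warning(h9 <- renkin_hindrance(0.9), "validity")
  expect_gte(h9, 0)
  expect_error(renkin_hindrance(1), "does not fit")
  expect_error(renkin_hindrance(-0.1))
})

test_that("effective diffusivity applies the hindrance to D_bulk", {
  p <- release_params(D_bulk = 1e-6)
  expect_equal(effective_diffusivity(p, 30),
               1e-6 * renkin_oracle(0.37 / 15), tolerance = 1e-12)
  expect_equal(effective_diffusivity(p, 30), 9.018e-7, tolerance = 1e-3)
  # wide-pore limit approaches free diffusion
  expect_equal(effective_diffusivity(p, 1e7), 1e-6, tolerance = 1e-6)
  expect_error(effective_diffusivity(p, 2 * p$r_molecule), "exceed")
  expect_true(effective_diffusivity(release_params(), 50) <
                release_params()$D_bulk)
})

test_that("mechanistic constant is calibrated at 75 nm and weakly size-dependent", {
  expect_equal(higuchi_constant(d = 75, mode = "mechanistic"), 9.5,
               tolerance = 1e-12)
  K30 <- higuchi_constant(d = 30, mode = "mechanistic")
  K150 <- higuchi_constant(d = 150, mode = "mechanistic")
  # the Renkin correction alone gives only ~4% spread over 30-150 nm:
  # the ratio equals the square root of the hindrance ratio
  expect_equal(K150 / K30,
               sqrt(renkin_oracle(0.37 / 75) / renkin_oracle(0.37 / 15)),
               tolerance = 1e-12)
  expect_equal(K150 / K30, 1.04, tolerance = 0.01)
  # increasing in d and porosity, decreasing in tortuosity
  expect_true(K150 > K30)
  p_hi_eps <- release_params(porosity = 0.45)
  expect_gt(higuchi_constant(p_hi_eps, 75), 9.5)
  p_hi_tau <- release_params(tortuosity = 3)
  expect_lt(higuchi_constant(p_hi_tau, 75), 9.5)
})

test_that("empirical constant reproduces the reference power law", {
  # independent oracle: hand least squares on the log-log pairs
  x <- log(RELEASE_REFERENCE$pore_diameter_nm)
  y <- log(RELEASE_REFERENCE$K_pct)
  p_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(p_hat, 0.446, tolerance = 1e-3)
  K_fit <- higuchi_constant(d = RELEASE_REFERENCE$pore_diameter_nm,
                            mode = "empirical")
  expect_equal(unname(log(K_fit)),
               unname(mean(y) + p_hat * (x - mean(x))), tolerance = 1e-10)
  # fit residuals are small: all five constants within ~5%
  expect_true(all(abs(K_fit / RELEASE_REFERENCE$K_pct - 1) < 0.05))
  expect_error(higuchi_constant(d = 75, mode = "nope"))
})

test_that("time-to-fraction inverts the square-root law", {
  expect_equal(time_to_fraction(8, 0.5), 39.0625)
  expect_equal(round(time_to_fraction(8, 0.5), 1), 39.1)
  expect_equal(round(time_to_fraction(14, 0.9), 1), 41.3)
  expect_equal(time_to_fraction(100, 0.5), 0.25)
  expect_error(time_to_fraction(8, 1.5), "exceed")
  expect_error(time_to_fraction(0, 0.5))
  # t90/t50 = (90/50)^2 = 3.24 exactly, for any K
  for (K in c(0.5, 6.8, 9.5, 14, 120))
    expect_equal(time_to_fraction(K, 0.9) / time_to_fraction(K, 0.5), 3.24)
})

test_that("release profiles are square-root shaped, monotone and capped", {
  t_grid <- seq(0, 200, by = 0.5)
  pr <- release_profile(8, t_grid)
  expect_equal(pr$Q_pct[1], 0)
  expect_true(all(diff(pr$Q_pct) >= 0))
  expect_true(all(pr$Q_pct <= 100))
  expect_equal(pr$Q_pct[pr$time_h == 1], 8)    # Q(1 h) = K
  # Q(t50) = 50% by construction
  for (K in c(6.8, 9.5, 14)) {
    t50 <- time_to_fraction(K, 0.5)
    expect_equal(release_profile(K, c(0, t50))$Q_pct[2], 50)
  }
  # Q^2 is linear in t below the cap
  below <- pr$Q_pct < 100
  fit <- lm(I(Q_pct^2) ~ time_h, data = data.frame(time_h = pr$time_h[below],
                                                   Q_pct = pr$Q_pct[below]))
  expect_equal(unname(coef(fit)[2]), 64, tolerance = 1e-9)
})

test_that("the release table reproduces the reference kinetics rows", {
  tab <- release_table()
  r50 <- tab[tab$pore_diameter_nm == 50, ]
  expect_equal(r50$t50_h, 39.1)
  expect_equal(r50$t90_h, 126.6)
  expect_equal(r50$initial_rate_pct_h, 8)
  r150 <- tab[tab$pore_diameter_nm == 150, ]
  expect_equal(r150$t50_h, 12.8)
  expect_equal(r150$t90_h, 41.3)
  expect_equal(r150$initial_rate_pct_h, 14)
  expect_equal(tab$rate_slope_1h_pct_h, round(RELEASE_REFERENCE$K_pct / 2, 1))
  expect_equal(nrow(release_table(RELEASE_REFERENCE[0, ])), 0)
  expect_warning(release_table(RELEASE_REFERENCE[c(1, 1), ]), "duplicate")
})

test_that("t50 sensitivity follows the closed-form proportionalities", {
  s <- t50_sensitivity(d = 75, delta = 0.1)
  tab <- s$table
  # t50 is proportional to tortuosity: change is exactly +/- delta
  expect_equal(tab$change_up_pct[tab$parameter == "tortuosity"], 10,
               tolerance = 1e-9)
  expect_equal(tab$change_down_pct[tab$parameter == "tortuosity"], -10,
               tolerance = 1e-9)
  # t50 is inversely proportional to D: +10% D -> -9.09% t50
  expect_equal(tab$change_up_pct[tab$parameter == "D"], 100 * (1 / 1.1 - 1),
               tolerance = 1e-9)
  expect_equal(tab$change_up_pct[tab$parameter == "porosity"],
               100 * (1 / 1.1 - 1), tolerance = 1e-9)
  expect_equal(s$envelope_pct, 100 * (1 / 0.9 - 1), tolerance = 1e-9)
  s0 <- t50_sensitivity(d = 75, delta = 0)
  expect_equal(s0$envelope_pct, 0)
  expect_error(t50_sensitivity(d = 75, delta = 1.2))
})
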