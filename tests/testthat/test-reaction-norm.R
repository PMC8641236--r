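test_that("Legendre basis and its derivative match closed forms", {
  tt <- seq(-5, 35, length.out = 11)
  b <- c(-5, 35)
  x <- 2 * (tt - b[1]) / (b[2] - b[1]) - 1
  phi <- legendre_basis(tt, order = 2, bounds = b)
  expect_equal(phi[, 1], rep(1, 11))
  expect_equal(phi[, 2], x)
  expect_equal(phi[, 3], (3 * x^2 - 1) / 2)
  # derivative includes the standardization Jacobian 2/(tmax - tmin)
  d <- legendre_basis(tt, order = 2, bounds = b, derivative = TRUE)
  jac <- 2 / (b[2] - b[1])
  expect_equal(d[, 1], rep(0, 11))
  expect_equal(d[, 2], rep(jac, 11))
  expect_equal(d[, 3], 3 * x * jac)
})

test_that("noise-free quadratic curves are recovered to numerical precision", {
  set.seed(1)
  n_an <- 30; k <- 12
  an <- rep(sprintf("a%02d", 1:n_an), each = k)
  temp <- rep(seq(0, 30, length.out = k), n_an)
  co <- cbind(rnorm(n_an, 2, 0.5), rnorm(n_an, 0, 0.1),
              rnorm(n_an, 0, 0.02))
  phi <- legendre_basis(temp, 2, bounds = c(0, 30))
  recs <- data.frame(animal = an, farm = "F1", lactation = 1,
                     year_lambing = 2010, month_lambing = 1, dim = 50,
                     temperature = temp,
                     milk = rowSums(phi * co[rep(1:n_an, each = k), ]),
                     date = 1)
  fit <- fit_reaction_norms(recs, order = 2, bounds = c(0, 30))
  expect_lt(max(abs(fit$coefs[sprintf("a%02d", 1:n_an), ] - co)), 1e-6)
  # slopes equal the hand-computed derivative of each individual curve
  sl <- slopes_at(fit, c(10, 25))
  for (tt in c(10, 25)) {
    dphi <- legendre_basis(tt, 2, c(0, 30), derivative = TRUE)
    want <- drop(co %*% t(dphi))
    got <- sl[[sprintf("slope_T%g", tt)]][match(sprintf("a%02d", 1:n_an),
                                                sl$animal)]
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("slope conventions: intercept-only animals are flat, order-1
           slopes are constant, extrapolation warns", {
  set.seed(2)
  n_an <- 25; k <- 10
  an <- rep(sprintf("b%02d", 1:n_an), each = k)
  temp <- rep(seq(2, 28, length.out = k), n_an)
  lev <- rnorm(n_an, 2, 0.5)
  recs <- data.frame(animal = an, farm = "F1", lactation = 1,
                     year_lambing = 2010, month_lambing = 1, dim = 50,
                     temperature = temp,
                     milk = lev[rep(1:n_an, each = k)] + rnorm(n_an * k, 0, 0.01),
                     date = 1)
  fit <- fit_reaction_norms(recs, order = 2)
  sl <- slopes_at(fit, c(10, 25))
  expect_lt(max(abs(sl$slope_T10)), 0.005)  # flat curves: slope ~ 0
  # order-1: identical slope at every temperature
  recs$milk <- recs$milk + 0.05 * recs$temperature
  fit1 <- fit_reaction_norms(recs, order = 1)
  sl1 <- slopes_at(fit1, c(5, 10, 25))
  expect_equal(sl1$slope_T5, sl1$slope_T10)
  expect_equal(sl1$slope_T10, sl1$slope_T25)
  expect_warning(slopes_at(fit1, 99), "extrapolated")
})

test_that("fitted slopes are calibrated against the simulated truth", {
  sim <- shared_sim()
  fit <- fit_reaction_norms(sim$records, order = 2)
  sl <- slopes_at(fit, c(10, 25))
  m <- merge(sl, sim$truth$animals, by = "animal")
  r <- lm(m$true_slope_T25 ~ m$slope_T25)
  co <- summary(r)$coefficients[2, ]
  expect_lt(abs(co[1] - 1), 3 * co[2])
  # sign contract for strong-signal animals
  strong <- abs(m$true_slope_T25) > 2 * sd(m$true_slope_T25)
  agree <- sign(m$slope_T25[strong]) == sign(m$true_slope_T25[strong])
  expect_gte(mean(agree), 0.95)
})

test_that("adding a constant to all yields shifts no slope", {
  sim <- shared_sim()
  recs <- sim$records
  f1 <- fit_reaction_norms(recs, order = 2)
  recs$milk <- recs$milk + 5
  f2 <- fit_reaction_norms(recs, order = 2)
  s1 <- slopes_at(f1, c(10, 25))
  s2 <- slopes_at(f2, c(10, 25))
  # identical up to optimizer noise, far below the slope scale (~0.02)
  expect_lt(max(abs(s1$slope_T10 - s2$slope_T10)), 1e-5)
  expect_lt(max(abs(s1$slope_T25 - s2$slope_T25)), 1e-5)
})

test_that("lifetime traits follow the test-interval computation", {
  recs <- data.frame(animal = "x", farm = "F1", lactation = 1L,
                     year_lambing = 2010, month_lambing = 1,
                     dim = c(10, 40), temperature = 15,
                     milk = c(2, 2), date = as.Date("2010-01-01") + c(10, 40))
  lt <- lifetime_traits(recs)
  expect_equal(lt$lifetime_milk, 2 * 10 + 2 * 30)  # hand oracle
  expect_equal(lt$productive_days, 31)
  # zero yields give zero lifetime milk
  recs0 <- recs; recs0$milk <- 0
  expect_equal(lifetime_traits(recs0)$lifetime_milk, 0)
  # two identical animals, identical outputs
  recs2 <- rbind(recs, transform(recs, animal = "y"))
  lt2 <- lifetime_traits(recs2)
  expect_equal(lt2$lifetime_milk[1], lt2$lifetime_milk[2])
  # single record with zero DIM: default 30-day interval
  one <- data.frame(animal = "z", farm = "F1", lactation = 1L,
                    year_lambing = 2010, month_lambing = 1, dim = 0,
                    temperature = 15, milk = 3,
                    date = as.Date("2010-05-01"))
  lt3 <- lifetime_traits(one)
  expect_equal(lt3$lifetime_milk, 3 * 30)
  expect_equal(lt3$productive_days, 1)
})
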