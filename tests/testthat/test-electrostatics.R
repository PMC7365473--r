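test_that("pair energy follows the screened Coulomb closed form", {
  p <- electro_params()
  expect_equal(screened_pair_energy(0, 2, 1, p), 0)
  expect_equal(screened_pair_energy(2, -2, 0.5, p),
               -4 * p$bjerrum_nm / 0.5 * exp(-0.5 / 1.3))
  expect_error(screened_pair_energy(1, 1, 0, p), "singularity")
  expect_error(screened_pair_energy(1, 1, -1, p), "singularity")
})

test_that("energy of like charges decreases monotonically with screening", {
  ldh <- c(Inf, 5, 2, 1.3, 0.8, 0.4)
  e <- vapply(ldh, function(l)
    screened_pair_energy(2, 2, 1.1, electro_params(screening_length_nm = l)),
    numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("chain energy is a literal double sum (linearity, single sites)", {
  p <- electro_params(cutoff_nm = Inf)
  one <- function(x, z, q) tibble::tibble(x_nm = x, z_nm = z, charge = q)
  expect_equal(chain_interaction_energy(one(0, 0, 2), one(2, 1.5, -2), p),
               screened_pair_energy(2, -2, sqrt(2^2 + 1.5^2), p))

  a1 <- one(0, c(0, 1), c(2, -2))
  a2 <- one(0, c(5, 7), c(2, 2))
  b <- one(2, c(0.5, 3, 6), c(-2, 2, -2))
  expect_equal(chain_interaction_energy(dplyr::bind_rows(a1, a2), b, p),
               chain_interaction_energy(a1, b, p) +
                 chain_interaction_energy(a2, b, p))

  expect_error(chain_interaction_energy(one(0, 0, 2), one(0, 0, 2), p),
               "coincident")
})

test_that("straight-pair placement matches the stated geometry", {
  ch <- random_chain(50, 3)
  p <- electro_params()
  par0 <- place_straight_pair(ch, ch, "parallel", 0, p)
  expect_equal(par0$b$z_nm, par0$a$z_nm)      # axially aligned pairwise
  expect_equal(unique(par0$b$x_nm), 2)

  l <- rod_length(ch)
  anti <- place_straight_pair(ch, ch, "antiparallel", l, p)
  expect_equal(anti$overlap_max_nm, 0)
  # zero overlap: nearest cross-pair distance equals the lateral separation
  dmin <- min(sqrt(outer(anti$a$x_nm, anti$b$x_nm, "-")^2 +
                     outer(anti$a$z_nm, anti$b$z_nm, "-")^2))
  expect_equal(dmin, 2)

  # overlap convention: equal-length rods at stagger s overlap L - s
  s <- 20 * rod_spacing_nm
  expect_equal(place_straight_pair(ch, ch, "antiparallel", s, p)$overlap_max_nm,
               l - s)
  expect_error(place_straight_pair(ch, ch, "antiparallel", -1, p),
               "negative")
})

test_that("stagger scans match the brute-force double sum", {
  p <- electro_params()
  pinf <- electro_params(cutoff_nm = Inf)
  a <- random_chain(60, 21)
  b <- random_chain(60, 22)
  for (orient in c("parallel", "antiparallel")) {
    sc <- stagger_scan(a, b, orient, 0, 2, s_step = 0.5, params = pinf)
    brute <- vapply(sc$stagger_nm, function(s) {
      pr <- place_straight_pair(a, b, orient, s, pinf)
      naive_pair_energy(pr$a, pr$b, pinf)
    }, numeric(1))
    expect_equal(sc$energy_kbt, brute, tolerance = 1e-12)
    # with the default cutoff too
    sc2 <- stagger_scan(a, b, orient, 0, 2, s_step = 0.5, params = p)
    brute2 <- vapply(sc2$stagger_nm, function(s) {
      pr <- place_straight_pair(a, b, orient, s, p)
      naive_pair_energy(pr$a, pr$b, p)
    }, numeric(1))
    expect_equal(sc2$energy_kbt, brute2, tolerance = 1e-12)
  }
})

test_that("neutral chains give an identically zero scan", {
  z <- as_chain(rep(0, 80))
  sc <- stagger_scan(z, z, "parallel", 0, 5, s_step = 1)
  expect_true(all(sc$energy_kbt == 0))
  expect_error(stagger_scan(z, z, "parallel", 5, 0), "empty")
})

test_that("parallel scans of identical chains are exchange-symmetric", {
  a <- synthetic_rod(n_sites = 260, tip_sites = 15, label = "x")
  s <- seq(0, 10, by = 1.456)
  e1 <- stagger_scan(a, a, "parallel", 0, 10, 1.456)$energy_kbt
  # exchanging which rod is shifted: shift the first instead of the second
  p <- electro_params()
  e2 <- vapply(s, function(si) {
    pr <- place_straight_pair(a, a, "parallel", si, p)
    chain_interaction_energy(pr$b, pr$a, p)
  }, numeric(1))
  expect_equal(e1, e2)
})

test_that("default cutoff agrees with the uncut sum to below 1e-3 kBT", {
  a <- random_chain(1000, 31)
  b <- random_chain(1000, 32)
  cut <- electro_params()                 # 12 * lDH
  uncut <- electro_params(cutoff_nm = Inf)
  for (s in c(0, 7.28, 50.96)) {
    pr <- place_straight_pair(a, b, "parallel", s, cut)
    d <- abs(chain_interaction_energy(pr$a, pr$b, cut) -
               chain_interaction_energy(pr$a, pr$b, uncut))
    expect_lt(d, 1e-3)
  }
})

test_that("local minima are strict minima, with optional smoothing", {
  sc <- structure(
    tibble::tibble(stagger_nm = 0:8,
                   energy_kbt = c(5, 3, 4, 2, 2, 6, 1, 7, 0)),
    class = c("stagger_scan", class(tibble::tibble())))
  m <- scan_minima(sc)
  expect_equal(m$stagger_nm, c(1, 6)) # plateaus and endpoints excluded
  expect_equal(nrow(scan_minima(sc[1:2, ])), 0)
})

test_that("potential field superposes the point-charge solution", {
  p <- electro_params()
  single <- as_chain(2)
  f <- potential_field(single, r_nm = 1.5, z_nm = c(0, 2), params = p)
  expect_equal(f$phi_kbt_e[1],
               2 * p$bjerrum_nm / 1.5 * exp(-1.5 / 1.3))
  expect_equal(f$phi_kbt_e[2],
               2 * p$bjerrum_nm / 2.5 * exp(-2.5 / 1.3))

  ch <- random_chain(40, 41)
  neg <- ch
  neg$charge <- -neg$charge
  z <- seq(-1, 7, by = 2)
  f1 <- potential_field(ch, 2, z, p)
  f2 <- potential_field(neg, 2, z, p)
  expect_equal(f1$phi_kbt_e + f2$phi_kbt_e, rep(0, length(z)))
  expect_error(potential_field(ch, 0, z, p), "r_nm")
})
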