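test_that("arc bending energy follows lp*La/(2R^2)", {
  expect_equal(bending_energy(130, 0), 0)
  expect_equal(bending_energy(Inf, 25), 0)
  expect_equal(bending_energy(130, 20, 130), 130 * 20 / (2 * 130^2))
  expect_error(bending_energy(0, 10), "radius")
  expect_error(bending_energy(-5, 10), "radius")
  expect_error(bending_energy(100, -1), "arc")
  # monotone: stiffer curvature costs more, longer arcs cost more
  expect_true(all(diff(bending_energy(seq(75, 300, 25), 20)) < 0))
  expect_true(all(diff(bending_energy(100, seq(0, 40, 5))) > 0))
})

test_that("straight sentinel reproduces the straight pair placement", {
  ch <- toy_rod(150)
  p <- electro_params()
  pr <- place_straight_pair(ch, ch, "antiparallel", 5, p)
  bent <- bent_rod_coordinates(ch, "antiparallel", 5, overlap_nm = 4,
                               radius_nm = Inf, arc_nm = 0, params = p,
                               partner_length_nm = rod_length(ch))
  expect_equal(bent$x_nm, pr$b$x_nm)
  expect_equal(bent$z_nm, pr$b$z_nm)
})

test_that("bent path is tangent-continuous with the prescribed arc angle", {
  ch <- toy_rod(300)
  p <- electro_params()
  R <- 80; La <- 20; lo <- 10
  for (orient in c("parallel", "antiparallel")) {
    b <- bent_rod_coordinates(ch, orient, 8, lo, R, La, p, rod_length(ch))
    # direction change between first and last polyline segments past the
    # bend equals La / R
    fr_dz <- if (orient == "parallel") -1 else 1
    contour <- rod_length(ch) - ch$position_nm
    ord <- order(contour)
    x <- b$x_nm[ord]; z <- b$z_nm[ord]
    seg <- cbind(diff(x), diff(z))
    ang <- atan2(seg[, 1], fr_dz * seg[, 2]) # 0 along the straight part
    expect_equal(ang[1], 0)
    expect_equal(max(ang), La / R, tolerance = 1e-6)
    # lateral distance from the partner axis never decreases along the path
    expect_true(all(diff(b$x_nm[ord]) > -1e-12))
  }
})

test_that("overlong arcs are clamped with a warning", {
  ch <- toy_rod(150) # ~21.7 nm rod
  expect_warning(
    bent_rod_coordinates(ch, "antiparallel", 2, 5, 80, 40,
                         electro_params(), rod_length(ch)),
    "clamped")
  expect_error(
    bent_rod_coordinates(ch, "antiparallel", 2, 50, 80, 20,
                         electro_params(), rod_length(ch)),
    "overlap_nm")
})

test_that("optimize_bend equals exhaustive enumeration on toy chains", {
  a <- toy_rod(220)
  b <- synthetic_rod(n_sites = 220, tip_sites = 30, label = "b2")
  p <- electro_params()
  w <- wlc_params(radius_steps = 3, arc_steps = 3)
  for (case in list(list("parallel", 6, 10), list("antiparallel", 10, 8),
                    list("antiparallel", 4, 15))) {
    orient <- case[[1]]; s <- case[[2]]; lo <- case[[3]]
    got <- optimize_bend(a, b, orient, s, lo, p, w)
    # independent enumeration via coordinates + brute-force energy
    grid <- expand.grid(R = w$radius_grid, La = w$arc_grid)
    apts <- tibble::tibble(x_nm = 0, z_nm = a$position_nm, charge = a$charge)
    etot <- mapply(function(R, La) {
      bp <- suppressWarnings(bent_rod_coordinates(b, orient, s, lo, R, La,
                                                  p, rod_length(a)))
      La_eff <- min(La, max(rod_length(b) -
        (if (orient == "parallel")
           max(0, s + rod_length(b) - rod_length(a)) else 0) - lo, 0))
      outer_pair_energy(apts, bp, p) + 130 * La_eff / (2 * R^2)
    }, grid$R, grid$La)
    expect_equal(got$e_total_kbt, min(etot), tolerance = 1e-9)
  }
})

test_that("neutral chains: straight candidate wins at full overlap", {
  z <- as_chain(rep(0, 400))
  got <- optimize_bend(z, z, "parallel", 2.912,
                       overlap_nm = rod_length(z) - 2.912)
  expect_true(got$straight)
  expect_equal(got$e_total_kbt, 0)
  # below full overlap the rod must leave its partner: minimal arc energy
  got2 <- optimize_bend(z, z, "parallel", 2.912, overlap_nm = 5)
  expect_false(got2$straight)
  expect_equal(got2$e_total_kbt, bending_energy(300, 15, 130))
})

test_that("energy landscape masks inaccessible cells and decomposes energies", {
  a <- toy_rod(200)
  p <- electro_params()
  w <- wlc_params(radius_steps = 3, arc_steps = 3)
  ls1 <- energy_landscape(a, a, "antiparallel", c(5, 15), 14, p, w)
  expect_tibble(ls1, c("stagger_nm", "lo_nm", "accessible", "e_total_kbt"))
  acc <- ls1[ls1$accessible, ]
  expect_equal(acc$e_total_kbt, acc$e_bend_kbt + acc$e_elec_kbt)
  lmax <- rod_length(a) - unique(ls1$stagger_nm)
  for (i in seq_len(nrow(ls1))) {
    lm <- lmax[match(ls1$stagger_nm[i], unique(ls1$stagger_nm))]
    expect_equal(ls1$accessible[i], ls1$lo_nm[i] <= lm + 1e-9)
  }
  expect_true(all(is.na(ls1$e_total_kbt[!ls1$accessible])))
  # each accessible column reaches exactly L_max
  top <- dplyr::summarise(dplyr::group_by(acc, stagger_nm),
                          m = max(lo_nm))
  expect_equal(top$m, lmax[match(top$stagger_nm, unique(ls1$stagger_nm))])
})

test_that("landscape fast path equals the per-cell reference optimizer", {
  a <- toy_rod(200)
  b <- synthetic_rod(n_sites = 200, tip_sites = 25, block_stride = 5,
                     label = "b")
  p <- electro_params()
  w <- wlc_params(radius_steps = 4, arc_steps = 3)
  for (orient in c("parallel", "antiparallel")) {
    ls1 <- energy_landscape(a, b, orient, c(4.368, 11.648), 21, p, w)
    acc <- ls1[ls1$accessible, ]
    for (i in seq_len(nrow(acc))) {
      ref <- optimize_bend(a, b, orient, acc$stagger_nm[i], acc$lo_nm[i],
                           p, w)
      expect_equal(acc$e_total_kbt[i], ref$e_total_kbt, tolerance = 1e-8)
      expect_equal(acc$radius_nm[i], ref$radius_nm)
    }
  }
})

test_that("minimization never exceeds the straight-rod energy at full overlap", {
  b <- synthetic_rod(n_sites = 240, tip_sites = 25, label = "b")
  p <- electro_params()
  for (s in c(2.912, 14.56)) {
    pr <- place_straight_pair(b, b, "antiparallel", s, p)
    e_straight <- chain_interaction_energy(pr$a, pr$b, p)
    cell <- optimize_bend(b, b, "antiparallel", s, pr$overlap_max_nm, p)
    expect_lte(cell$e_total_kbt, e_straight + 1e-9)
  }
})

test_that("overlap potential extracts the stored landscape column", {
  a <- toy_rod(200)
  ls1 <- energy_landscape(a, a, "antiparallel", c(5, 15), 14,
                          wlc = wlc_params(radius_steps = 3, arc_steps = 3))
  v <- overlap_potential(ls1, 15)
  s_used <- attr(v, "stagger_nm")
  col <- ls1[ls1$accessible & abs(ls1$stagger_nm - s_used) < 1e-9, ]
  col <- col[order(col$lo_nm), ]
  expect_equal(v$energy_kbt, col$e_total_kbt)
  expect_equal(attr(v, "overlap_max_nm"), max(col$lo_nm))
  expect_error(overlap_potential(ls1, 40), "outside")
  expect_message(overlap_potential(ls1, 14.8), "nearest")
})
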