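test_that("pair_table enumerates weighted pairs once", {
  m <- two_atom_model(2.8)
  pt <- pair_table(m)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$rij, 2.8)
  expect_equal(pt$weight, 1)           # single-element composition

  toy <- make_toy_cluster()
  expect_equal(nrow(pair_table(toy)), 18 * 17 / 2)

  # mixed composition: Ag-Cl pairs lighter than Ag-Ag when f(Ag) > f(Cl)
  ptt <- pair_table(toy)
  el <- toy$element
  agag <- ptt$weight[el[ptt$i] == "Ag" & el[ptt$j] == "Ag"][1]
  agcl <- ptt$weight[el[ptt$i] == "Ag" & el[ptt$j] == "Cl" |
                       el[ptt$i] == "Cl" & el[ptt$j] == "Ag"][1]
  fbar <- mean(element_weight(el))
  expect_equal(agag, 47 * 47 / fbar^2)
  expect_equal(agcl, 47 * 17 / fbar^2)
  expect_lt(agcl, agag)

  co <- cluster_model(data.frame(element = "Ag", x = c(0, 1e-8), y = 0, z = 0))
  expect_error(pair_table(co), class = "clusterpdf_degenerate_geometry_error")
})

test_that("calc_pdf places and widens peaks as specified", {
  m <- two_atom_model(2.80)
  curve <- calc_pdf(m, default_rgrid(0, 6))
  expect_equal(curve$r[which.max(curve$g)], 2.80, tolerance = 1e-8)
  expect_equal(curve$g[1], 0)          # defined 0 at r = 0

  # biso 0.5 + 0.5 -> sigma = sqrt(1/(8 pi^2)) in quadrature with the floor
  mb <- two_atom_model(2.80, biso = 0.5)
  sig_expected <- sqrt(1 / (8 * pi^2) + 0.05^2)
  pk <- calc_pdf(mb, default_rgrid(0, 6))
  # half-max width of the r*G product recovers sigma
  y <- pk$g * pk$r
  half <- which(y > max(y) / 2)
  fwhm <- (max(half) - min(half) + 1) * 0.01
  expect_equal(fwhm, 2 * sqrt(2 * log(2)) * sig_expected, tolerance = 0.03)

  # uniform coordinate scaling doubles the peak position (up to the small
  # 1/r skew of an isolated peak, and to peak-overlap changes in a cluster)
  pr1 <- find_peaks(calc_pdf(two_atom_model(2.8), default_rgrid(0, 14)), 0.2)
  pr2 <- find_peaks(calc_pdf(two_atom_model(5.6), default_rgrid(0, 14)), 0.2)
  expect_equal(pr2, 2 * pr1, tolerance = 1e-3)
  toy <- make_toy_cluster()
  doubled <- toy
  doubled$x <- toy$x * 2; doubled$y <- toy$y * 2; doubled$z <- toy$z * 2
  p1 <- find_peaks(calc_pdf(toy, default_rgrid(0, 14)), 0.2)
  p2 <- find_peaks(calc_pdf(doubled, default_rgrid(0, 28)), 0.2)
  expect_lt(abs(p2[1] - 2 * p1[1]), 0.03)
})

test_that("calc_pdf matches the brute-force oracle on random models", {
  rg <- default_rgrid(0, 20)
  for (seed in 1:20) {
    n <- sample(5:30, 1)
    m <- random_model(n, seed = 1000 + seed)
    expect_lt(max(abs(calc_pdf(m, rg)$g - oracle_pdf(m, rg))), 1e-8)
  }
})

test_that("calc_pdf is permutation invariant and conserves peak area", {
  m <- random_model(12, seed = 9)
  rg <- default_rgrid(0, 20)
  set.seed(2)
  perm <- m[sample(nrow(m)), ]
  expect_lt(max(abs(calc_pdf(m, rg)$g -
                      calc_pdf(cluster_model(perm), rg)$g)), 1e-10)

  # isolated pair: integral of r G(r) = 2 s w, independent of sigma
  for (biso in c(0, 0.5, 2)) {
    mp <- two_atom_model(5, biso = biso)
    cv <- calc_pdf(mp, default_rgrid(0, 10), scale = 1.7)
    expect_equal(sum(cv$g * cv$r) * 0.01, 2 * 1.7, tolerance = 1e-3)
  }
})

test_that("rw matches hand-evaluated cases and scale properties", {
  rg <- default_rgrid(1, 2)
  set.seed(3)
  a <- pdf_curve(rg, runif(length(rg), 0.5, 1))
  expect_equal(rw(a, a), 0)
  expect_equal(rw(a, pdf_curve(rg, rep(0, length(rg)))), 1)

  two <- pdf_curve(c(0, 0.01), c(1, 0))
  expect_equal(rw(two, pdf_curve(c(0, 0.01), c(0, 0))), 1)
  expect_equal(rw(two, pdf_curve(c(0, 0.01), c(1, 1))), 1)

  b <- pdf_curve(rg, a$g * 0.8 + 0.1)
  expect_equal(rw(a, b), rw(pdf_curve(rg, 3 * a$g), pdf_curve(rg, 3 * b$g)))

  # scale-refined misfit is the minimum over s of rw(obs, s * calc)
  s_hat <- sum(a$g * b$g) / sum(b$g^2)
  rw_min <- rw(a, pdf_curve(rg, s_hat * b$g))
  for (s in c(0.5, 0.9, 1.5)) {
    expect_gte(rw(a, pdf_curve(rg, s * b$g)), rw_min - 1e-12)
  }

  zero <- pdf_curve(rg, rep(0, length(rg)))
  expect_error(rw(zero, a), class = "clusterpdf_division_error")
})

test_that("linear_combination weights and validates", {
  rg <- default_rgrid(0, 5)
  c1 <- pdf_curve(rg, sin(rg))
  expect_equal(linear_combination(list(c1), 1)$g, c1$g)
  expect_equal(linear_combination(list(c1, c1), c(0.5, 0.5))$g, c1$g)

  c2 <- pdf_curve(rg, cos(rg))
  mix <- linear_combination(list(c1, c2), c(3, 1))
  expect_equal(mix$g, 0.75 * c1$g + 0.25 * c2$g)

  other <- pdf_curve(default_rgrid(0, 4), sin(default_rgrid(0, 4)))
  expect_error(linear_combination(list(c1, other), c(1, 1)),
               class = "clusterpdf_validation_error")
  # the decamer composition: A:C:G:T = 3:4:2:1
  expect_equal(unname(table(strsplit("CACCTAGCGA", "")[[1]])[c("A", "C", "G", "T")]),
               c(3L, 4L, 2L, 1L), ignore_attr = TRUE)
})

test_that("find_peaks locates well-separated Gaussians with refinement", {
  rg <- default_rgrid(0, 8)
  g <- dnorm(rg, 2.80, 0.1) + 0.8 * dnorm(rg, 5.00, 0.12)
  peaks <- find_peaks(pdf_curve(rg, g), 0.05)
  expect_length(peaks, 2)
  expect_equal(peaks, c(2.80, 5.00), tolerance = 1e-3)

  expect_length(find_peaks(pdf_curve(rg, rep(1, length(rg))), 0.05), 0)

  # off-grid center recovered by parabolic interpolation
  g2 <- dnorm(rg, 2.804, 0.1)
  expect_equal(find_peaks(pdf_curve(rg, g2), 0.05), 2.804, tolerance = 5e-4)
})

test_that("coherence_length brackets the last real feature", {
  toy <- make_toy_cluster()
  dmax <- max(dist(coords(toy)))
  curve <- calc_pdf(toy, default_rgrid(0, 25))
  cl <- coherence_length(curve, noise_floor = 0.02 * max(abs(curve$g)))
  expect_lt(cl["r_high"], dmax + 1)
  expect_gt(cl["r_high"], 0.6 * dmax)

  single <- calc_pdf(two_atom_model(2.8), default_rgrid(0, 10))
  ci <- coherence_length(single, noise_floor = 0.1 * max(single$g))
  expect_gt(ci["r_low"], 2.0)
  expect_lt(ci["r_high"], 3.6)

  flat <- pdf_curve(default_rgrid(0, 10), rep(1e-6, 1001))
  expect_error(coherence_length(flat, noise_floor = 1),
               class = "clusterpdf_undefined_coherence_error")
})

test_that("an 18-atom cluster with max pair distance ~11 A bounds coherence in 10-12 A", {
  # dumbbell fixture: two Ag9 cubes-plus-centre whose farthest corners are
  # 11 A apart, so the last PDF feature sits just under 11 A
  cube <- expand.grid(x = c(-1.4, 1.4), y = c(-1.4, 1.4), z = c(-1.4, 1.4))
  blob <- rbind(cube, data.frame(x = 0, y = 0, z = 0))
  sep <- sqrt(11^2 - 2 * 2.8^2) - 2.8
  m <- cluster_model(tibble::tibble(
    element = "Ag",
    x = c(blob$x, blob$x + sep), y = c(blob$y, blob$y), z = c(blob$z, blob$z),
    biso = 0.5))
  dmax <- max(dist(coords(m)))
  expect_equal(dmax, 11, tolerance = 1e-9)
  curve <- calc_pdf(m, default_rgrid(0, 25))
  cl <- coherence_length(curve, noise_floor = 0.02 * max(abs(curve$g)))
  expect_gte(cl[["r_high"]], 10)
  expect_lte(cl[["r_high"]], 12)
})
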