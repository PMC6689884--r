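# Lipophilicity potential, surface scoring, and the logG/R statistic.

test_that("kernels are normalized, monotone, and cut off", {
  d <- seq(0, 12, by = 0.25)
  for (k in list(weighting_kernel("exponential"),
                 weighting_kernel("audry"))) {
    w <- kernel_weight(k, d)
    expect_equal(w[1], 1)
    expect_true(all(diff(w) <= 0))
    expect_true(all(w[d >= k$cutoff] == 0))
  }
  expect_equal(kernel_weight(weighting_kernel("exponential", lambda = 1.5),
                             1.5), exp(-1))
  expect_equal(kernel_weight(weighting_kernel("audry"), 3), 0.25)
})

test_that("the potential is the direct distance-weighted contribution sum", {
  # single atom at the evaluation point
  p1 <- single_atom_particle(r = 1.7, f = 1)
  for (k in list(weighting_kernel("exponential"), weighting_kernel("audry"))) {
    expect_equal(mlp_at_point(c(0, 0, 0), p1, k), 1.0)
  }

  # antisymmetric pair, equidistant point
  pair <- vgnp_from_atoms(data.frame(element = "C", x = c(-2, 2), y = 0,
                                     z = 0, vdw = 1.7, f = c(1, -1)))
  expect_equal(mlp_at_point(c(0, 1.3, 0), pair, weighting_kernel()), 0)

  # 5 random atoms, random points: direct summation oracle
  p <- random_particle(5, seed = 8)
  pts <- matrix(vgnp:::with_seed(9, runif(9, -6, 6)), ncol = 3)
  k <- weighting_kernel("exponential", lambda = 1.5, cutoff = 10)
  expected <- apply(pts, 1, function(x) {
    d <- sqrt((x[1] - p$atoms$x)^2 + (x[2] - p$atoms$y)^2 +
                (x[3] - p$atoms$z)^2)
    sum(p$atoms$f * ifelse(d >= 10, 0, exp(-d / 1.5)))
  })
  expect_equal(mlp_at_point(pts, p, k), expected, tolerance = 1e-12)
})

test_that("surface scoring splits intensity by sign", {
  # three isolated atoms, surface points at their centres: mlp = f exactly
  atoms <- data.frame(element = "C", x = c(0, 30, 60), y = 0, z = 0,
                      vdw = 1.7, f = c(2, -1, 0.5))
  p <- vgnp_from_atoms(atoms)
  sas <- fake_sas(cbind(c(0, 30, 60), 0, 0))
  s <- score_surface(sas, p, weighting_kernel(cutoff = 10))
  expect_equal(s$mlp, c(2, -1, 0.5))
  expect_equal(s$i_g, 2.5)
  expect_equal(s$i_r, 1)
  expect_equal(s$i_g + s$i_r, sum(abs(s$mlp)))

  # all-positive contributions leave the hydrophilic channel empty
  pos <- random_particle(10, seed = 3)
  pos$atoms$f <- abs(pos$atoms$f)
  spos <- score_surface(identify_sas_points(pos, h = 0.8), pos,
                        weighting_kernel())
  expect_equal(spos$i_r, 0)
  expect_gt(spos$i_g, 0)
})

test_that("negating every contribution swaps the channels exactly", {
  p <- random_particle(20, seed = 5)
  sas <- identify_sas_points(p, h = 0.8)
  s <- score_surface(sas, p, weighting_kernel())
  q <- p
  q$atoms$f <- -q$atoms$f
  sneg <- score_surface(identify_sas_points(q, h = 0.8), q,
                        weighting_kernel())
  expect_identical(sneg$i_g, s$i_r)
  expect_identical(sneg$i_r, s$i_g)
  expect_identical(log_g_over_r(sneg), -log_g_over_r(s))
})

test_that("logG/R is the base-10 log of the intensity ratio", {
  mk <- function(i_g, i_r) {
    structure(list(points = NULL, mlp = NULL, i_g = i_g, i_r = i_r,
                   kernel = weighting_kernel(), grid = NULL),
              class = "scored_surface")
  }
  expect_equal(log_g_over_r(mk(3.7, 3.7)), 0)
  expect_equal(log_g_over_r(mk(100, 1)), 2)
  err <- tryCatch(log_g_over_r(mk(5, 0)), condition = identity)
  expect_s3_class(err, "vgnp_degenerate_surface")
  expect_equal(err$i_g, 5)
  expect_equal(err$i_r, 0)
  expect_error(log_g_over_r(mk(0, 0)), class = "vgnp_degenerate_surface")
  # clamping substitutes eps = 1e-6 * total intensity
  expect_warning(v <- log_g_over_r(mk(5, 0), clamp = TRUE), "clamping")
  expect_equal(v, log10(5 / (1e-6 * 5)))
  expect_warning(v2 <- log_g_over_r(mk(0, 5), clamp = TRUE), "clamping")
  expect_equal(v2, -6)
})

test_that("logG/R is invariant under rigid motion up to grid effects", {
  p <- random_particle(20, seed = 6)
  k <- weighting_kernel()
  base <- log_g_over_r(score_surface(identify_sas_points(p, h = 0.8), p, k))
  vals <- vgnp:::with_seed(41, vapply(1:10, function(i) {
    R <- vgnp:::random_rotation()
    shift <- runif(3, -2, 2)
    xyz <- as.matrix(p$atoms[, c("x", "y", "z")]) %*% t(R)
    q <- p
    q$atoms$x <- xyz[, 1] + shift[1]
    q$atoms$y <- xyz[, 2] + shift[2]
    q$atoms$z <- xyz[, 3] + shift[3]
    log_g_over_r(score_surface(identify_sas_points(q, h = 0.8), q, k))
  }, numeric(1)))
  expect_true(all(abs(vals - base) < 0.05))
})

test_that("the exponential kernel is local: the truncation error vanishes with the cutoff", {
  p <- random_particle(20, seed = 7)
  sas <- identify_sas_points(p, h = 0.8)
  lgr <- function(cut) {
    log_g_over_r(score_surface(sas, p, weighting_kernel(cutoff = cut)))
  }
  # atoms beyond the cutoff contribute exactly zero
  far <- p
  far$atoms <- rbind(far$atoms,
                     data.frame(element = "C", x = 100, y = 0, z = 0,
                                vdw = 1.7, f = 50, ligand_id = NA, copy = NA))
  expect_identical(log_g_over_r(score_surface(sas, far, weighting_kernel())),
                   lgr(10))
  # truncation error decays with the cutoff; once the tail weight is
  # negligible (~13 lambda), doubling the cutoff moves logG/R by < 1e-3
  e10 <- abs(lgr(10) - lgr(40))
  e15 <- abs(lgr(15) - lgr(40))
  e20 <- abs(lgr(20) - lgr(40))
  expect_gt(e10, e15)
  expect_gte(e15, e20)
  expect_lt(abs(lgr(20) - lgr(40)), 1e-3)
})
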