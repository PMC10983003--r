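test_that("one-center repulsion is the IP/EA difference", {
  expect_equal(oneCenterRepulsion("C.sp2"), 11.16 - 0.03)
  tab <- defaultValenceTable()
  for (k in tab$key) expect_gt(oneCenterRepulsion(k), 0)
  expect_error(oneCenterRepulsion("Si.sp2"), "unsupported")
})

test_that("two-center repulsion interpolates between known limits", {
  # r -> 0: the arithmetic mean of the one-center values
  g0 <- twoCenterRepulsion("C.sp2", "C.sp2", 0)
  expect_equal(g0, oneCenterRepulsion("C.sp2"), tolerance = 1e-12)
  gmix <- twoCenterRepulsion("C.sp2", "N.pyridine", 0)
  expect_equal(gmix, (oneCenterRepulsion("C.sp2") + oneCenterRepulsion("N.pyridine")) / 2)
  # large r: bare Coulomb law within 2%
  expect_equal(twoCenterRepulsion("C.sp2", "C.sp2", 10), 14.397 / 10,
               tolerance = 0.02)
  # strictly decreasing, positive, bounded by the one-center scale
  r <- seq(0, 8, by = 0.25)
  vals <- twoCenterRepulsion("C.sp2", "C.sp2", r)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= oneCenterRepulsion("C.sp2")))
  expect_error(twoCenterRepulsion("C.sp2", "C.sp2", -1), "negative")
})

test_that("Slater 2p overlap matches 3D quadrature over the distance grid", {
  tab <- defaultValenceTable()
  zs <- sort(unique(round(tab$zeta, 6)))
  pairs <- rbind(t(combn(zs, 2)), cbind(zs, zs))
  set.seed(42)
  for (r in c(0.8, 1.4, 2.4, 3.6, 5.0)) {
    for (p in sample(nrow(pairs), 4)) {
      za <- pairs[p, 1]; zb <- pairs[p, 2]
      for (orient in c("pi", "sigma")) {
        exact <- slater2pOverlap(za, zb, r, orient)
        quad <- slaterOverlapQuadrature(za, zb, r, orient)
        expect_equal(exact, quad, tolerance = 1e-6, ignore_attr = TRUE,
                     label = sprintf("S_%s(%.3f,%.3f,%.1f)", orient, za, zb, r))
      }
    }
  }
})

test_that("overlap limits: self-overlap one, long-range decay, |S| <= 1", {
  expect_equal(slater2pOverlap(1.28, 1.28, 0, "pi"), 1.0)
  expect_lt(abs(slater2pOverlap(1.28, 1.28, 50, "pi")), 1e-6)
  rs <- seq(0, 6, by = 0.1)
  for (orient in c("pi", "sigma")) {
    S <- vapply(rs, function(r) slater2pOverlap(1.28, 2.45, r, orient), 0)
    expect_true(all(abs(S) <= 1 + 1e-12))
  }
})

test_that("spline overlap tracks the exact recursion", {
  za <- defaultValenceTable()$zeta[1]
  # grid node reproduces the exact value; mid-grid within 1e-4
  expect_equal(splineOverlap(za, za, 1.50, "pi"),
               slater2pOverlap(za, za, 1.50, "pi"), tolerance = 1e-12)
  expect_equal(splineOverlap(za, za, 1.45, "pi"),
               slater2pOverlap(za, za, 1.45, "pi"), tolerance = 1e-4)
  # out of grid falls back to exact
  expect_equal(splineOverlap(za, za, 8.0, "pi"),
               slater2pOverlap(za, za, 8.0, "pi"), tolerance = 1e-15)
})

test_that("resonance integral is negative, cosine-attenuated, zero at 90 deg", {
  b0 <- resonanceIntegral("C.sp2", "C.sp2", 1.40, theta = 0)
  expect_lt(b0, 0)
  expect_equal(resonanceIntegral("C.sp2", "C.sp2", 1.40, theta = 90), 0,
               tolerance = 1e-12)
  expect_equal(resonanceIntegral("C.sp2", "C.sp2", 1.40, theta = 60), b0 * 0.5,
               tolerance = 1e-12)
  # |beta| decreasing on [0, 90]
  bs <- vapply(seq(0, 90, 10), function(th)
    abs(resonanceIntegral("C.sp2", "C.sp2", 1.40, theta = th)), 0)
  expect_true(all(diff(bs) <= 1e-12))
})

test_that("benzene Hueckel spectrum from the core matrix has textbook ordering", {
  g <- ringPolygon(6L, 1.397)
  ps <- perceivePiSystem(g)
  params <- buildParameterSet(ps, g)
  hk <- huckelGuess(params)
  alpha <- params$Hcore[1, 1]
  beta <- params$beta[1, 2]
  expected <- sort(alpha + beta * c(2, 1, 1, -1, -1, -2))
  expect_equal(hk$eps, expected, tolerance = 1e-8)
  expect_lt(beta, 0)   # bonding combination lowest
})

test_that("parameter assembly has the right sparsity and equivariance", {
  g <- pentaleneD2h()
  ps <- perceivePiSystem(g)
  params <- buildParameterSet(ps, g)
  expect_equal(params$n, 8L)
  expect_true(isSymmetric(params$gamma))
  expect_true(isSymmetric(params$Hcore))
  expect_equal(sum(params$beta[upper.tri(params$beta)] != 0), 9L)  # 9 bonds
  expect_true(all(diag(params$gamma) >= params$gamma - 1e-12))
  # permutation equivariance: eigenvalues of Hcore unchanged
  set.seed(3)
  perm <- sample(8L)
  g2 <- permuteAtoms(g, perm)
  params2 <- buildParameterSet(perceivePiSystem(g2), g2)
  expect_equal(eigen(params2$Hcore, symmetric = TRUE)$values,
               eigen(params$Hcore, symmetric = TRUE)$values, tolerance = 1e-10)
  # rigid-motion invariance of every matrix
  g3 <- applyRotation(g, randomRotation(5), shift = c(2, 2, -7))
  params3 <- buildParameterSet(perceivePiSystem(g3), g3)
  expect_equal(params3$gamma, params$gamma, tolerance = 1e-9)
  expect_equal(params3$beta, params$beta, tolerance = 1e-9)
})
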