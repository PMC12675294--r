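test_that("Chamfer family equals exhaustive brute-force oracles", {
  set.seed(51)
  for (rep in 1:100) {
    m <- sample(2:10, 1); mp <- sample(2:10, 1)
    Y <- randomCloud(m, with_normals = TRUE)
    Yp <- randomCloud(mp, with_normals = TRUE)
    expect_equal(chamfer(Y, Yp)$total, bruteChamfer(Y$points, Yp$points),
                 tolerance = 1e-12)
    expect_equal(weightedChamfer(Y, Yp)$total,
                 bruteWeightedChamfer(Y$points, Y$weights, Yp$points,
                                      Yp$weights),
                 tolerance = 1e-12)
    expect_equal(chamferNormals(Y, Yp, w_n = 0.02)$total,
                 bruteNcd(Y$points, Y$normals, Yp$points, Yp$normals, 0.02),
                 tolerance = 1e-12)
    expect_equal(pointToPlaneChamfer(Y, Yp)$total,
                 brutePcd(Y$points, Y$normals, Yp$points, Yp$normals),
                 tolerance = 1e-12)
  }
})

test_that("measure structure: symmetry, zero on identical clouds,
           decomposition", {
  set.seed(52)
  Y <- randomCloud(9, with_normals = TRUE)
  Yp <- randomCloud(7, with_normals = TRUE)
  expect_equal(chamfer(Y, Yp)$total, chamfer(Yp, Y)$total,
               tolerance = 1e-12)
  for (fn in list(chamfer, weightedChamfer,
                  function(a, b) chamferNormals(a, b, 0.01),
                  pointToPlaneChamfer)) {
    r <- fn(Y, Y)
    expect_equal(r$total, 0)
    r2 <- fn(Y, Yp)
    expect_gte(r2$total, 0)
    expect_equal(r2$total, r2$forward_term + r2$backward_term,
                 tolerance = 1e-9)
    expect_true(all(r2$pointwise_forward >= 0))
    expect_true(all(r2$pointwise_backward >= 0))
  }
  # single-point pair: CD = 1 + 1
  expect_equal(chamfer(weightedPointCloud(rbind(c(0, 0, 0))),
                       weightedPointCloud(rbind(c(1, 0, 0))))$total, 2)
})

test_that("NCD limits: w_n = 0 reduces to CD; antiparallel normals at
           coincident points add 4 w_n", {
  set.seed(53)
  Y <- randomCloud(8, with_normals = TRUE)
  Yp <- randomCloud(6, with_normals = TRUE)
  expect_equal(chamferNormals(Y, Yp, w_n = 0)$total, chamfer(Y, Yp)$total,
               tolerance = 1e-15)
  # convergence NCD -> CD as w_n -> 0
  gaps <- vapply(c(1e-1, 1e-3, 1e-6), function(w)
    abs(chamferNormals(Y, Yp, w)$total - chamfer(Y, Yp)$total), numeric(1))
  expect_true(all(diff(gaps) < 0))
  a <- weightedPointCloud(rbind(c(0.5, 0.5, 0.5)),
                          normals = rbind(c(0, 0, 1)))
  b <- weightedPointCloud(rbind(c(0.5, 0.5, 0.5)),
                          normals = rbind(c(0, 0, -1)))
  expect_equal(chamferNormals(a, b, w_n = 0.25)$total, 4 * 0.25)
})

test_that("point-to-plane: tangential displacement is invisible", {
  n <- rbind(c(0, 0, 1))
  a <- weightedPointCloud(rbind(c(0.2, 0.2, 0.5)), normals = n)
  b <- weightedPointCloud(rbind(c(0.7, 0.4, 0.5)), normals = n)
  r <- pointToPlaneChamfer(a, b)
  expect_equal(r$total, 0)
})

test_that("FLD/BLD are unsquared nearest-neighbour distances, in cm when
           inverted", {
  set.seed(54)
  a <- randomCloud(15); b <- randomCloud(12)
  fb <- fldBld(a, b)
  expect_equal(fb$fld, bruteNnDist(a$points, b$points), tolerance = 1e-12)
  expect_equal(fb$bld, bruteNnDist(b$points, a$points), tolerance = 1e-12)
  idr <- fldBld(a, a)
  expect_equal(idr$max_fld, 0)
  expect_equal(idr$max_bld, 0)
  # rigid offset on a well-separated cloud
  sep <- weightedPointCloud(cbind(seq(0, 9), 0, 0))
  off <- weightedPointCloud(sweep(sep$points, 2, c(0.3, 0, 0), "+"))
  expect_equal(fldBld(off, sep)$max_fld, 0.3, tolerance = 1e-12)
  # cm reporting through the stored inverse transform
  tf <- fitUnitCube(weightedPointCloud(matrix(runif(30, 0, 10), 10, 3)))
  fbcm <- fldBld(a, b, inverse_transform = tf)
  expect_equal(fbcm$fld,
               bruteNnDist(invertUnitCube(tf, a$points),
                           invertUnitCube(tf, b$points)),
               tolerance = 1e-12)
})

test_that("bidirectional error is the sum of the two directional calls", {
  set.seed(55)
  S <- randomCloud(10); T_ <- randomCloud(10)
  # identity map
  be <- bidirectionalError(S, T_, S, T_, measure = "cd")
  expect_equal(be$total, chamfer(S, T_)$total + chamfer(T_, S)$total)
  expect_equal(be$total, 2 * chamfer(S, T_)$total, tolerance = 1e-12)
  expect_equal(bidirectionalError(S, S, S, S)$total, 0)
})

test_that("Chamfer-family position gradients match central differences", {
  set.seed(56)
  A <- randomCloud(6, with_normals = TRUE)
  B <- randomCloud(5, with_normals = TRUE)
  h <- 1e-7
  cfgs <- list(list(measure = "cd", w_n = 0), list(measure = "cdw", w_n = 0),
               list(measure = "pcd", w_n = 0))
  fns <- list(cd = chamfer, cdw = weightedChamfer,
              pcd = pointToPlaneChamfer)
  for (cf in cfgs) {
    g <- vascuflow:::chamferGradFirst(A, B, measure = cf$measure)
    fn <- fns[[cf$measure]]
    for (i in c(1, 4)) for (d in 1:3) {
      ap <- A; ap$points[i, d] <- ap$points[i, d] + h
      am <- A; am$points[i, d] <- am$points[i, d] - h
      num <- (fn(ap, B)$total - fn(am, B)$total) / (2 * h)
      expect_equal(g[i, d], num, tolerance = 1e-5,
                   label = sprintf("%s grad [%d,%d]", cf$measure, i, d))
    }
  }
})
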