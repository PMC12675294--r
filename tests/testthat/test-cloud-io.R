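test_that("mesh to cloud: centroids, area weights and normals", {
  # single triangle: centroid, unit weight, +z normal
  m1 <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                    rbind(c(1, 2, 3)))
  cl1 <- meshToCloud(m1)
  expect_equal(cl1$points[1, ], c(1 / 3, 1 / 3, 0))
  expect_equal(cl1$weights, 1)
  expect_equal(cl1$normals[1, ], c(0, 0, 1))

  # regular tetrahedron: 4 equal faces -> weight 0.25 each
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tet <- surfaceMesh(v, rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3),
                              c(2, 3, 4)))
  clt <- meshToCloud(tet)
  expect_true(tet$closed)
  expect_equal(clt$weights, rep(0.25, 4))

  # tube with unequal cells vs an independent cross-product oracle
  spec <- vesselSpec(rbind(c(0, 0, 0), c(0.4, 0.1, 2), c(0, 0, 4)),
                     radius = c(0.5, 0.8, 0.4), n_circ = 8, n_long = 10)
  tube <- makeTube(spec)
  cl <- meshToCloud(tube)
  oracleAreas <- vapply(seq_len(nrow(tube$triangles)), function(f) {
    a <- tube$vertices[tube$triangles[f, 1], ]
    b <- tube$vertices[tube$triangles[f, 2], ]
    cc <- tube$vertices[tube$triangles[f, 3], ]
    e1 <- b - a; e2 <- cc - a
    0.5 * sqrt(sum(c(e1[2] * e2[3] - e1[3] * e2[2],
                     e1[3] * e2[1] - e1[1] * e2[3],
                     e1[1] * e2[2] - e1[2] * e2[1])^2))
  }, numeric(1))
  expect_equal(cl$weights, oracleAreas / sum(oracleAreas), tolerance = 1e-12)
  expect_lt(abs(sum(cl$weights) - 1), 1e-12)

  # degenerate triangle is refused with its index
  bad <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                           c(0, 1, 0)),
                     rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_error(meshToCloud(bad), "zero-area.*1")
})

test_that("weighted cloud invariants are enforced", {
  expect_error(weightedPointCloud(matrix(0, 0, 3)), "empty")
  expect_error(weightedPointCloud(diag(3), c(1, -1, 1)), "positive")
  cl <- weightedPointCloud(diag(3), c(5, 3, 2))
  expect_lt(abs(sum(cl$weights) - 1), 1e-12)
  cl2 <- weightedPointCloud(diag(3), normals = diag(3) * 4)
  expect_equal(sqrt(rowSums(cl2$normals^2)), rep(1, 3), tolerance = 1e-12)
})

test_that("unit cube fit maps the cohort into the margin box and inverts", {
  set.seed(31)
  pts <- cbind(runif(40, -2, 2), runif(40, 0, 1), runif(40, 5, 6))
  pts[1, ] <- c(-2, 0, 5); pts[2, ] <- c(2, 1, 6)   # pin the bbox
  cl <- weightedPointCloud(pts)
  tf <- fitUnitCube(cl, margin = 0)
  mapped <- applyUnitCube(tf, cl)
  expect_equal(apply(mapped$points, 2, min), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(apply(mapped$points, 2, max), c(1, 1, 1), tolerance = 1e-12)
  # margin case over a cohort
  cl2 <- weightedPointCloud(matrix(runif(30, 2, 3), 10, 3))
  tfm <- fitUnitCube(list(cl, cl2), margin = 0.1)
  allp <- rbind(applyUnitCube(tfm, cl)$points,
                applyUnitCube(tfm, cl2)$points)
  expect_true(all(allp >= 0.1 - 1e-12 & allp <= 0.9 + 1e-12))
  # round trip
  back <- invertUnitCube(tfm, applyUnitCube(tfm, cl))
  expect_equal(back$points, cl$points, tolerance = 1e-10)
  # degenerate axis: constant z
  flat <- weightedPointCloud(cbind(runif(5), runif(5), 2))
  expect_warning(tfd <- fitUnitCube(flat), "degenerate")
  expect_equal(tfd$scale[3], 1)
})

test_that("cloud IO round-trips points, weights, normals and label", {
  set.seed(32)
  cl <- randomCloud(17, with_normals = TRUE, label = "fixture A")
  for (fmt in c("ply", "vtp", "rds")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    writeCloud(cl, path)
    back <- readCloud(path)
    expect_identical(back$points, cl$points, label = fmt)
    expect_identical(back$weights, cl$weights)
    expect_identical(back$normals, cl$normals)
    expect_identical(back$label, cl$label)
  }
  # PLY without weights falls back to uniform with a warning
  noW <- c("ply", "format ascii 1.0", "element vertex 2",
           "property double x", "property double y", "property double z",
           "end_header", "0 0 0", "1 1 1")
  p <- file.path(tempdir(), "now.ply")
  writeLines(noW, p)
  expect_warning(clW <- readCloud(p), "uniform")
  expect_equal(clW$weights, c(0.5, 0.5))
  # malformed files name the offending element
  writeLines(c("not a ply"), p)
  expect_error(readCloud(p), "magic|malformed")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property double x", "property double y",
               "property double z", "end_header", "0 0", "1 1 1"), p)
  expect_error(readCloud(p), "malformed")
  expect_error(readCloud("x.xyz"), "unknown")
})

test_that("PCA normal estimation recovers sphere normals outward", {
  set.seed(33)
  u <- matrix(rnorm(3 * 150), 150, 3)
  u <- u / sqrt(rowSums(u^2))
  cl <- estimateNormals(weightedPointCloud(u))
  agreement <- rowSums(cl$normals * u)     # true outward normal is u itself
  expect_gt(mean(agreement > 0.9), 0.95)
})
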