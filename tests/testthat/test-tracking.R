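test_that("DLC CSV writer and reader round-trip coordinates exactly", {
  set.seed(11)
  s <- makeSession(10)
  f <- withr::local_tempfile(fileext = ".csv")
  writeDLC(s, f)
  s2 <- readDLC(f, fps = 30)
  expect_equal(dim(s2@coords), c(10L, 5L, 3L))
  expect_lt(max(abs(s2@coords - s@coords)), 1e-6)
  expect_equal(frameTimes(s2), (0:9) / 30)
})

test_that("reader rejects malformed files with informative errors", {
  set.seed(12)
  s <- makeSession(5)
  f <- withr::local_tempfile(fileext = ".csv")
  writeDLC(s, f)

  ## missing body part
  txt <- readLines(f)
  txt[2] <- gsub("tail_base", "tailbase", txt[2])
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, f2)
  expect_error(readDLC(f2, fps = 30), "tail_base")
  ## ... unless mapped explicitly
  expect_s4_class(readDLC(f2, fps = 30, partMap = c(tail_base = "tailbase")),
                  "TrackingSession")

  ## non-numeric cell, reported with its row
  txt <- readLines(f)
  row4 <- strsplit(txt[6], ",")[[1]]
  row4[2] <- "oops"
  txt[6] <- paste(row4, collapse = ",")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, f3)
  expect_error(readDLC(f3, fps = 30), "row 3")

  ## not a DLC header at all
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "3,4"), f4)
  expect_error(readDLC(f4, fps = 30), "scorer")
})

test_that("head point is the mean of nose, ears and neck", {
  parts <- c("nose", "left_ear", "right_ear", "neck", "tail_base")
  arr <- array(0, dim = c(1, 5, 3),
               dimnames = list(NULL, parts, c("x", "y", "likelihood")))
  arr[1, "nose", 1:2] <- c(0, 0)
  arr[1, "left_ear", 1:2] <- c(2, 0)
  arr[1, "right_ear", 1:2] <- c(0, 2)
  arr[1, "neck", 1:2] <- c(2, 2)
  arr[1, , "likelihood"] <- 1
  h <- computeHead(trackingSession(arr, fps = 30))
  expect_equal(unname(h[1, ]), c(1, 1))

  arr[1, , "x"] <- 5
  arr[1, , "y"] <- 5
  h <- computeHead(trackingSession(arr, fps = 30))
  expect_equal(unname(h[1, ]), c(5, 5))

  ## brute-force oracle: per-coordinate averaging on random frames
  set.seed(13)
  s <- makeSession(50)
  h <- computeHead(s)
  hp <- c("nose", "left_ear", "right_ear", "neck")
  expect_lt(max(abs(h[, 1] - rowMeans(s@coords[, hp, "x"]))), 1e-9)
  expect_lt(max(abs(h[, 2] - rowMeans(s@coords[, hp, "y"]))), 1e-9)
})

test_that("low-likelihood frames are interpolated, unusable sessions refused", {
  set.seed(14)
  s <- makeSession(9)
  ## a clean linear track so interpolation is exactly recoverable
  for (p in dimnames(s@coords)[[2]]) {
    s@coords[, p, "x"] <- 1:9
    s@coords[, p, "y"] <- 2 * (1:9)
  }
  s@coords[5, "nose", "likelihood"] <- 0.1
  h <- computeHead(s, likelihoodFloor = 0.6)
  expect_equal(unname(h[5, ]), c(5, 10))
  expect_equal(attr(h, "interpolated"), 5L)

  s@coords[, "neck", "likelihood"] <- 0
  expect_error(computeHead(s, likelihoodFloor = 0.6), "unusable")
})

test_that("sessions are truncated to the analysis window", {
  parts <- c("nose", "left_ear", "right_ear", "neck", "tail_base")
  n <- 480 * 30
  arr <- array(1, dim = c(n, 5, 3),
               dimnames = list(NULL, parts, c("x", "y", "likelihood")))
  s <- trackingSession(arr, fps = 30)
  t465 <- truncateSession(s, 465)
  expect_equal(length(frameTimes(t465)), 13950L)
  expect_lt(max(frameTimes(t465)), 465)

  expect_warning(short <- truncateSession(t465, 600), "shorter")
  expect_equal(length(frameTimes(short)), 13950L)
  expect_error(truncateSession(s, 0), "positive")
})

test_that("points project onto the nearest arm axis with normalized distance", {
  geom <- defaultGeometry()
  pA <- projectPoint(geom@armEnds["A", ], geom)
  expect_equal(pA$arm, "A")
  expect_equal(pA$pos, 1)

  pC <- projectPoint(geom@center, geom)
  expect_equal(pC$pos, 0)

  ## 25% along arm B, verified against a hand distance computation
  q <- geom@center + 0.25 * (geom@armEnds["B", ] - geom@center)
  pB <- projectPoint(q, geom)
  expect_equal(pB$arm, "B")
  handPos <- sqrt(sum((q - geom@center)^2)) /
    sqrt(sum((geom@armEnds["B", ] - geom@center)^2))
  expect_equal(pB$pos, handPos)
  expect_equal(pB$pos, 0.25)
})

test_that("projection is invariant to rotating/scaling the whole scene", {
  set.seed(15)
  s <- makeSession(200)
  geom <- defaultGeometry()
  tr <- projectSession(s, geom)

  rot <- function(xy, th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy %*% t(R)
  }
  for (transform in list(
    function(xy) rot(xy, pi / 2),                    # 90 degree rotation
    function(xy) 2.5 * xy + rep(c(40, -17), each = nrow(xy))  # scale+shift
  )) {
    s2 <- s
    for (p in dimnames(s@coords)[[2]]) {
      s2@coords[, p, c("x", "y")] <- transform(s@coords[, p, c("x", "y")])
    }
    geom2 <- mazeGeometry(
      center = drop(transform(matrix(geom@center, 1))),
      armEnds = transform(geom@armEnds),
      armLengthCm = geom@armLengthCm
    )
    tr2 <- projectSession(s2, geom2)
    expect_equal(tr2@headArm, tr@headArm)
    expect_equal(tr2@headPos, tr@headPos, tolerance = 1e-9)
    expect_equal(tr2@tailPos, tr@tailPos, tolerance = 1e-9)
  }
})

test_that("maze geometry validity enforces the 120-degree layout", {
  ## arm C dragged 40 degrees off its slot
  ang <- c(90, 210, 290) * pi / 180
  ends <- cbind(300 + 360 * cos(ang), 300 + 360 * sin(ang))
  expect_error(mazeGeometry(c(300, 300), ends), "120")

  ## one arm much shorter than the others
  geom <- defaultGeometry()
  ends <- geom@armEnds
  ends["B", ] <- geom@center + 0.5 * (ends["B", ] - geom@center)
  expect_error(mazeGeometry(geom@center, ends), "inconsistent")

  expect_equal(pxPerCm(defaultGeometry()), 10)
})
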