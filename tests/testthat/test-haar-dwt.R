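test_that("filter bank invariants hold in every mode", {
  for (mode in c("raw", "orthonormal", "average")) {
    bank <- haar_filter_bank(mode)
    # detail kernels sum to zero, LL is constant positive
    expect_equal(sum(bank$w_lh), 0)
    expect_equal(sum(bank$w_hl), 0)
    expect_equal(sum(bank$w_hh), 0)
    expect_true(all(bank$w_ll > 0))
    expect_equal(length(unique(c(bank$w_ll))), 1L)
  }
  raw <- haar_filter_bank("raw")
  expect_true(all(unlist(raw[c("w_ll", "w_lh", "w_hl", "w_hh")]) %in% c(-1, 1)))

  ortho <- haar_filter_bank("orthonormal")
  K <- sapply(ortho[c("w_ll", "w_lh", "w_hl", "w_hh")], c)
  expect_equal(crossprod(K), diag(4), ignore_attr = TRUE)

  avg <- haar_filter_bank("average")
  expect_equal(avg$w_ll, matrix(0.25, 2, 2))
  expect_equal(avg$w_lh, haar_filter_bank("orthonormal")$w_lh)
})

test_that("dwt_level matches hand-computed 2x2 block coefficients", {
  # block [[1,2],[3,4]] read row-major
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  s <- dwt_level(x, haar_filter_bank("raw"))
  expect_equal(dim(s$data), c(1L, 1L, 4L))
  expect_equal(c(s$data[1, 1, ]), c(10, 4, 2, 0))
})

test_that("dwt_level output shape is (H/2, W/2, 4C) and 512x512x3 -> 256x256x12", {
  img <- array(0, c(512, 512, 3))
  s <- dwt_level(img)
  expect_equal(dim(s$data), c(256L, 256L, 12L))
  expect_equal(s$channel_order$subband[1:8],
               rep(c("LL", "LH", "HL", "HH"), 2))
})

test_that("detail subbands of a constant image vanish; raw LL is 4c", {
  for (mode in c("raw", "orthonormal", "average")) {
    img <- array(2.5, c(6, 8, 2))
    s <- dwt_level(img, haar_filter_bank(mode))
    details <- s$data[, , s$channel_order$subband != "LL"]
    expect_equal(max(abs(details)), 0)
  }
  s <- dwt_level(array(2.5, c(6, 8, 1)), haar_filter_bank("raw"))
  expect_equal(c(s$data[, , 1]), rep(10, 12))
})

test_that("dwt_level agrees with the brute-force oracle on random images", {
  set.seed(42)
  for (rep in 1:20) {
    h <- 2L * sample(2:6, 1); w <- 2L * sample(2:6, 1); C <- sample(1:3, 1)
    mode <- sample(c("raw", "orthonormal", "average"), 1)
    img <- random_image(h, w, C)
    bank <- haar_filter_bank(mode)
    expect_equal(dwt_level(img, bank)$data, oracle_dwt_level(img, bank),
                 tolerance = 1e-10)
  }
})

test_that("odd dimensions and empty input are rejected with axis named", {
  expect_error(dwt_level(matrix(0, 3, 4)), "rows")
  expect_error(dwt_level(matrix(0, 4, 5)), "cols")
  expect_error(dwt_level(array(0, c(0, 4, 1))), "empty")
  expect_error(dwt_level(matrix(c(NA, 1, 2, 3), 2)), "finite")
})

test_that("dwt_pyramid shapes follow the dyadic law and recursion matches the oracle", {
  img <- array(stats::runif(512 * 512 * 3), c(512, 512, 3))
  p <- dwt_pyramid(img, levels = 4)
  expect_length(p, 4L)
  shapes <- t(vapply(p, function(s) dim(s$data), integer(3)))
  expect_equal(shapes,
               cbind(c(256L, 128L, 64L, 32L), c(256L, 128L, 64L, 32L), 12L),
               ignore_attr = TRUE)

  set.seed(7)
  small <- random_image(16, 16, 1)
  bank <- haar_filter_bank("orthonormal")
  p3 <- dwt_pyramid(small, 3, bank)
  oracle <- oracle_dwt_pyramid(small, 3, bank)
  for (l in 1:3) expect_equal(p3[[l]]$data, oracle[[l]], tolerance = 1e-10)

  p1 <- dwt_pyramid(small, 1, bank)
  expect_equal(p1[[1]]$data, dwt_level(small, bank)$data)
})

test_that("infeasible pyramid depth errors state the maximum level count", {
  expect_error(dwt_pyramid(matrix(0, 24, 24), levels = 4), "at most 3")
})

test_that("orthonormal mode conserves energy (Parseval)", {
  set.seed(11)
  for (rep in 1:5) {
    img <- random_image(8, 8, sample(1:3, 1))
    s <- dwt_level(img, haar_filter_bank("orthonormal"))
    expect_equal(sum(subband_energy(s)), sum(img^2), tolerance = 1e-10)
  }
  # constant image: full pyramid level-1 energy equals input energy too
  img <- array(3, c(8, 8, 1))
  s <- dwt_level(img, haar_filter_bank("orthonormal"))
  expect_equal(sum(subband_energy(s)), sum(img^2), tolerance = 1e-12)
  expect_equal(unname(subband_energy(dwt_level(array(0, c(4, 4, 2))))),
               rep(0, 8))
})

test_that("average-mode LL equals stride-2 average pooling; raw is 4x that", {
  set.seed(13)
  img <- random_image(12, 10, 2)
  pooled <- avg_pool(img, window = 2, stride = 2, padding = "valid")
  avg <- dwt_level(img, haar_filter_bank("average"))
  raw <- dwt_level(img, haar_filter_bank("raw"))
  ll_idx <- avg$channel_order$subband == "LL"
  expect_equal(avg$data[, , ll_idx], pooled)
  expect_equal(raw$data[, , ll_idx], 4 * pooled)
})

test_that("dwt_level agrees with an external wavelet library on subband energies", {
  testthat::skip_if(Sys.which("python") == "", "python not available")
  set.seed(5)
  img <- matrix(round(stats::rnorm(16 * 16), 6), 16, 16)
  f <- tempfile(fileext = ".csv")
  utils::write.table(img, f, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- paste(
    "import sys, numpy as np, pywt",
    "x = np.loadtxt(sys.argv[1], delimiter=',')",
    "cA, (cH, cV, cD) = pywt.dwt2(x, 'haar')",
    "print(repr(float((cA**2).sum())))",
    "for c in (cH, cV, cD): print(repr(float((c**2).sum())))",
    sep = "\n")
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  out <- suppressWarnings(system2("python", c(sf, f), stdout = TRUE))
  skip_if(length(out) != 4, "pywt unavailable")
  ext <- as.numeric(out)
  s <- dwt_level(img, haar_filter_bank("orthonormal"))
  e <- subband_energy(s)
  # LL energies must match exactly; detail energies as a set (the external
  # library's H/V naming convention is the transpose of ours)
  expect_equal(unname(e["ch1.LL"]), ext[1], tolerance = 1e-10)
  expect_equal(sort(unname(e[c("ch1.LH", "ch1.HL", "ch1.HH")])),
               sort(ext[2:4]), tolerance = 1e-10)
})
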