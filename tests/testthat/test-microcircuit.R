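test_that("presynaptic sigmoid has the right midpoint, saturation and slope", {
  expect_equal(presynaptic_rate(syn0$eta, syn0), 0.5)
  expect_equal(presynaptic_rate(1e4, syn0), 1)
  expect_equal(presynaptic_rate(-1e4, syn0), 0)
  v <- seq(-5, 5, length.out = 41)
  expect_true(all(diff(presynaptic_rate(v, syn0)) > 0))
  # derivative at the half-maximum point equals r/4 (finite differences)
  h <- 1e-6
  fd <- (presynaptic_rate(syn0$eta + h, syn0) -
           presynaptic_rate(syn0$eta - h, syn0)) / (2 * h)
  expect_equal(fd, syn0$r / 4, tolerance = 1e-8)
})

test_that("sigmoid gain matches the analytic slope and vanishes at saturation", {
  expect_equal(sigmoid_gain(syn0), 0.54 / 4, tolerance = 1e-12)
  s2 <- synaptic_params(r = 0.9, eta = 1.3)
  h <- 1e-6
  fd <- (presynaptic_rate(h, s2) - presynaptic_rate(-h, s2)) / (2 * h)
  expect_equal(sigmoid_gain(s2), fd, tolerance = 1e-7)
  expect_lt(sigmoid_gain(synaptic_params(eta = 50)), 1e-8)
  expect_lt(sigmoid_gain(synaptic_params(eta = -50)), 1e-8)
})

test_that("spatial kernel transform has its closed-form limits", {
  k <- 1.7
  d0 <- spatial_kernel_ft("a21", k, 0, conn0)
  al <- conn0$alpha[["a21"]]; cc <- conn0$c_decay[["a21"]]
  expect_equal(Im(d0), 0)
  expect_equal(Re(d0), al * cc / (cc^2 + k^2))
  expect_equal(spatial_kernel_ft("a21", 0, 0, conn0), complex(real = al / cc))
  expect_error(spatial_kernel_ft("a13", 1, 1, conn0), "unknown")
  expect_error(spatial_kernel_ft(c(1, 3), 1, 1, conn0), "structurally zero")
})

test_that("spatial kernel transform matches direct quadrature and is Hermitian", {
  set.seed(42)
  for (i in 1:12) {
    edge <- sample(cmc_edges()$edge, 1)
    k <- runif(1, -6, 6)
    w <- 2 * pi * runif(1, 2, 90)
    ana <- spatial_kernel_ft(edge, k, w, conn0)
    num <- kernel_quadrature(edge, k, w, conn0)
    expect_equal(ana, num, tolerance = 1e-6)
    expect_equal(spatial_kernel_ft(edge, k, -w, conn0), Conj(ana))
  }
})

test_that("spatial kernel is a monotone low-pass in wavenumber", {
  ks <- seq(0, 10, by = 0.5)
  for (edge in c("a11", "a14")) {
    mag <- Mod(sapply(ks, function(k) spatial_kernel_ft(edge, k, 0, conn0)))
    expect_true(all(diff(mag) < 0))
  }
})

test_that("coupling matrix has the microcircuit sparsity and sign pattern", {
  set.seed(7)
  conn <- random_conn()
  J <- jacobian_J(1.1, 2 * pi * 40, syn0, conn)
  zeros <- rbind(c(1, 3), c(2, 4), c(3, 1), c(3, 4), c(4, 2), c(4, 3))
  for (i in seq_len(nrow(zeros)))
    expect_identical(J[zeros[i, 1], zeros[i, 2]], 0 + 0i)
  e <- cmc_edges()
  J0 <- jacobian_J(0.7, 0, syn0, conn)      # real at omega = 0
  for (i in seq_len(nrow(e)))
    expect_gt(e$sign[i] * Re(J0[e$to[i], e$from[i]]), 0)
  # element-wise oracle
  for (i in seq_len(nrow(e))) {
    expect_equal(J[e$to[i], e$from[i]],
                 e$sign[i] * syn0$kappa[e$to[i]] * sigmoid_gain(syn0) *
                   spatial_kernel_ft(e$edge[i], 1.1, 2 * pi * 40, conn))
  }
  # degenerate (saturated) sigmoid removes all coupling
  Jd <- jacobian_J(1.1, 2 * pi * 40, synaptic_params(eta = 200), conn)
  expect_lt(max(Mod(Jd)), 1e-20 * max(Mod(J)))
})

test_that("transfer function reduces to the uncoupled synaptic filter", {
  tiny <- connectivity_params(alpha = setNames(rep(1e-9, 10),
                                               cmc_edges()$edge))
  w <- 2 * pi * 25
  tf <- transfer_matrix(0.4, w, syn0, tiny)
  k1 <- syn0$kappa[1]
  expect_equal(tf[1], k1 / (k1 + 1i * w)^2, tolerance = 1e-6)
  tf0 <- transfer_matrix(0, 0, syn0, tiny)
  expect_equal(Mod(tf0[1]), 1 / k1, tolerance = 1e-6)
})

test_that("matrix and closed-form transfer routes agree on random draws", {
  set.seed(11)
  worst <- 0
  for (i in 1:250) {
    syn <- random_syn()
    conn <- random_conn()
    k <- runif(1, -8, 8)
    w <- 2 * pi * runif(1, 1, 120)
    a <- transfer_matrix(k, w, syn, conn)
    b <- transfer_closed_form(k, w, syn, conn)
    worst <- max(worst, max(Mod(a - b)) / max(Mod(a)))
  }
  expect_lt(worst, 1e-8)
})

test_that("transfer functions are Hermitian in frequency and even in wavenumber", {
  g <- small_grid()
  for (k in c(0, 1.3)) for (f in c(12, 55)) {
    w <- 2 * pi * f
    expect_equal(transfer_matrix(k, -w, syn0, conn0),
                 Conj(transfer_matrix(k, w, syn0, conn0)))
    expect_equal(transfer_matrix(-k, w, syn0, conn0),
                 transfer_matrix(k, w, syn0, conn0))
  }
})

test_that("grid evaluation matches pointwise evaluation", {
  g <- small_grid(n_k = 8L)
  tg <- transfer_grid(g, syn0, conn0)
  for (ik in c(1L, 9L, 17L)) for (iw in c(1L, 5L)) {
    expect_equal(tg[, ik, iw],
                 transfer_matrix(g$wavenumbers[ik], g$omega[iw], syn0, conn0),
                 tolerance = 1e-10)
  }
})

test_that("prior-mean circuit is stable with a finite-frequency resonance", {
  g <- spectral_grid(seq(2, 120, by = 2), n_k = 32L)
  tg <- transfer_grid(g, syn0, conn0)
  expect_true(all(is.finite(Mod(tg))))
  m <- transfer_map(4L, g, syn0, conn0)
  k0 <- which(g$wavenumbers == 0)
  peak <- which.max(m[k0, ])
  expect_gt(peak, 1)
  expect_lt(peak, length(g$freqs))
  expect_gt(g$freqs[peak], 30)   # gamma-band resonance
  expect_lt(g$freqs[peak], 90)
})

test_that("transfer map is symmetric in wavenumber and matches |T|^2", {
  g <- small_grid(n_k = 6L)
  m <- transfer_map(4L, g, syn0, conn0)
  expect_equal(m, m[rev(seq_len(nrow(m))), ], ignore_attr = TRUE)
  tg <- transfer_grid(g, syn0, conn0)
  expect_equal(m, abs(tg[4L, , ])^2, ignore_attr = TRUE)
  expect_error(transfer_map(5L, g), "1..4")
})

test_that("parameter constructors validate their invariants", {
  expect_error(synaptic_params(kappa_ms = c(1, 1, 1)), "4 positive")
  expect_error(synaptic_params(r = -1), "positive")
  expect_error(connectivity_params(alpha = setNames(rep(-1, 10),
                                                    cmc_edges()$edge)))
  expect_error(spectral_grid(c(10, 5)), "strictly increasing")
  expect_error(spectral_grid(c(-1, 5)), "strictly increasing")
  g <- small_grid()
  expect_setequal(g$wavenumbers, -g$wavenumbers)  # closed under negation
  expect_false(any(duplicated(g$wavenumbers)))
})
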