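test_that("default priors carry the tabulated means in canonical units", {
  pri <- default_priors()
  m <- setNames(pri$mean, pri$name)
  expect_equal(m[["kappa1"]], 500)           # 1/2 per ms, stored per s
  expect_equal(m[["kappa2"]], 1000 / 35)
  expect_equal(m[["kappa3"]], 1000 / 35)
  expect_equal(m[["kappa4"]], 500)
  expect_equal(m[["c_a11"]], 2)              # self decay, 1/mm
  expect_equal(m[["c_a14"]], 0.6)            # cross decay
  expect_equal(m[["inv_speed"]], 1 / 300)    # 0.3 m/s = 0.3 mm/ms
  expect_equal(m[["r"]], 0.54)
  expect_equal(m[["alpha_a11"]], 108e3)
  expect_equal(m[["alpha_a23"]], 4536e3)
  expect_equal(m[["alpha_a44"]], 9e3)
  expect_equal(attr(pri, "conn")$patch_length, 25)
  # every free parameter appears exactly once
  expect_false(any(duplicated(pri$name)))
})

test_that("packing and unpacking are a lossless round trip", {
  pri <- default_priors()
  mod <- model_space()[[7L]]
  nm <- packed_names(pri, mod)
  set.seed(3)
  x <- setNames(rnorm(length(nm), 0, 0.3), nm)
  packed <- pack_params(x, pri, mod)
  expect_equal(packed, x)
  up <- unpack_params(packed, pri, mod)
  repacked <- pack_params(c(up$dev[pri$name[pri$free]],
                            setNames(up$beta,
                                     paste0("beta_", names(up$beta)))),
                          pri, mod)
  expect_equal(repacked, packed)
})

test_that("zero deviations reproduce the prior means exactly", {
  pri <- default_priors()
  up <- unpack_params(rep(0, sum(pri$free)), pri, cmc_model())
  expect_equal(up$syn$kappa, synaptic_params()$kappa)
  expect_equal(up$conn$alpha, connectivity_params()$alpha)
  expect_equal(up$conn$c_decay, connectivity_params()$c_decay)
  expect_equal(up$sensors$centres, sensor_model()$centres)
  expect_equal(up$noise$alpha_u, noise_params()$alpha_u)
})

test_that("a log-2 deviation doubles exactly one parameter", {
  pri <- default_priors()
  packed <- pack_params(c(alpha_a41 = log(2)), pri, cmc_model())
  up <- unpack_params(packed, pri, cmc_model())
  expect_equal(up$conn$alpha[["a41"]], 2 * default_alpha()[["a41"]])
  others <- setdiff(names(up$conn$alpha), "a41")
  expect_equal(up$conn$alpha[others], default_alpha()[others])
})

test_that("deviations on fixed parameters are rejected", {
  pri <- default_priors()
  expect_error(pack_params(c(r = 0.5), pri, cmc_model()), "fixed")
  expect_error(pack_params(c(nonsense = 1), pri, cmc_model()), "unknown")
})

test_that("condition effects are log-linear in the contrast covariate", {
  pri <- default_priors()
  mod <- model_space()[[1L]]               # G only
  des <- condition_design()
  b44 <- -0.5
  packed <- pack_params(c(beta_alpha_a44 = b44), pri, mod)
  th <- sapply(seq_along(des$covariate), function(cd)
    apply_condition_effects(packed, mod, des, cd, pri)$conn$alpha[["a44"]])
  lg <- log(th)
  u <- des$covariate
  expect_equal(diff(lg), b44 * diff(u))
  expect_equal(th[9] / th[1], exp(b44 * (u[9] - u[1])))
  # the 82% condition has covariate 0.82 under percentage coding
  expect_equal(u[9], 0.82)
  # no sensitivities: identical parameters in every condition
  p0 <- pack_params(numeric(0), pri, mod)
  for (cd in c(1L, 5L, 9L))
    expect_equal(apply_condition_effects(p0, mod, des, cd, pri)$conn,
                 unpack_params(p0, pri, mod)$conn)
  expect_error(apply_condition_effects(packed, mod, des, 10L, pri),
               "not in the design")
})

test_that("modulation of a parameter outside the model's set is an error", {
  pri <- default_priors()
  expect_error(pack_params(c(beta_alpha_a11 = 0.1), pri,
                           model_space()[[7L]]), "unknown")
  expect_error(pack_params(c(beta_c_a11 = 0.1), pri, model_space()[[1L]]),
               "unknown")
})

test_that("condition effects preserve positivity of scale parameters", {
  pri <- default_priors()
  mod <- model_space()[[7L]]
  set.seed(9)
  packed <- pack_params(setNames(rnorm(length(packed_names(pri, mod)), 0, 1),
                                 packed_names(pri, mod)), pri, mod)
  for (cd in c(1L, 9L)) {
    p <- apply_condition_effects(packed, mod, condition_design(), cd, pri)
    expect_true(all(p$conn$alpha > 0))
    expect_true(all(p$conn$c_decay > 0))
    expect_true(all(p$syn$kappa > 0))
  }
})

test_that("the factorial model space has 8 distinct models in the standard order", {
  sp <- model_space()
  expect_length(sp, 8L)
  key <- sapply(sp, function(m) paste(m$G, m$L, m$E))
  expect_false(any(duplicated(key)))
  expect_true(sum(sapply(sp, `[[`, "null")) == 1L)
  expect_true(sp[[8L]]$null)
  # single factors first, then gain+extent, couplings+extent, gain+couplings
  expect_equal(sp[[1L]]$modulated, paste0("alpha_", c("a33", "a44")))
  expect_equal(sort(sp[[2L]]$modulated),
               sort(paste0("alpha_", c("a14", "a12", "a21", "a23",
                                       "a41", "a32"))))
  expect_equal(sp[[3L]]$modulated, paste0("c_", cmc_edges()$edge))
  expect_true(sp[[6L]]$G && sp[[6L]]$L && !sp[[6L]]$E)  # all but extent
  expect_setequal(sp[[7L]]$modulated,
                  union(union(sp[[1L]]$modulated, sp[[2L]]$modulated),
                        sp[[3L]]$modulated))
})

test_that("the mass restriction collapses space and frees site gains", {
  massm <- mass_restriction(model_space()[[8L]])
  expect_equal(massm$variant, "mass")
  pri_f <- default_priors()
  pri_m <- default_priors(variant = "mass")
  expect_lt(sum(pri_m$free), sum(pri_f$free))
  m <- setNames(pri_m$mean, pri_m$name)
  expect_equal(m[["inv_speed"]], 0)        # point-like patch: no delays
  # predictions are invariant to electrode centres
  g <- small_grid(n_k = 8L)
  p1 <- predict_csd(g, sens0, noise0, syn0, conn0, variant = "mass")
  s2 <- sensor_model(centres = runif(8, 0, 25))
  p2 <- predict_csd(g, s2, noise0, syn0, conn0, variant = "mass")
  expect_equal(p1$values, p2$values)
})

test_that("condition designs support percentage and log-intensity coding", {
  d1 <- condition_design()
  expect_equal(d1$covariate, c(0, 5, 10, 16, 23, 32, 44, 60, 82) / 100)
  d2 <- condition_design(coding = "log")
  expect_equal(range(d2$covariate), c(0, 1))
  expect_true(all(diff(d2$covariate) > 0))
})
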