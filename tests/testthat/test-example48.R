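test_that("the printed CF fractions of the Na point are reproduced exactly", {
  # the exact rationals exceed the 2^53 double guard mid-computation, so
  # exactness is certified in two independent prime fields plus doubles
  want <- qcfnet:::.EX48_CF
  entries <- list(bc_bc = c("b1", "c1", "b2", "c2"),
                  ab_ab = c("a1", "b1", "a2", "b2"),
                  ac_ac = c("a1", "c1", "a2", "c2"),
                  ab_ac = c("a1", "b1", "a2", "c1"),
                  ab_bc = c("a1", "b1", "b2", "c1"),
                  ac_bc = c("a1", "c1", "b1", "c2"))
  for (p in GFP_PRIMES[1:2]) {
    pars <- lapply(qcfnet:::.EX48_NA, function(fr) qcfnet:::.gfp_rat(fr[1], fr[2], p))
    tab <- cf_table(make_named("Na"), params = pars)
    for (nm in names(entries)) {
      e <- entries[[nm]]
      expect_equal(cf_entry(tab, e[1], e[2], e[3], e[4])$v,
                   qcfnet:::.gfp_rat(want[[nm]][1], want[[nm]][2], p)$v,
                   label = nm)
    }
  }
  parsn <- lapply(qcfnet:::.EX48_NA, function(fr) fr[1] / fr[2])
  tabn <- cf_table(make_named("Na"), params = parsn)
  for (nm in names(entries)) {
    e <- entries[[nm]]
    expect_equal(rr_tonum(cf_entry(tabn, e[1], e[2], e[3], e[4])),
                 want[[nm]][1] / want[[nm]][2], tolerance = 1e-13)
  }
})

test_that("the rotated network reproduces the CF table exactly (two prime fields)", {
  for (p in GFP_PRIMES[1:2]) {
    ex <- example_4_8("gfp", prime = p)
    ta <- cf_table(ex$net_a, params = ex$params_a)
    tb <- cf_table(ex$net_b, params = ex$params_b)
    for (i in seq_along(ta$quartets))
      for (s in 1:3)
        expect_equal(ta$quartets[[i]]$cf[[s]]$v, tb$quartets[[i]]$cf[[s]]$v)
  }
  # float solution: machine-precision table agreement and the known gamma
  ex <- example_4_8()
  expect_equal(ex$params_b$gamma, 236700 / 253367, tolerance = 1e-12)
  expect_equal(ex$params_b$l3, 26191 / 31250, tolerance = 1e-12)
  ta <- cf_table(ex$net_a, params = ex$params_a)
  tb <- cf_table(ex$net_b, params = ex$params_b)
  expect_cf_equal(ta, tb, tol = 1e-12)
})

test_that("both parameterizations are locally 6-dimensional at the point", {
  pt <- lapply(qcfnet:::.EX48_NA, function(fr) qq(fr[1], fr[2]))
  expect_equal(as.integer(variety_dimension("Na", point = pt)), 6L)
})

test_that("classification is identical (and ambiguous) on the two tables", {
  ex <- example_4_8()
  ca <- classify_three_cycle(cf_table(ex$net_a, params = ex$params_a),
                             std_blocks6)
  cb <- classify_three_cycle(cf_table(ex$net_b, params = ex$params_b),
                             std_blocks6)
  expect_identical(ca$verdict, cb$verdict)
  expect_identical(sort(ca$hybrid), sort(cb$hybrid))
  # the hybrid cannot be pinned to a single block here
  expect_gte(length(ca$hybrid), 2)
})
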