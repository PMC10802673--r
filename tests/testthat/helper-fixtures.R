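# shared helpers for the test suite

# numeric CF matrix of a table (rows follow the canonical quartet order)
cf_mat <- function(tab) {
  do.call(rbind, lapply(tab$quartets, function(q) vapply(q$cf, rr_tonum, 0)))
}

expect_cf_equal <- function(t1, t2, tol = 0) {
  m1 <- cf_mat(t1); m2 <- cf_mat(t2)
  expect_equal(dim(m1), dim(m2))
  if (tol == 0) expect_true(max(abs(m1 - m2)) == 0)
  else expect_lt(max(abs(m1 - m2)), tol)
}

# exact equality of two qq values
expect_qq_equal <- function(a, b) {
  expect_s3_class(a, "qq")
  expect_true(a$n == b$n && a$d == b$d)
}

# exact parameters in GF(p)
gfp_params <- function(params, prime) {
  lapply(params, function(v) {
    if (inherits(v, "qq")) qcfnet:::.gfp_rat(v$n, v$d, prime) else
      qcfnet:::.gfp_rat(round(v * 1e6), 1e6, prime)
  })
}

# a small quartet species tree with internal length t
quartet_tree <- function(t) {
  parse_network(sprintf("(((a:1.0,b:1.0):%g,c:2.0):1.0,d:3.0);", t))
}

std_blocks5 <- list(A = c("a1", "a2"), B = c("b1", "b2"), C = "c")
std_blocks6 <- list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"))
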