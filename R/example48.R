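# The indistinguishability construction for the 3-cycle hybrid node: a
# 6-taxon network Na with fixed parameters, and a rotated network Nb whose
# parameters are solved exactly from the p-vector fiber so that the two CF
# tables coincide.  Exactness is verified in GF(p) (the rational magnitudes
# exceed the 2^53 double guard); the float solution agrees to machine
# precision.

# the fixed Na parameter point (fractions over 100)
.EX48_NA <- list(gamma = c(28, 100), h1 = c(83, 100), h2 = c(78, 100),
                 x = c(98, 100), l1 = c(88, 100), l2 = c(61, 100),
                 l3 = c(50, 100))

# the six CF values of Na at that point (engine-verified fractions)
.EX48_CF <- list(bc_bc = c(2989, 30000), ab_ab = c(906412969, 5859375000),
                 ac_ac = c(29951713, 234375000), ab_ac = c(602701, 2343750),
                 ab_bc = c(9394, 46875), ac_bc = c(1243, 7500))

# generic 3x3 Cramer solve over any ring
.cramer3 <- function(M, b) {
  det3 <- function(M) {
    rr_add(rr_sub(rr_mul(M[[1]][[1]], rr_sub(rr_mul(M[[2]][[2]], M[[3]][[3]]),
                                             rr_mul(M[[2]][[3]], M[[3]][[2]]))),
                  rr_mul(M[[1]][[2]], rr_sub(rr_mul(M[[2]][[1]], M[[3]][[3]]),
                                             rr_mul(M[[2]][[3]], M[[3]][[1]])))),
           rr_mul(M[[1]][[3]], rr_sub(rr_mul(M[[2]][[1]], M[[3]][[2]]),
                                      rr_mul(M[[2]][[2]], M[[3]][[1]]))))
  }
  D <- det3(M)
  lapply(1:3, function(j) {
    Mj <- M
    for (i in 1:3) Mj[[i]][[j]] <- b[[i]]
    .rdiv(det3(Mj), D)
  })
}

#' The two indistinguishable 3-cycle networks
#'
#' Returns the 6-taxon network Na at its fixed parameter point together with
#' the rotated network Nb whose parameters are solved (exactly, in the
#' requested ring) from the six p-vector fiber equations with l2 pinned at
#' 1/2, so that cf_table(Na) == cf_table(Nb).  The hybrid node of the shared
#' 3-cycle therefore cannot be identified from CFs at this point.
#'
#' @param ring "numeric" for doubles or "gfp" for exact modular arithmetic
#' @param prime the GF(p) prime when `ring = "gfp"`
#' @return list with `net_a`, `params_a`, `net_b`, `params_b`
#' @export
example_4_8 <- function(ring = c("numeric", "gfp"), prime = GFP_PRIMES[1]) {
  ring <- match.arg(ring)
  conv <- function(fr) {
    if (ring == "numeric") fr[1] / fr[2] else .gfp_rat(fr[1], fr[2], prime)
  }
  pa <- lapply(.EX48_NA, conv)
  tmpl <- pa$gamma
  one <- rr_fromint(tmpl, 1)
  pv <- p_vector(pa$gamma, pa$l1, pa$l2, pa$l3, pa$h1, pa$h2, pa$x,
                 strict = FALSE)
  # the rotation a -> b -> c -> a maps Nb's p-vector onto Na's conditional
  # probabilities:
  q1 <- rr_sub(one, rr_mul(rr_fromint(tmpl, 3), pv$p5))
  q2 <- rr_sub(one, rr_mul(rr_fromint(tmpl, 3), pv$p6))
  q3 <- pv$p2
  q4 <- rr_divint(rr_sub(one, pv$p1), 3)
  q5 <- pv$p4
  q6 <- rr_divint(rr_sub(one, pv$p3), 3)
  half <- rr_fromint(tmpl, 1, 2)
  two <- rr_fromint(tmpl, 2); three <- rr_fromint(tmpl, 3)
  A <- rr_mul(two, rr_sub(one, q3))            # x l3 = (1 - q3)/l2
  B <- rr_mul(rr_mul(three, q4), two)          # gamma + (1-gamma) x
  C <- rr_sub(one, q1)                         # l3 (1 - gamma + gamma x)
  x <- .rdiv(rr_mul(A, rr_sub(one, B)), rr_sub(C, A))
  g <- .rdiv(rr_sub(B, x), rr_sub(one, x))
  l3 <- .rdiv(A, x)
  w <- rr_mul(g, rr_sub(one, g))
  M <- list(list(x, one, rr_mul(two, w)),
            list(one, one, rr_mul(w, rr_sub(three, x))),
            list(one, x, rr_mul(two, w)))
  b <- list(.rdiv(rr_sub(one, q2), l3),
            rr_mul(three, q5),
            rr_mul(rr_fromint(tmpl, 6), q6))
  sol <- .cramer3(M, b)
  U <- sol[[1]]; V <- sol[[2]]; L <- sol[[3]]
  h1 <- .rdiv(U, rr_mul(L, rr_mul(g, g)))
  h2 <- .rdiv(V, rr_mul(L, rr_mul(rr_sub(one, g), rr_sub(one, g))))
  list(net_a = make_named("Na"), params_a = pa,
       net_b = make_named("Nb"),
       params_b = list(gamma = g, h1 = h1, h2 = h2, x = x,
                       l1 = L, l2 = half, l3 = l3))
}
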