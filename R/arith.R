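# Ring-generic arithmetic used by the CF engine.
#
# The engine computes CFs as polynomials in edge probabilities (ell = exp(-t))
# and inheritance probabilities (gamma) with rational coefficients, so a single
# dynamic program can be run over several coefficient rings:
#   * plain doubles            -- fast numeric mode,
#   * exact rationals ("qq")   -- exact identities; doubles with a 2^53 guard,
#   * GF(p) ("gfp")            -- exact modular arithmetic for quantities whose
#                                 numerators/denominators exceed 2^53,
#   * polynomials ("mpol")     -- symbolic mode, exact rational coefficients.
# The interface is the rr_* generics below; bare integers are the only plain
# numerics the engine mixes in.

MAXI <- 2^53

.chk_int <- function(x) {
  if (any(abs(x) >= MAXI)) stop("exact integer overflow beyond 2^53", call. = FALSE)
  x
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(t > 0, t, a)
  }
  ifelse(a == 0, 1, a)
}

# vectorized reduced-fraction helpers (numerators/denominators in doubles)
qreduce <- function(n, d) {
  if (any(d == 0)) stop("zero denominator")
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- gcd2(n, d)
  list(n = n / g, d = d / g)
}

qadd2 <- function(n1, d1, n2, d2) {
  g <- gcd2(d1, d2)
  a <- d2 / g
  n <- .chk_int(.chk_int(n1 * a) + .chk_int(n2 * (d1 / g)))
  qreduce(n, .chk_int(d1 * a))
}

qmul2 <- function(n1, d1, n2, d2) {
  g1 <- gcd2(n1, d2); g2 <- gcd2(n2, d1)
  qreduce(.chk_int((n1 / g1) * (n2 / g2)), .chk_int((d1 / g2) * (d2 / g1)))
}

## ---- exact rational scalars -------------------------------------------------

#' Exact rational scalar
#'
#' A reduced fraction held in doubles; every operation checks that numerator
#' and denominator stay below 2^53, so results are exact or an error is raised,
#' never silently rounded.
#'
#' @param n numerator (whole number)
#' @param d denominator (whole number, nonzero)
#' @return an object of class `qq`
#' @export
qq <- function(n, d = 1) {
  if (n != round(n) || d != round(d)) stop("qq() needs whole numbers")
  r <- qreduce(.chk_int(n), .chk_int(d))
  structure(list(n = r$n, d = r$d), class = "qq")
}

#' @export
print.qq <- function(x, ...) {
  cat(if (x$d == 1) format(x$n) else paste0(format(x$n), "/", format(x$d)), "\n")
  invisible(x)
}

#' @export
format.qq <- function(x, ...) if (x$d == 1) format(x$n) else paste0(x$n, "/", x$d)

## ---- GF(p) scalars ----------------------------------------------------------

# primes p with p^2 < 2^53 so products are exact in doubles
GFP_PRIMES <- c(67108859, 67108837, 67108819, 94906249)

#' Element of the prime field GF(p)
#'
#' @param v integer value (any whole number; reduced mod p)
#' @param p a prime with p^2 < 2^53
#' @return an object of class `gfp`
#' @export
gfp <- function(v, p) {
  structure(list(v = v %% p, p = p), class = "gfp")
}

.gfp_inv <- function(a, p) {
  # extended Euclid
  if (a %% p == 0) stop("not invertible mod p")
  t0 <- 0; t1 <- 1; r0 <- p; r1 <- a %% p
  while (r1 != 0) {
    q <- (r0 - r0 %% r1) / r1
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
  }
  t0 %% p
}

# map a rational n/d into GF(p)
.gfp_rat <- function(n, d, p) {
  v <- ((n %% p) * .gfp_inv(d %% p, p)) %% p
  gfp(v, p)
}

#' @export
print.gfp <- function(x, ...) { cat(x$v, " (mod ", x$p, ")\n", sep = ""); invisible(x) }

## ---- multivariate polynomials ----------------------------------------------

#' Multivariate polynomial with exact rational coefficients
#'
#' Terms are rows of an exponent matrix over a fixed variable universe;
#' coefficients are reduced fractions in doubles (2^53 guard).
#'
#' @param vars character vector: the variable universe
#' @param E integer matrix, one row per term, one column per variable
#' @param cn,cd coefficient numerators / denominators
#' @return an object of class `mpol`
#' @export
mpol <- function(vars, E = matrix(0L, 0, length(vars)), cn = numeric(0), cd = numeric(0)) {
  colnames(E) <- vars
  structure(list(vars = vars, E = E, cn = cn, cd = cd), class = "mpol")
}

#' A single variable as a polynomial
#' @param v variable name
#' @param vars variable universe
#' @export
mpol_var <- function(v, vars) {
  E <- matrix(0L, 1, length(vars))
  E[1, match(v, vars)] <- 1L
  mpol(vars, E, 1, 1)
}

#' A rational constant as a polynomial
#' @param vars variable universe
#' @param n,d numerator and denominator
#' @export
mpol_const <- function(vars, n, d = 1) {
  if (n == 0) return(mpol(vars))
  r <- qreduce(n, d)
  mpol(vars, matrix(0L, 1, length(vars)), r$n, r$d)
}

# combine duplicate monomials, drop zero coefficients, sort for canonical form
.mpol_collapse <- function(p) {
  if (nrow(p$E) == 0) return(p)
  key <- apply(p$E, 1, paste, collapse = ",")
  if (anyDuplicated(key)) {
    E2 <- NULL; cn2 <- numeric(0); cd2 <- numeric(0)
    for (k in unique(key)) {
      i <- which(key == k)
      n <- p$cn[i[1]]; d <- p$cd[i[1]]
      for (j in i[-1]) { r <- qadd2(n, d, p$cn[j], p$cd[j]); n <- r$n; d <- r$d }
      if (n != 0) { E2 <- rbind(E2, p$E[i[1], , drop = FALSE]); cn2 <- c(cn2, n); cd2 <- c(cd2, d) }
    }
    if (is.null(E2)) return(mpol(p$vars))
    p$E <- E2; p$cn <- cn2; p$cd <- cd2
  } else {
    keep <- p$cn != 0
    p$E <- p$E[keep, , drop = FALSE]; p$cn <- p$cn[keep]; p$cd <- p$cd[keep]
  }
  if (nrow(p$E) > 1) {
    o <- do.call(order, c(as.data.frame(p$E), list(decreasing = TRUE)))
    p$E <- p$E[o, , drop = FALSE]; p$cn <- p$cn[o]; p$cd <- p$cd[o]
  }
  colnames(p$E) <- p$vars
  p
}

.mpol_add <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  .mpol_collapse(mpol(a$vars, rbind(a$E, b$E), c(a$cn, b$cn), c(a$cd, b$cd)))
}

.mpol_neg <- function(a) { a$cn <- -a$cn; a }

.mpol_mul <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  na <- nrow(a$E); nb <- nrow(b$E)
  if (na == 0 || nb == 0) return(mpol(a$vars))
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  E <- a$E[ia, , drop = FALSE] + b$E[ib, , drop = FALSE]
  cn <- numeric(length(ia)); cd <- numeric(length(ia))
  for (k in seq_along(ia)) {
    r <- qmul2(a$cn[ia[k]], a$cd[ia[k]], b$cn[ib[k]], b$cd[ib[k]])
    cn[k] <- r$n; cd[k] <- r$d
  }
  .mpol_collapse(mpol(a$vars, E, cn, cd))
}

#' Partial derivative of a polynomial
#' @param p an `mpol`
#' @param v variable name
#' @export
mpol_deriv <- function(p, v) {
  j <- match(v, p$vars)
  keep <- p$E[, j] > 0
  if (!any(keep)) return(mpol(p$vars))
  E <- p$E[keep, , drop = FALSE]
  cn <- .chk_int(p$cn[keep] * E[, j])
  E[, j] <- E[, j] - 1L
  .mpol_collapse(mpol(p$vars, E, cn, p$cd[keep]))
}

#' Evaluate a polynomial on vectors of numeric values
#'
#' @param p an `mpol`
#' @param vals named list of numeric vectors (equal length), one per variable
#' @return numeric vector of values
#' @export
mpol_eval <- function(p, vals) {
  npts <- if (length(vals)) length(vals[[1]]) else 1L
  out <- numeric(npts)
  if (nrow(p$E) == 0) return(out)
  for (k in seq_len(nrow(p$E))) {
    term <- rep((p$cn[k] / p$cd[k]), npts)
    for (j in seq_along(p$vars)) {
      e <- p$E[k, j]
      if (e > 0) term <- term * vals[[p$vars[j]]]^e
    }
    out <- out + term
  }
  out
}

# evaluate with exact rational substitution, returning a qq (scalar points only)
mpol_eval_qq <- function(p, vals) {
  acc <- qq(0)
  if (nrow(p$E) == 0) return(acc)
  for (k in seq_len(nrow(p$E))) {
    term <- qq(p$cn[k], p$cd[k])
    for (j in seq_along(p$vars)) {
      e <- p$E[k, j]
      if (e > 0) term <- rr_mul(term, rr_pow(vals[[p$vars[j]]], e))
    }
    acc <- rr_add(acc, term)
  }
  acc
}

# evaluate in GF(p) at a rational point given as list of qq
mpol_eval_gfp <- function(p, vals, prime) {
  acc <- gfp(0, prime)
  if (nrow(p$E) == 0) return(acc)
  for (k in seq_len(nrow(p$E))) {
    term <- .gfp_rat(p$cn[k], p$cd[k], prime)
    for (j in seq_along(p$vars)) {
      e <- p$E[k, j]
      if (e > 0) {
        v <- vals[[p$vars[j]]]
        term <- rr_mul(term, rr_pow(.gfp_rat(v$n, v$d, prime), e))
      }
    }
    acc <- rr_add(acc, term)
  }
  acc
}

#' @export
print.mpol <- function(x, ...) {
  if (nrow(x$E) == 0) { cat("0\n"); return(invisible(x)) }
  terms <- vapply(seq_len(nrow(x$E)), function(k) {
    co <- if (x$cd[k] == 1) format(x$cn[k]) else paste0(x$cn[k], "/", x$cd[k])
    mono <- paste0(vapply(seq_along(x$vars), function(j) {
      e <- x$E[k, j]
      if (e == 0) "" else if (e == 1) x$vars[j] else paste0(x$vars[j], "^", e)
    }, ""), collapse = "")
    if (mono == "") co else paste0(co, "*", mono)
  }, "")
  cat(paste(terms, collapse = " + "), "\n")
  invisible(x)
}

## ---- the ring interface -----------------------------------------------------

#' Ring operations used by the CF engine
#'
#' `rr_add`, `rr_sub`, `rr_mul` are binary ring operations; `rr_pow` raises to
#' a nonnegative integer power; `rr_divint` divides by a nonzero integer
#' (exact in every supported ring); `rr_fromint` embeds a rational n/d using a
#' template element to select the ring; `rr_tonum` converts to double.
#'
#' @param a,b ring elements (doubles, `qq`, `gfp` or `mpol`)
#' @param k integer
#' @param tmpl template ring element
#' @param n,d integers
#' @name ring-ops
NULL

#' @rdname ring-ops
#' @export
rr_add <- function(a, b) UseMethod("rr_add")
#' @rdname ring-ops
#' @export
rr_sub <- function(a, b) UseMethod("rr_sub")
#' @rdname ring-ops
#' @export
rr_mul <- function(a, b) UseMethod("rr_mul")
#' @rdname ring-ops
#' @export
rr_pow <- function(a, k) UseMethod("rr_pow")
#' @rdname ring-ops
#' @export
rr_divint <- function(a, k) UseMethod("rr_divint")
#' @rdname ring-ops
#' @export
rr_fromint <- function(tmpl, n, d = 1) UseMethod("rr_fromint")
#' @rdname ring-ops
#' @export
rr_tonum <- function(a) UseMethod("rr_tonum")

#' @export
rr_add.default <- function(a, b) a + b
#' @export
rr_sub.default <- function(a, b) a - b
#' @export
rr_mul.default <- function(a, b) a * b
#' @export
rr_pow.default <- function(a, k) a^k
#' @export
rr_divint.default <- function(a, k) a / k
#' @export
rr_fromint.default <- function(tmpl, n, d = 1) n / d
#' @export
rr_tonum.default <- function(a) a

#' @export
rr_add.qq <- function(a, b) { r <- qadd2(a$n, a$d, b$n, b$d); structure(r, class = "qq") }
#' @export
rr_sub.qq <- function(a, b) { r <- qadd2(a$n, a$d, -b$n, b$d); structure(r, class = "qq") }
#' @export
rr_mul.qq <- function(a, b) { r <- qmul2(a$n, a$d, b$n, b$d); structure(r, class = "qq") }
#' @export
rr_pow.qq <- function(a, k) {
  out <- qq(1)
  for (i in seq_len(k)) out <- rr_mul(out, a)
  out
}
#' @export
rr_divint.qq <- function(a, k) rr_mul(a, qq(1, k))
#' @export
rr_fromint.qq <- function(tmpl, n, d = 1) qq(n, d)
#' @export
rr_tonum.qq <- function(a) a$n / a$d

#' @export
rr_add.gfp <- function(a, b) gfp((a$v + b$v) %% a$p, a$p)
#' @export
rr_sub.gfp <- function(a, b) gfp((a$v - b$v) %% a$p, a$p)
#' @export
rr_mul.gfp <- function(a, b) gfp((a$v * b$v) %% a$p, a$p)
#' @export
rr_pow.gfp <- function(a, k) {
  out <- gfp(1, a$p)
  for (i in seq_len(k)) out <- rr_mul(out, a)
  out
}
#' @export
rr_divint.gfp <- function(a, k) {
  kk <- k %% a$p
  if (k < 0) kk <- (a$p - ((-k) %% a$p)) %% a$p
  gfp((a$v * .gfp_inv(kk, a$p)) %% a$p, a$p)
}
#' @export
rr_fromint.gfp <- function(tmpl, n, d = 1) .gfp_rat(n, d, tmpl$p)
#' @export
rr_tonum.gfp <- function(a) a$v

#' @export
rr_add.mpol <- function(a, b) .mpol_add(a, b)
#' @export
rr_sub.mpol <- function(a, b) .mpol_add(a, .mpol_neg(b))
#' @export
rr_mul.mpol <- function(a, b) .mpol_mul(a, b)
#' @export
rr_pow.mpol <- function(a, k) {
  out <- mpol_const(a$vars, 1)
  for (i in seq_len(k)) out <- .mpol_mul(out, a)
  out
}
#' @export
rr_divint.mpol <- function(a, k) {
  for (i in seq_along(a$cn)) {
    r <- qmul2(a$cn[i], a$cd[i], 1, k)
    a$cn[i] <- r$n; a$cd[i] <- r$d
  }
  a
}
#' @export
rr_fromint.mpol <- function(tmpl, n, d = 1) mpol_const(tmpl$vars, n, d)
#' @export
rr_tonum.mpol <- function(a) {
  if (nrow(a$E) == 0) return(0)
  if (any(a$E != 0)) stop("polynomial is not constant")
  a$cn[1] / a$cd[1]
}

# is a ring element (of any supported ring) exactly zero?
rr_iszero <- function(a) {
  if (inherits(a, "qq")) return(a$n == 0)
  if (inherits(a, "gfp")) return(a$v == 0)
  if (inherits(a, "mpol")) return(nrow(a$E) == 0)
  a == 0
}
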