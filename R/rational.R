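## Internal polynomial / rational-function algebra over the Laplace variable s.
## Polynomials are numeric coefficient vectors in descending powers of s.
## Kept dependency-free: the circuit transfer functions are low order (<= 3)
## and exact coefficient arithmetic here is what the tests pin against an
## independent complex nodal oracle.

polyTrim <- function(p, tol = 0) {
  if (length(p) == 0L) return(0)
  nz <- which(abs(p) > tol)
  if (length(nz) == 0L) return(0)
  p[nz[1L]:length(p)]
}

polyMul <- function(a, b) {
  la <- length(a); lb <- length(b)
  out <- rep_len(a[1L] * b[1L] * 0, la + lb - 1L)  # keeps complex inputs complex
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

polyAdd <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- max(la, lb)
  pad <- function(p, n) c(numeric(n - length(p)), p)
  pad(a, n) + pad(b, n)
}

## Horner evaluation at (possibly complex) points, descending coefficients.
polyEval <- function(p, x) {
  acc <- rep_len(if (is.complex(x)) 0 + 0i else 0, length(x))
  for (coef in p) acc <- acc * x + coef
  acc
}

## A rational function is list(num =, den =), descending powers of s.
ratNew <- function(num, den) {
  num <- polyTrim(as.numeric(num))
  den <- polyTrim(as.numeric(den))
  if (all(den == 0)) stop("rational function with zero denominator")
  ## normalise: leading denominator coefficient 1
  lead <- den[1L]
  list(num = num / lead, den = den / lead)
}

ratMul <- function(a, b) ratNew(polyMul(a$num, b$num), polyMul(a$den, b$den))

ratDiv <- function(a, b) {
  if (all(b$num == 0)) stop("division by a zero rational function")
  ratNew(polyMul(a$num, b$den), polyMul(a$den, b$num))
}

ratAdd <- function(a, b) {
  ratNew(polyAdd(polyMul(a$num, b$den), polyMul(b$num, a$den)),
         polyMul(a$den, b$den))
}

## Impedance of two elements in parallel: Z1 Z2 / (Z1 + Z2).
ratParallel <- function(a, b) ratDiv(ratMul(a, b), ratAdd(a, b))

## Element impedances. A zero capacitance is an open circuit: parallel
## combination with anything returns the other branch, so C = 0 is handled
## by the callers before building the RC pair.
impResistor <- function(r) ratNew(r, 1)
impCapacitor <- function(cap) ratNew(1, c(cap, 0))

## R // C, degenerating gracefully when cap == 0 (open) -> plain resistor.
impParallelRC <- function(r, cap) {
  if (cap == 0) return(impResistor(r))
  ratNew(r, c(r * cap, 1))
}

## Cancel common roots of num and den to a relative tolerance, then rebuild
## real-coefficient polynomials. Orders here are tiny, so polyroot is exact
## enough; conjugate pairs survive because cancellation is symmetric.
ratReduce <- function(rat, tol = 1e-6) {
  num <- rat$num; den <- rat$den
  if (length(num) < 2L || length(den) < 2L) return(ratNew(num, den))
  numLead <- num[1L]; denLead <- den[1L]
  rootsOf <- function(p) {
    if (length(p) < 2L) return(complex(0))
    polyroot(rev(p))  # polyroot wants ascending coefficients
  }
  rn <- rootsOf(num)
  rd <- rootsOf(den)
  keepN <- rep(TRUE, length(rn))
  keepD <- rep(TRUE, length(rd))
  for (i in seq_along(rn)) {
    for (j in seq_along(rd)) {
      if (keepN[i] && keepD[j] &&
          Mod(rn[i] - rd[j]) <= tol * (1 + Mod(rn[i]) + Mod(rd[j]))) {
        keepN[i] <- FALSE
        keepD[j] <- FALSE
        break
      }
    }
  }
  fromRoots <- function(r) {
    p <- 1 + 0i
    for (rt in r) p <- polyMul(p, c(1, -rt))
    Re(p)
  }
  ratNew(numLead * fromRoots(rn[keepN]), denLead * fromRoots(rd[keepD]))
}

## Bilinear (Tustin) substitution s = k (z-1)/(z+1), k = 2 fs, mapping an
## analog rational function to digital filter coefficients b (num) and a
## (den) in descending powers of z (i.e. b[1] + b[2] z^-1 + ...).
ratBilinear <- function(num, den, fs) {
  k <- 2 * fs
  n <- length(den) - 1L              # denominator degree sets the order
  m <- length(num) - 1L
  if (m > n) stop("improper transfer function: numerator degree exceeds denominator")
  zm1 <- c(1, -1)                    # (z - 1)
  zp1 <- c(1, 1)                     # (z + 1)
  term <- function(coefs, degShift) {
    ## sum_i c_i k^(d_i) (z-1)^(d_i) (z+1)^(n - d_i); coefs descending
    deg <- length(coefs) - 1L
    acc <- numeric(n + 1L)
    for (i in seq_along(coefs)) {
      d <- deg - (i - 1L)
      p <- coefs[i] * k^d
      poly <- 1
      for (q in seq_len(d)) poly <- polyMul(poly, zm1)
      for (q in seq_len(n - d)) poly <- polyMul(poly, zp1)
      acc <- polyAdd(acc, p * poly)
    }
    acc
  }
  b <- term(num, n)
  a <- term(den, n)
  list(b = b / a[1L], a = a / a[1L])
}
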