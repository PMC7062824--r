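# Period life table and the two scalar calibrations used every projected year:
# mortality scaled to a life-expectancy target, fertility scaled to a TFR
# target. Both calibrations are single-scalar so the census age/education
# profiles of the base matrices are preserved.

LIFE_TABLE_OPEN_CAP <- 10 # years of remaining life in the 100+ interval when m = 0

#' Life expectancy at birth from a mortality schedule
#'
#' Standard period life table over single-year ages 0--99 plus an open 100+
#' interval. Deaths within each closed age interval are assumed uniformly
#' distributed (a_x = 0.5). The open interval contributes a remaining
#' expectancy of 1/m at age 100, capped at `r LIFE_TABLE_OPEN_CAP` years so a
#' zero-mortality schedule yields a finite e0 of 100 + cap.
#'
#' @param qx Numeric vector of length 101: the probability of dying within the
#'   year at ages 0..99, and the death rate of the open 100+ interval as the
#'   last element. All values in \[0, 1\].
#' @return Life expectancy at birth (years).
#' @export
#' @examples
#' life_expectancy(rep(0.01, 101))
life_expectancy <- function(qx) {
  if (length(qx) != 101L) rlang::abort("qx must have length 101 (ages 0..100+)")
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1)) {
    rlang::abort("qx values must lie in [0, 1]")
  }
  lx <- c(1, cumprod(1 - qx[1:100]))        # survivorship at ages 0..100
  dx <- lx[1:100] * qx[1:100]
  Lx <- lx[1:100] - 0.5 * dx
  m_open <- qx[101]
  e_open <- if (m_open <= 0) LIFE_TABLE_OPEN_CAP else min(1 / m_open, LIFE_TABLE_OPEN_CAP)
  unname(sum(Lx) + lx[101] * e_open)
}

#' Calibrate a mortality schedule to a life-expectancy target
#'
#' Finds the single scalar k such that the life table of `k * mor_base`
#' (entries clipped to at most 1) has life expectancy `le_target`, by bisection
#' on k in \[0, 10\]. When `mor_base` is a matrix (ages x education stages) the
#' life table is computed on the across-education mean schedule and the whole
#' matrix is scaled, so relative education differentials are preserved.
#'
#' @param mor_base Numeric vector of length 101, or a 101-row matrix with one
#'   column per education stage.
#' @param le_target Target life expectancy at birth (years).
#' @param tol Convergence tolerance on life expectancy (years).
#' @return Scaled mortality object of the same shape as `mor_base`, with the
#'   scalar attached as attribute `"scale"`.
#' @export
calibrate_mortality <- function(mor_base, le_target, tol = 1e-9) {
  mat <- is.matrix(mor_base)
  sched <- if (mat) rowMeans(mor_base) else mor_base
  le_at <- function(k) life_expectancy(pmin(k * sched, 1))
  lo <- 0; hi <- 10
  le_lo <- le_at(lo); le_hi <- le_at(hi)
  if (le_target > le_lo || le_target < le_hi) {
    rlang::abort(sprintf(
      "life-expectancy target %.4f outside achievable bracket [%.4f, %.4f] for mortality scales [%g, %g]",
      le_target, le_hi, le_lo, hi, lo))
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    le_mid <- le_at(mid)
    if (abs(le_mid - le_target) < tol || (hi - lo) < 1e-15) break
    if (le_mid > le_target) lo <- mid else hi <- mid
  }
  out <- pmin(mid * mor_base, 1)
  attr(out, "scale") <- mid
  out
}

#' Implied total fertility rate of a fertility matrix
#'
#' TFR is the sum over childbearing ages 15--49 of the female-population
#' weighted mean fertility rate, the mean taken across education stages and
#' provinces. Ages where no women are present contribute the unweighted mean
#' rate (they cannot influence births either way).
#'
#' @param fer Fertility array `[province, age 0..100, edu]`, births per
#'   woman-year, nonzero only for ages 15--49.
#' @param female Female population array of the same shape, persons.
#' @return Implied TFR, births per woman.
#' @export
implied_tfr <- function(fer, female) {
  stopifnot(length(dim(fer)) == 3L, all(dim(fer) == dim(female)))
  ages <- 16:50 # indices of ages 15..49 on the 0-based age axis
  tfr <- 0
  for (ai in ages) {
    f <- fer[, ai, , drop = FALSE]
    w <- female[, ai, , drop = FALSE]
    sw <- sum(w)
    tfr <- tfr + if (sw > 0) sum(f * w) / sw else mean(f)
  }
  tfr
}

#' Calibrate fertility rates to a TFR target
#'
#' Returns `s * fer_base` with the single scalar s chosen so the implied
#' national TFR (weighted by the supplied female population) equals
#' `tfr_target` exactly; TFR is linear in the scale, so s is closed-form.
#'
#' @param fer_base Fertility array `[province, age, edu]`.
#' @param tfr_target Target TFR, births per woman (> 0).
#' @param female Female population array of the same shape.
#' @return Scaled fertility array with scalar attribute `"scale"`.
#' @export
calibrate_fertility <- function(fer_base, tfr_target, female) {
  if (!is.numeric(tfr_target) || tfr_target <= 0) {
    rlang::abort("tfr_target must be positive")
  }
  base <- implied_tfr(fer_base, female)
  if (base <= 0) rlang::abort("fer_base implies zero TFR; cannot calibrate")
  s <- tfr_target / base
  out <- s * fer_base
  attr(out, "scale") <- s
  out
}
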