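#' Derive the 19 bioclimatic variables from monthly climate
#'
#' Standard ANUCLIM-style derivation from 12 monthly minimum temperatures,
#' maximum temperatures (degrees C) and precipitation totals (mm):
#'
#' * bio1  annual mean temperature: mean of monthly means `(tmin+tmax)/2`
#' * bio2  mean diurnal range: mean of monthly `(tmax - tmin)`
#' * bio3  isothermality: `100 * bio2 / bio7` (0 where bio7 is 0)
#' * bio4  temperature seasonality: `100 *` sd of the 12 monthly means
#' * bio5  max temperature of the warmest month; bio6 min of the coldest
#' * bio7  annual range `bio5 - bio6`
#' * bio8/bio9 mean temperature of the wettest/driest quarter
#' * bio10/bio11 mean temperature of the warmest/coldest quarter
#' * bio12 annual precipitation; bio13/bio14 wettest/driest month
#' * bio15 precipitation seasonality: `100 * sd/mean` of monthly
#'   precipitation (plain coefficient of variation; 0 when the mean is 0)
#' * bio16/bio17 precipitation of the wettest/driest quarter
#' * bio18/bio19 precipitation of the warmest/coldest quarter
#'
#' Quarters are the 12 windows of 3 consecutive months, wrapping across the
#' year boundary (Dec-Jan-Feb is a quarter). Quarter temperature is the mean
#' of the window's monthly means; quarter precipitation is the window sum.
#' Ties between quarters are broken by the earliest starting month.
#' Standard deviations use the sample (n-1) denominator. Temperatures are in
#' plain degrees C; if importing integer grids stored as degrees x 10, set
#' `temp_scale = 0.1`.
#'
#' @param tmin,tmax Lists of 12 matrices (degrees C), January first.
#' @param prec List of 12 matrices (mm, non-negative).
#' @param temp_scale Multiplier applied to tmin/tmax on entry (default 1).
#' @return Named list of 19 matrices, `bio1` ... `bio19`.
#' @export
compute_bioclim <- function(tmin, tmax, prec, temp_scale = 1) {
  stopifnot(length(tmin) == 12, length(tmax) == 12, length(prec) == 12)
  dm <- dim(as.matrix(tmin[[1]]))
  arr <- function(lst, scale = 1) {
    a <- array(NA_real_, c(dm[1], dm[2], 12))
    for (m in 1:12) a[, , m] <- as.matrix(lst[[m]]) * scale
    a
  }
  tn <- arr(tmin, temp_scale); tx <- arr(tmax, temp_scale); pr <- arr(prec)
  if (any(tn > tx, na.rm = TRUE)) stop("tmin exceeds tmax in some cells")
  if (any(pr < 0, na.rm = TRUE)) stop("negative precipitation")
  tm <- (tn + tx) / 2

  amean <- function(a) apply(a, c(1, 2), mean)
  asd   <- function(a) apply(a, c(1, 2), stats::sd)
  amax  <- function(a) apply(a, c(1, 2), max)
  amin  <- function(a) apply(a, c(1, 2), min)

  bio <- list()
  bio$bio1 <- amean(tm)
  bio$bio2 <- amean(tx - tn)
  bio$bio4 <- 100 * asd(tm)
  bio$bio5 <- amax(tx)
  bio$bio6 <- amin(tn)
  bio$bio7 <- bio$bio5 - bio$bio6
  bio$bio3 <- ifelse(bio$bio7 == 0, 0, 100 * bio$bio2 / bio$bio7)
  bio$bio12 <- apply(pr, c(1, 2), sum)
  bio$bio13 <- amax(pr)
  bio$bio14 <- amin(pr)
  prm <- amean(pr)
  bio$bio15 <- ifelse(prm == 0, 0, 100 * asd(pr) / prm)

  # 12 wrapping quarters: qt = mean temperature, qp = precipitation sum
  qt <- array(NA_real_, c(dm[1], dm[2], 12))
  qp <- array(NA_real_, c(dm[1], dm[2], 12))
  for (q in 1:12) {
    idx <- ((q - 1):(q + 1)) %% 12 + 1
    qt[, , q] <- (tm[, , idx[1]] + tm[, , idx[2]] + tm[, , idx[3]]) / 3
    qp[, , q] <- pr[, , idx[1]] + pr[, , idx[2]] + pr[, , idx[3]]
  }
  pick <- function(val, by, which = c("max", "min")) {
    which <- match.arg(which)
    # earliest-quarter tie-break: which.max/which.min return the first index
    sel <- apply(by, c(1, 2), function(v)
      if (all(is.na(v))) NA_integer_
      else if (which == "max") which.max(v) else which.min(v))
    out <- matrix(NA_real_, dm[1], dm[2])
    for (q in 1:12) {
      hit <- !is.na(sel) & sel == q
      out[hit] <- val[, , q][hit]
    }
    out
  }
  bio$bio8  <- pick(qt, qp, "max")
  bio$bio9  <- pick(qt, qp, "min")
  bio$bio10 <- amax(qt)
  bio$bio11 <- amin(qt)
  bio$bio16 <- amax(qp)
  bio$bio17 <- amin(qp)
  bio$bio18 <- pick(qp, qt, "max")
  bio$bio19 <- pick(qp, qt, "min")

  bio[paste0("bio", 1:19)]
}
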