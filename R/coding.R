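#' Build a coded-factor mapping from harvest conditions
#'
#' Maps the five raw harvest factors onto the centred design interval
#' \[-1, +1\] used by the response-surface model:
#' \describe{
#'   \item{X1 collection date}{days since the earliest collection,
#'     affinely rescaled so the observed date span maps to \[-1, 1\].}
#'   \item{X2 variety}{ordinal position in the closed nine-variety list
#'     ([straw_varieties()]), affinely rescaled over the full list.}
#'   \item{X3 geographic area}{Guariba = -1, Valparaiso = +1.}
#'   \item{X4 borer infection level}{affine map of the observed \% range.}
#'   \item{X5 harvest number}{affine map of the observed 1st--7th range.}
#' }
#' Treating variety as one ordinal coded column is a modelling caveat: the
#' factor is nominal, but the polynomial needs a single numeric axis.
#'
#' @param conditions Conditions data frame (defines the observed ranges).
#' @return An object of class `factor_coding`.
#' @export
factor_coding <- function(conditions) {
  validate_conditions(conditions)
  d <- as.numeric(conditions$collection_date)
  coding <- list(
    date = range(d),
    date_origin = min(conditions$collection_date),
    variety = straw_varieties(),
    area = c(Guariba = -1, Valparaiso = 1),
    infection = range(conditions$infection_level),
    harvest = range(conditions$harvest_number)
  )
  class(coding) <- "factor_coding"
  coding
}

# Affine map of raw range [lo, hi] onto [-1, 1]; midpoint codes to 0.
code_affine <- function(x, rng, what) {
  lo <- rng[1L]; hi <- rng[2L]
  if (hi == lo) return(rep(0, length(x)))
  if (any(x < lo - 1e-9 | x > hi + 1e-9)) {
    stop("raw ", what, " value outside the coded range [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  2 * (x - lo) / (hi - lo) - 1
}

#' Code raw harvest conditions onto the design scale
#'
#' @param conditions Conditions data frame.
#' @param coding A `factor_coding`; defaults to one built from `conditions`.
#' @return n x 5 numeric matrix with columns `X1`..`X5`, all in \[-1, 1\].
#' @export
code_factors <- function(conditions, coding = factor_coding(conditions)) {
  stopifnot(inherits(coding, "factor_coding"))
  vi <- match(conditions$variety, coding$variety)
  if (any(is.na(vi))) {
    stop("variety outside the coded list: ",
         paste(unique(conditions$variety[is.na(vi)]), collapse = ", "),
         call. = FALSE)
  }
  ai <- coding$area[conditions$area]
  if (any(is.na(ai))) stop("area outside the coded levels", call. = FALSE)
  X <- cbind(
    X1 = code_affine(as.numeric(conditions$collection_date), coding$date,
                     "collection date"),
    X2 = code_affine(vi, c(1, length(coding$variety)), "variety index"),
    X3 = as.numeric(ai),
    X4 = code_affine(conditions$infection_level, coding$infection,
                     "infection level"),
    X5 = code_affine(conditions$harvest_number, coding$harvest,
                     "harvest number")
  )
  rownames(X) <- conditions$sample_id
  X
}

#' Decode a coded design point back to raw harvest values
#'
#' Continuous factors are inverted exactly; variety and area snap to the
#' nearest declared level.
#'
#' @param x Coded vector of length 5 (X1..X5).
#' @param coding A `factor_coding`.
#' @return A one-row data frame of raw factor values.
#' @export
decode_factors <- function(x, coding) {
  stopifnot(inherits(coding, "factor_coding"), length(x) == 5L)
  inv <- function(z, rng) rng[1L] + (z + 1) / 2 * (rng[2L] - rng[1L])
  nv <- length(coding$variety)
  vidx <- round(inv(x[2L], c(1, nv)))
  vidx <- min(max(vidx, 1L), nv)
  data.frame(
    collection_date = as.Date(round(inv(x[1L], coding$date)),
                              origin = "1970-01-01"),
    variety = coding$variety[vidx],
    area = names(coding$area)[which.min(abs(coding$area - x[3L]))],
    infection_level = inv(x[4L], coding$infection),
    harvest_number = inv(x[5L], coding$harvest)
  )
}

#' @export
print.factor_coding <- function(x, ...) {
  cat("Coded-factor mapping onto [-1, 1]:\n")
  cat("  X1 date      :", format(as.Date(x$date[1L], origin = "1970-01-01")),
      "to", format(as.Date(x$date[2L], origin = "1970-01-01")), "\n")
  cat("  X2 variety   : ordinal over", length(x$variety), "varieties\n")
  cat("  X3 area      : Guariba = -1, Valparaiso = +1\n")
  cat("  X4 infection :", x$infection[1L], "to", x$infection[2L], "%\n")
  cat("  X5 harvest   :", x$harvest[1L], "to", x$harvest[2L], "\n")
  invisible(x)
}
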