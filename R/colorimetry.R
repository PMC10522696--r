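#' Smith-Pokorny cone fundamentals matrix
#'
#' Linear transform from Judd-modified CIE tristimulus (X, Y, Z) to
#' L, M, S cone excitations (Smith-Pokorny normalization: L + M = Y,
#' S scaled by 0.01608 Z). Note that published S-cone excitations vary
#' with normalization convention, so S values from this matrix should
#' be compared across stimuli, not across studies.
#'
#' @return 3 x 3 numeric matrix (rows L, M, S; columns X, Y, Z).
#' @export
smithPokornyMatrix <- function() {
  matrix(c(0.15514,  0.54312, -0.03286,
           -0.15514, 0.45684,  0.03286,
           0.0,      0.0,      0.01608),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("L", "M", "S"), c("X", "Y", "Z")))
}

#' Cone excitations from CIE xyY chromaticity and luminance
#'
#' Converts chromaticity (x, y) and luminance Y (cd/m^2) to tristimulus
#' X = xY/y, Z = (1 - x - y) Y / y, then applies a cone-fundamentals
#' matrix to obtain (eps_L, eps_M, eps_S).
#'
#' @param x,y CIE chromaticity coordinates (y > 0).
#' @param Y luminance (cd/m^2).
#' @param fundamentals 3 x 3 matrix mapping (X, Y, Z) to (L, M, S);
#'   default [smithPokornyMatrix()].
#' @return named numeric vector c(L =, M =, S =).
#' @export
xyYToLMS <- function(x, y, Y, fundamentals = smithPokornyMatrix()) {
  if (y <= 0) stop("chromaticity y must be > 0")
  X <- x * Y / y
  Z <- (1 - x - y) * Y / y
  lms <- as.vector(fundamentals %*% c(X, Y, Z))
  names(lms) <- c("L", "M", "S")
  lms
}

#' Weber cone contrast of a stimulus against the background
#'
#' C = (eps_stim - eps_bg) / eps_bg per cone class, rounded to two
#' decimals for report output (raw values also returned).
#'
#' @param epsStim cone excitations of the stimulus.
#' @param epsBg cone excitations of the background (all > 0).
#' @param digits rounding applied to the reported contrast.
#' @return named numeric vector of rounded contrasts, with the
#'   unrounded values in attribute "raw".
#' @export
coneContrast <- function(epsStim, epsBg, digits = 2L) {
  if (any(epsBg <= 0)) stop("background cone excitation must be > 0")
  raw <- (epsStim - epsBg) / epsBg
  out <- round(raw, digits)
  attr(out, "raw") <- raw
  out
}

#' Excitations and contrasts for a table of xyY stimuli
#'
#' Convenience wrapper for stimulus-calibration reports: computes cone
#' excitations for each row of an xyY table and Weber contrasts against
#' a designated background row.
#'
#' @param stimuli data.frame with columns name, x, y, Y.
#' @param background name of the background row.
#' @param fundamentals cone-fundamentals matrix.
#' @return data.frame with excitations (L, M, S) and contrasts
#'   (C_L, C_M, C_S; NA for the background row).
#' @export
colorimetryTable <- function(stimuli, background = "background",
                             fundamentals = smithPokornyMatrix()) {
  stopifnot(all(c("name", "x", "y", "Y") %in% names(stimuli)))
  exc <- t(mapply(function(x, y, Y) xyYToLMS(x, y, Y, fundamentals),
                  stimuli$x, stimuli$y, stimuli$Y))
  bg <- which(stimuli$name == background)
  if (length(bg) != 1L)
    stop(sprintf("background row '%s' not found", background))
  ctr <- t(apply(exc, 1L, coneContrast, epsBg = exc[bg, ]))
  ctr[bg, ] <- NA_real_
  out <- cbind(stimuli, exc,
               stats::setNames(as.data.frame(ctr),
                               c("C_L", "C_M", "C_S")))
  rownames(out) <- NULL
  out
}
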