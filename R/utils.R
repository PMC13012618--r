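# Physical constants and small numeric helpers shared across modules.

#' @keywords internal
.const <- list(
  kB_kJ = 0.008314,      # Boltzmann constant, kJ mol^-1 K^-1
  T_default = 310,       # default simulation temperature, K
  kcal_kJ = 4.184,       # 1 kcal = 4.184 kJ
  nm_per_angstrom = 0.1
)

#' Thermal energy kBT in kJ/mol
#' @param temperature temperature in K
#' @return kBT in kJ mol^-1
#' @keywords internal
kBT_kJ <- function(temperature = .const$T_default) .const$kB_kJ * temperature

# Atomic masses (u) for elements encountered in protein/nucleotide systems.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, MG = 24.305, `NA` = 22.990, CL = 35.45, K = 39.098,
  ZN = 65.38, FE = 55.845, CA = 40.078
)

#' Infer element symbol from a PDB-style atom name
#'
#' Uses the standard convention: strip leading digits, two-letter elements
#' (MG, CL, NA, ZN, FE) are recognized explicitly, otherwise the first
#' alphabetic character is taken.
#' @param name character vector of atom names
#' @return character vector of element symbols
#' @keywords internal
infer_element <- function(name) {
  nm <- toupper(gsub("^[0-9']+", "", trimws(name)))
  two <- c("MG", "CL", "ZN", "FE", "BR", "MN", "SE")
  el <- substr(nm, 1, 1)
  is2 <- substr(nm, 1, 2) %in% two
  el[is2] <- substr(nm[is2], 1, 2)
  # sodium: "NA" atom name is ambiguous with nitrogen names (NA in HIS etc.
  # is a nitrogen); only a bare "NA" name is treated as sodium
  el[nm == "NA"] <- "NA"
  el
}

#' Mass lookup with unit fallback
#' @keywords internal
element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 1
  unname(m)
}

#' Wrap angles into (-180, 180] degrees
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Signed dihedral angle of four points (degrees)
#'
#' Standard atan2 formulation over the two bond-plane normals; the sign
#' follows the IUPAC convention (positive = clockwise looking from p2 to p3).
#' @param p1,p2,p3,p4 numeric length-3 vectors (or F x 3 matrices)
#' @return dihedral in degrees, in (-180, 180]
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(b2n, n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Squared Pearson correlation between two order-parameter series
#'
#' @param a,b numeric vectors or `op_series` objects of equal length (>= 3)
#' @return squared Pearson correlation coefficient
#' @export
correlate_series <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3) stop("need at least 3 points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero-variance input")
  stats::cor(a, b)^2
}

#' Normalized histogram (probability density) of a series
#'
#' Densities integrate to one over the supplied bin edges.
#' @param x numeric vector or `op_series`
#' @param breaks numeric vector of strictly increasing bin edges
#' @return data.frame with `mid`, `density`, `count`
#' @export
series_histogram <- function(x, breaks) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty series")
  if (any(diff(breaks) <= 0)) stop("bin edges must be strictly increasing")
  inside <- x >= breaks[1] & x <= breaks[length(breaks)]
  if (!any(inside)) stop("no values fall inside the bin range")
  h <- graphics::hist(x[inside], breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, count = h$counts)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
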