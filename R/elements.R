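#' @keywords internal
"_PACKAGE"

# Element property tables. Covalent radii after Cordero et al. (2008),
# van der Waals radii after Bondi (1964); both in Angstrom.
.ELEMENTS <- data.frame(
  element  = c("H",  "C",  "N",  "O",  "S",  "P",  "F",  "CL", "BR", "I",
               "NA", "K",  "MG", "CA", "ZN"),
  covalent = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20, 1.39,
               1.66, 2.03, 1.41, 1.76, 1.22),
  vdw      = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
               2.27, 2.75, 1.73, 2.31, 1.39),
  stringsAsFactors = FALSE
)

# Minimal Lennard-Jones well depths (kcal/mol) and rmin/2-like radii (A),
# loosely after united CHARMM/AMBER magnitudes.
.LJ_PARAMS <- data.frame(
  element = c("H",   "C",   "N",   "O",   "S",   "P",   "NA",  "K",
              "CL", "F", "BR", "I", "MG", "CA", "ZN"),
  eps     = c(0.020, 0.086, 0.170, 0.210, 0.250, 0.200, 0.047, 0.087,
              0.150, 0.061, 0.270, 0.400, 0.015, 0.120, 0.250),
  rmin    = c(1.10,  1.91,  1.82,  1.66,  2.00,  2.10,  1.37,  1.76,
              2.27, 1.70, 2.22, 2.35, 0.79, 1.37, 1.10),
  stringsAsFactors = FALSE
)

#' Look up an element property
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param what one of `"covalent"`, `"vdw"`.
#' @return numeric vector of radii in Angstrom.
#' @keywords internal
element_radius <- function(element, what = c("covalent", "vdw")) {
  what <- match.arg(what)
  i <- match(toupper(element), .ELEMENTS$element)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  }
  .ELEMENTS[[what]][i]
}

#' @keywords internal
lj_params_for <- function(element) {
  i <- match(toupper(element), .LJ_PARAMS$element)
  i[is.na(i)] <- match("C", .LJ_PARAMS$element)  # benign fallback
  .LJ_PARAMS[i, c("eps", "rmin")]
}

# Coulomb constant in kcal * A / (mol * e^2)
.COULOMB_K <- 332.06
# Gas constant in kcal / (mol * K)
.R_KCAL <- 1.987204e-3
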