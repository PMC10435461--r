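#' Unit-cell container
#'
#' @param a,b,c Cell edge lengths in angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param label Optional text label.
#' @return An object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      label = "") {
  if (any(c(a, b, c) <= 0)) abort("cell lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0 | ang >= 180)) abort("cell angles must lie in (0, 180)")
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, label = label), class = "unit_cell")
}

#' Read a unit cell from a CIF cell block or a JSON record
#'
#' Only the `_cell_length_*` / `_cell_angle_*` tags of a CIF are consumed;
#' parenthesised standard uncertainties are stripped. JSON records carry
#' fields `a`, `b`, `c` and optionally `alpha`, `beta`, `gamma`, `label`.
#'
#' @param path File path (`.cif` or `.json`).
#' @return A [unit_cell()].
#' @export
read_unit_cell <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    r <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(unit_cell(r$a, r$b, r$c, r$alpha %||% 90, r$beta %||% 90,
                     r$gamma %||% 90, r$label %||% ""))
  }
  lines <- readLines(path)
  grab <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(ln) == 0) abort(paste("CIF tag missing:", tag))
    val <- sub(paste0("^\\s*", tag, "\\s+"), "", ln[1])
    as.numeric(sub("\\(.*\\)", "", val))
  }
  unit_cell(grab("_cell_length_a"), grab("_cell_length_b"),
            grab("_cell_length_c"), grab("_cell_angle_alpha"),
            grab("_cell_angle_beta"), grab("_cell_angle_gamma"),
            label = basename(path))
}

#' Unit-cell similarity index between two crystal structures
#'
#' The isomorphism index
#' \eqn{\pi = (a + b + c)/(a' + b' + c') - 1} computed from the
#' orthogonalized cell edge lengths of the two structures; angles are stored
#' on the cells but do not enter the index. A value of exactly 0 indicates
#' predictably isomorphous structures; the magnitude is the headline report
#' value, rounded to 3 decimals.
#'
#' @param cell_1,cell_2 [unit_cell()] objects (numerator and denominator).
#' @param isomorphous_cutoff Reporting convenience: |pi| at or below this
#'   value sets `isomorphous_hint` (the literature only pins pi = 0).
#' @return A one-row tibble: `pi_signed`, `pi_abs` (rounded to 3 decimals),
#'   `isomorphous_hint`.
#' @export
#' @examples
#' similarity_index(unit_cell(7.5570, 29.5198, 10.2393),
#'                  unit_cell(7.5424, 29.800, 10.060))
similarity_index <- function(cell_1, cell_2, isomorphous_cutoff = 0.01) {
  stopifnot(inherits(cell_1, "unit_cell"), inherits(cell_2, "unit_cell"))
  pi_signed <- (cell_1$a + cell_1$b + cell_1$c) /
    (cell_2$a + cell_2$b + cell_2$c) - 1
  tibble(pi_signed = pi_signed,
         pi_abs = round(abs(pi_signed), 3),
         isomorphous_hint = abs(pi_signed) <= isomorphous_cutoff)
}

#' Combine energy-framework components into a total interaction energy
#'
#' Scaled sum of the four pairwise-interaction energy components of an
#' energy-framework analysis: total = k_ele*E_ele + k_pol*E_pol +
#' k_dis*E_dis + k_rep*E_rep. The default scale factors are the CE-HF
#' model constants (1.019, 0.651, 0.901, 0.811); reports echo the factors
#' used. A negative repulsion component is flagged with a warning, not an
#' error.
#'
#' @param components A data frame (or one-row list) with columns
#'   `electrostatic`, `polarization`, `dispersion`, `repulsion` (kcal/mol).
#' @param scale_factors Numeric length-4 vector of dimensionless factors in
#'   the component order above.
#' @return A tibble with the components, the factors used and `total`
#'   (kcal/mol).
#' @export
#' @examples
#' combine_framework_energy(data.frame(electrostatic = -14.36,
#'   polarization = -4.57, dispersion = -68.31, repulsion = 31.26))
combine_framework_energy <- function(components,
                                     scale_factors = c(1.019, 0.651,
                                                       0.901, 0.811)) {
  x <- as_tibble(as.list(unlist(components))[
    c("electrostatic", "polarization", "dispersion", "repulsion")])
  if (any(vapply(x, is.null, TRUE)))
    abort("all four components (electrostatic, polarization, dispersion, repulsion) are required")
  stopifnot(length(scale_factors) == 4)
  if (any(x$repulsion < 0))
    warn("repulsion component is negative; expected >= 0")
  x$total <- scale_factors[1] * x$electrostatic +
    scale_factors[2] * x$polarization +
    scale_factors[3] * x$dispersion +
    scale_factors[4] * x$repulsion
  x$k_ele <- scale_factors[1]; x$k_pol <- scale_factors[2]
  x$k_dis <- scale_factors[3]; x$k_rep <- scale_factors[4]
  x
}
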