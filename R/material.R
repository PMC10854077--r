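#' Material specification for one sample group
#'
#' Solid (trabecular bone tissue) and fluid (marrow) constitutive
#' parameters.  Bone tissue is treated as a homogeneous isotropic linear
#' elastic solid; marrow as an incompressible Newtonian fluid.
#'
#' @param E_gpa Young's modulus of the bone tissue in GPa.
#' @param nu Poisson's ratio (`0 <= nu < 0.5`).
#' @param rho_fluid_g_cm3 marrow density in g/cm^3 (carried for
#'   completeness; the quasi-static Stokes solve is inertia-free).
#' @param mu_fluid_pa_s marrow dynamic viscosity in Pa s.
#' @param group_label optional group name.
#' @return an object of class `material_spec`.
#' @export
material_spec <- function(E_gpa = 15.08, nu = 0.3, rho_fluid_g_cm3 = 0.95,
                          mu_fluid_pa_s = 85.5, group_label = NA_character_) {
  if (E_gpa <= 0) stop("E_gpa must be positive")
  if (nu < 0 || nu >= 0.5) stop("nu must satisfy 0 <= nu < 0.5")
  if (mu_fluid_pa_s <= 0 || rho_fluid_g_cm3 <= 0)
    stop("fluid density and viscosity must be positive")
  structure(
    list(E_gpa = E_gpa, nu = nu, rho_fluid_g_cm3 = rho_fluid_g_cm3,
         mu_fluid_pa_s = mu_fluid_pa_s, group_label = group_label),
    class = "material_spec")
}

#' Study groups: elastic moduli and typical bone volume fractions
#'
#' The six experimental groups of the rat study the simulation emulates:
#' healthy control (CON), untreated type 2 diabetes (T2DM), and four
#' verapamil dose groups (VER4 to VER48, doses 4-48 mg/kg/day).  Each row
#' carries the nanoindentation-derived tissue modulus used for that group's
#' models and the bone volume fraction of the group's typical sample.
#'
#' @return data.frame with columns `group`, `E_gpa`, `bvtv`.
#' @export
bone_groups <- function() {
  data.frame(
    group = c("CON", "T2DM", "VER4", "VER12", "VER24", "VER48"),
    E_gpa = c(15.08, 11.28, 12.00, 12.60, 13.63, 14.43),
    bvtv = c(0.768, 0.237, 0.1296, 0.2885, 0.3216, 0.4906),
    stringsAsFactors = FALSE)
}

#' Material specification for a named study group
#'
#' @param group one of `"CON"`, `"T2DM"`, `"VER4"`, `"VER12"`, `"VER24"`,
#'   `"VER48"`.
#' @return a [material_spec()] with that group's tissue modulus.
#' @export
group_material <- function(group) {
  tab <- bone_groups()
  i <- match(group, tab$group)
  if (is.na(i)) stop("unknown group: ", group)
  material_spec(E_gpa = tab$E_gpa[i], group_label = group)
}
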