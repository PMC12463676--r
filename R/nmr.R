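# Closed-form mass-conservation model linking amide-proton NMR signal
# intensities and pellet geometry to cellular uptake, intracellular
# concentration, a membrane-binding bound, and condensate partitioning.
#
# Units are SI-coherent throughout: lengths m, areas m^2, cell volumes m^3,
# liquid volumes L, concentrations mol/L. The only cross-unit step, the
# m^3 -> L conversion when a cell volume meets a liquid volume, is explicit
# in concentrations_from_uptake().

M3_PER_L <- 1e-3  # 1 L = 1e-3 m^3

#' Fractional uptake of a compound from the medium
#'
#' The fraction of added compound lost from the medium in the presence of
#' cells, from the ratio of the compound's NMR signal with (`s_plus`) and
#' without (`s_minus`) cells: U = 1 - s_plus/s_minus.
#'
#' Signal in the presence of cells may slightly exceed the cell-free signal
#' through measurement noise; overshoot up to `tol` (relative) is clipped
#' to U = 0, anything larger is treated as a measurement inconsistency.
#'
#' @param s_plus signal intensity with cells (>= 0, arbitrary units)
#' @param s_minus signal intensity without cells (> 0, same units)
#' @param tol relative tolerance for `s_plus > s_minus` (default 0.02)
#' @return fractional uptake U in \[0, 1\]
#' @examples
#' fractional_uptake(0.65, 1.0)  # 0.35
#' @export
fractional_uptake <- function(s_plus, s_minus, tol = 0.02) {
  check_positive(s_minus, "s_minus")
  if (!is.numeric(s_plus) || length(s_plus) != 1L || s_plus < 0) {
    stop("`s_plus` must be a single non-negative number")
  }
  u <- 1 - s_plus / s_minus
  if (u < -tol) {
    stop(sprintf(
      "signal with cells exceeds cell-free signal by %.1f%% (> %.1f%% tolerance): inconsistent measurement",
      -100 * u, 100 * tol))
  }
  max(u, 0)
}

#' Extracellular and intracellular concentrations implied by uptake
#'
#' Mass conservation of the added compound between medium and cells:
#' C_out = (1 - U) c_add V_add / V_out and
#' C_cell = U c_add V_add / (V_1 N_cell).
#' The total cell volume is far smaller than the medium volume, so
#' `v_out` defaults to `v_add`.
#'
#' @param u fractional uptake in \[0, 1\]
#' @param c_add added concentration (mol/L)
#' @param v_add added volume (L)
#' @param v_1 single-cell volume (m^3)
#' @param n_cell number of cells
#' @param v_out extracellular volume (L), defaults to `v_add`
#' @return list with `c_out` and `c_cell` (mol/L)
#' @examples
#' # 35% uptake of 100 uM in 600 ul by 1e6 spherical cells of radius 10 um
#' geom <- sphere_geometry(1e-5)
#' concentrations_from_uptake(0.35, 100e-6, 600e-6, geom$volume, 1e6)
#' @export
concentrations_from_uptake <- function(u, c_add, v_add, v_1, n_cell,
                                       v_out = v_add) {
  stopifnot(u >= 0, u <= 1)
  check_positive(c_add, "c_add"); check_positive(v_add, "v_add")
  check_positive(v_1, "v_1"); check_positive(n_cell, "n_cell")
  check_positive(v_out, "v_out")
  v_cell_l <- v_1 * n_cell / M3_PER_L  # total cell volume, m^3 -> L
  list(c_out = (1 - u) * c_add * v_add / v_out,
       c_cell = u * c_add * v_add / v_cell_l)
}

#' Compound molecules per plasma-membrane lipid
#'
#' Upper bound on membrane sequestration: if all compound taken up were
#' dissolved in the plasma membrane, R = A_L N_A U c_add V_add /
#' (A_1 N_cell) molecules would sit on each lipid (footprint `a_lipid`).
#' R well above 1 makes pure membrane partitioning implausible.
#'
#' @param u fractional uptake in \[0, 1\]
#' @param c_add added concentration (mol/L)
#' @param v_add added volume (L)
#' @param a_lipid footprint of one lipid molecule (m^2), typically 0.5 nm^2
#'   = 5e-19 m^2
#' @param a_1 surface area of one cell (m^2)
#' @param n_cell number of cells
#' @return molecules of compound per lipid molecule (dimensionless)
#' @examples
#' lipid_ratio(0.35, 100e-6, 600e-6, 0.5e-18, 1.3e-9, 1e6)  # ~4.9
#' @export
lipid_ratio <- function(u, c_add, v_add, a_lipid, a_1, n_cell) {
  stopifnot(u >= 0, u <= 1)
  check_positive(c_add, "c_add"); check_positive(v_add, "v_add")
  check_positive(a_lipid, "a_lipid"); check_positive(a_1, "a_1")
  check_positive(n_cell, "n_cell")
  a_lipid * AVOGADRO * u * c_add * v_add / (a_1 * n_cell)
}

#' Volume and surface area of a spherical cell
#'
#' @param radius sphere radius (m)
#' @return list with `volume` (m^3) and `area` (m^2)
#' @examples
#' sphere_geometry(1e-5)  # HeLa-sized cell: V ~ 4.19e-15 m^3, A ~ 1.3e-9 m^2
#' @export
sphere_geometry <- function(radius) {
  check_positive(radius, "radius")
  list(volume = 4 / 3 * pi * radius^3, area = 4 * pi * radius^2)
}

#' Spherical-cap volume of a condensate pellet
#'
#' A centrifuged condensate pellet sits as a spherical cap in the
#' hemispherical bottom of a microcentrifuge tube of inner radius `r`.
#' From the pellet radius `a` seen in a perpendicular photograph, the
#' subtended half-angle is theta = asin(a/r) and the cap volume is
#' V = pi/3 r^3 (2 + cos theta)(1 - cos theta)^2.
#'
#' @param a pellet radius (m), 0 <= a <= r
#' @param r tube inner radius (m)
#' @return cap volume (m^3); equals the hemisphere 2/3 pi r^3 at a = r
#' @examples
#' cap_volume(2.5e-3, 2.5e-3) / (2 / 3 * pi * 2.5e-3^3)  # 1
#' @export
cap_volume <- function(a, r) {
  check_positive(r, "r")
  if (!is.numeric(a) || length(a) != 1L || a < 0) {
    stop("`a` must be a single non-negative number")
  }
  if (a > r) stop("pellet radius `a` cannot exceed tube radius `r`")
  theta <- asin(a / r)
  pi / 3 * r^3 * (2 + cos(theta)) * (1 - cos(theta))^2
}

#' Condensate partition coefficient from the NMR signal factor
#'
#' The signal factor SF is the measured intensity ratio between the dilute
#' phase and the condensate pellet resuspended in `v_added`; the partition
#' coefficient (condensate over dilute concentration) follows as
#' PC = (V_cond + V_added) / (SF V_cond).
#'
#' @param sf signal factor (> 0, dimensionless)
#' @param v_cond condensate volume (any volume unit)
#' @param v_added resuspension volume (same unit)
#' @return partition coefficient PC (> 0)
#' @examples
#' partition_coefficient(5.3, 5e-6, 260e-6)  # ~10
#' @export
partition_coefficient <- function(sf, v_cond, v_added) {
  check_positive(sf, "sf"); check_positive(v_added, "v_added")
  if (!is.numeric(v_cond) || length(v_cond) != 1L || v_cond <= 0) {
    stop("`v_cond` must be > 0: no condensate, partition undefined")
  }
  (v_cond + v_added) / (sf * v_cond)
}

#' Phase concentrations from total amount and partition coefficient
#'
#' Distributes the total compound over the condensate and dilute phases:
#' \[L\]_cond = L_tot V_tot / (V_cond + (V_tot - V_cond)/PC),
#' \[L\]_dil = \[L\]_cond / PC. Mass is conserved exactly:
#' \[L\]_cond V_cond + \[L\]_dil (V_tot - V_cond) = L_tot V_tot.
#'
#' @param l_tot total concentration (mol/L)
#' @param v_tot total sample volume
#' @param v_cond condensate volume (same unit as `v_tot`, 0 < v_cond < v_tot)
#' @param pc partition coefficient (> 0)
#' @return list with `cond` and `dil` concentrations (mol/L)
#' @examples
#' phase_concentrations(100e-6, 260e-6, 5e-6, 10)
#' @export
phase_concentrations <- function(l_tot, v_tot, v_cond, pc) {
  check_positive(l_tot, "l_tot"); check_positive(v_tot, "v_tot")
  check_positive(v_cond, "v_cond"); check_positive(pc, "pc")
  if (v_cond >= v_tot) stop("`v_cond` must be smaller than `v_tot`")
  cond <- l_tot * v_tot / (v_cond + (v_tot - v_cond) / pc)
  list(cond = cond, dil = cond / pc)
}

#' Percentage of compound signal residing in the condensate phase
#'
#' @param sf signal factor (>= 0)
#' @return percent of total signal in the condensate, 100 / (1 + SF)
#' @examples
#' condensate_signal_fraction(9)  # 10
#' @export
condensate_signal_fraction <- function(sf) {
  if (!is.numeric(sf) || length(sf) != 1L || sf < 0) {
    stop("`sf` must be a single non-negative number")
  }
  100 / (1 + sf)
}

#' Full uptake report from an NMR cell experiment
#'
#' Convenience wrapper chaining [fractional_uptake()],
#' [sphere_geometry()], [concentrations_from_uptake()] and [lipid_ratio()].
#'
#' @param s_plus,s_minus signal with / without cells
#' @param c_add added concentration (mol/L)
#' @param v_add added volume (L)
#' @param n_cell cell count
#' @param cell_radius cell radius (m), default 1e-5 (HeLa approximation)
#' @param a_lipid lipid footprint (m^2), default 0.5 nm^2
#' @return list with `u`, `c_out`, `c_cell`, `v_1`, `a_1`, `lipid_ratio`
#' @export
nmr_uptake_report <- function(s_plus, s_minus, c_add, v_add, n_cell,
                              cell_radius = 1e-5, a_lipid = 0.5e-18) {
  u <- fractional_uptake(s_plus, s_minus)
  geom <- sphere_geometry(cell_radius)
  conc <- concentrations_from_uptake(u, c_add, v_add, geom$volume, n_cell)
  list(u = u,
       c_out = conc$c_out,
       c_cell = conc$c_cell,
       v_1 = geom$volume,
       a_1 = geom$area,
       lipid_ratio = lipid_ratio(u, c_add, v_add, a_lipid, geom$area,
                                 n_cell))
}

#' Full partitioning report from an NMR condensate experiment
#'
#' Chains [cap_volume()], [partition_coefficient()],
#' [phase_concentrations()] and [condensate_signal_fraction()].
#'
#' @param sf signal factor
#' @param pellet_a pellet radius (m)
#' @param tube_r tube inner radius (m)
#' @param v_added resuspension volume (L)
#' @param l_tot total compound concentration (mol/L)
#' @param v_tot total sample volume (L)
#' @return list with `v_cond` (L), `pc`, `conc_cond`, `conc_dil` (mol/L)
#'   and `signal_fraction_pct`
#' @export
nmr_partition_report <- function(sf, pellet_a, tube_r, v_added, l_tot,
                                 v_tot) {
  v_cond <- cap_volume(pellet_a, tube_r) / M3_PER_L  # m^3 -> L
  pc <- partition_coefficient(sf, v_cond, v_added)
  conc <- phase_concentrations(l_tot, v_tot, v_cond, pc)
  list(v_cond = v_cond, pc = pc, conc_cond = conc$cond,
       conc_dil = conc$dil,
       signal_fraction_pct = condensate_signal_fraction(sf))
}
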