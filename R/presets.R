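# Species constructors and the two named parameter presets.

.octahedral <- function() {
  cbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

#' Hexamer species: one sphere with up to six octahedral binding patches
#'
#' The six patches sit at the octahedral directions on the sphere surface,
#' the unique maximally symmetric six-point arrangement, with patch-sphere
#' centres at radius (body diameter + site diameter)/2.  \code{valence = 1}
#' builds the monovalent variant used for dissociation-constant estimation.
#'
#' @param diameter body diameter, nm
#' @param siteDiameter patch diameter, nm
#' @param valence number of patches kept (1..6)
#' @param siteOnSurface place patch centres on the sphere surface (radius
#'   d/2) instead of protruding by the patch radius
#' @return a \linkS4class{SpeciesSpec} with patch class "A"
#' @export
hexamerSpec <- function(diameter = 12.6, siteDiameter = 2, valence = 6,
                        siteOnSurface = FALSE) {
  u <- .octahedral()[, seq_len(valence), drop = FALSE]
  r <- if (siteOnSurface) diameter / 2 else (diameter + siteDiameter) / 2
  new("SpeciesSpec", name = "hexamer", bodyDiameters = diameter,
      bodyOffsets = matrix(0, 3, 1), siteUnitVectors = u, siteOffsets = u * r,
      siteDiameter = siteDiameter, siteType = "A",
      temperatureGroup = "default", effectiveDiameter = diameter)
}

#' Rod dimer species: three collinear overlapping spheres, two end patches
#'
#' Models the stiff antiparallel coiled-coil dimer as three spheres along the
#' body x axis.  Neighbouring spheres overlap; the inter-centre spacing
#' defaults to 5 nm so the rod length (2 spacing + outer diameter = 23.45 nm)
#' matches the single-sphere rod diameter used by the java-style engine.
#' Patches point along +x and -x from the outer spheres, so the two binding
#' sites face opposite ends - the geometry that favours network expansion
#' because one rod cannot reach the same hexamer twice.
#'
#' @param innerDiameter,outerDiameter sphere diameters, nm
#' @param spacing inter-centre spacing along the rod axis, nm
#' @param siteDiameter patch diameter, nm
#' @param valence number of patches kept (1 or 2)
#' @return a \linkS4class{SpeciesSpec} with patch class "B"
#' @export
dimerRodSpec <- function(innerDiameter = 11.7, outerDiameter = 13.45,
                         spacing = 5, siteDiameter = 2, valence = 2) {
  off <- rbind(c(-spacing, 0, spacing), 0, 0)
  u <- cbind(c(1, 0, 0), c(-1, 0, 0))[, seq_len(valence), drop = FALSE]
  sr <- spacing + (outerDiameter + siteDiameter) / 2
  new("SpeciesSpec", name = "dimer",
      bodyDiameters = c(outerDiameter, innerDiameter, outerDiameter),
      bodyOffsets = off, siteUnitVectors = u, siteOffsets = u * sr,
      siteDiameter = siteDiameter, siteType = "B",
      temperatureGroup = "default",
      effectiveDiameter = 2 * spacing + outerDiameter)
}

#' Generic single-sphere species
#'
#' Used for inert crowders and tracers (valence 0) and for the java-style
#' engine where both binding components are plain spheres with patches on
#' their surface.
#'
#' @param name species label
#' @param diameter sphere diameter, nm
#' @param siteType "none", "A" or "B"
#' @param valence number of patches (octahedral directions are used)
#' @param siteDiameter patch diameter, nm
#' @param temperatureGroup thermostat group ("crowder" for active crowders)
#' @return a \linkS4class{SpeciesSpec}
#' @export
sphereSpec <- function(name, diameter, siteType = "none", valence = 0,
                       siteDiameter = 2, temperatureGroup = "default") {
  u <- .octahedral()[, seq_len(valence), drop = FALSE]
  new("SpeciesSpec", name = name, bodyDiameters = diameter,
      bodyOffsets = matrix(0, 3, 1), siteUnitVectors = u,
      siteOffsets = u * diameter / 2, siteDiameter = siteDiameter,
      siteType = siteType, temperatureGroup = temperatureGroup,
      effectiveDiameter = diameter)
}

#' Load the raw preset table
#'
#' @param preset "hoomd_style" or "java_style"
#' @return named list of preset values
#' @export
presetValues <- function(preset = c("hoomd_style", "java_style")) {
  preset <- match.arg(preset)
  path <- system.file("extdata", "presets.yaml", package = "synDropSim")
  yaml::read_yaml(path)[[preset]]
}

#' Species roster for a preset
#'
#' @param preset preset name
#' @param monomeric build the monovalent (valence 1 and 1) variants used for
#'   dissociation-constant estimation
#' @return named list of \linkS4class{SpeciesSpec}
#' @export
presetSpecies <- function(preset = c("hoomd_style", "java_style"),
                          monomeric = FALSE) {
  preset <- match.arg(preset)
  p <- presetValues(preset)
  vHex <- if (monomeric) 1L else 6L
  vDim <- if (monomeric) 1L else 2L
  if (preset == "hoomd_style") {
    hex <- hexamerSpec(p$hexamer_diameter, p$site_diameter, vHex)
    dim <- dimerRodSpec(p$rod_inner_diameter, p$rod_outer_diameter,
                        p$rod_sphere_spacing, p$site_diameter, vDim)
  } else {
    hex <- sphereSpec("hexamer", p$hexamer_diameter, "A", vHex, p$site_diameter)
    dim <- sphereSpec("dimer", p$rod_diameter, "B", vDim, p$site_diameter)
  }
  list(hexamer = hex, dimer = dim,
       crowder = sphereSpec("crowder", p$crowder_diameter,
                            temperatureGroup = "crowder"),
       gem = sphereSpec("gem", p$gem_diameter))
}

#' System composition for a preset
#'
#' The full system holds 1170 dimers and 390 hexamers (three divalent rods
#' per hexavalent hub, balancing complementary sites one-to-one) plus tracer
#' particles in an 860-nm box; the monomeric system holds 200 + 200
#' monovalent components in a 400-nm box.  \code{scale} shrinks copy numbers
#' by \code{scale} and the box edge by \code{scale^(1/3)}, preserving every
#' concentration.
#'
#' @param preset preset name
#' @param monomeric monovalent dissociation-constant system
#' @param scale copy-number scale factor (1, 1/8, 1/27, ...)
#' @param boundaryMode "periodic" or "walled"
#' @return a \linkS4class{SystemComposition} with a zero-count crowder slot
#' @export
presetComposition <- function(preset = c("hoomd_style", "java_style"),
                              monomeric = FALSE, scale = 1,
                              boundaryMode = "periodic") {
  preset <- match.arg(preset)
  p <- presetValues(preset)
  sp <- presetSpecies(preset, monomeric)
  edge <- if (monomeric) p$monomeric_box_edge else p$box_edge
  edge <- edge * scale^(1 / 3)
  counts <- if (monomeric) {
    c(hexamer = p$n_monomeric, dimer = p$n_monomeric, crowder = 0, gem = 0)
  } else {
    c(hexamer = p$n_hexamer, dimer = p$n_dimer, crowder = 0,
      gem = if (is.null(p$n_gem)) 0 else p$n_gem)
  }
  counts[c("hexamer", "dimer", "gem")] <-
    round(counts[c("hexamer", "dimer", "gem")] * scale)
  SystemComposition(sp, counts, SimulationBox(edge, boundaryMode))
}

#' Force-field parameters for a preset
#' @param preset preset name
#' @return a \linkS4class{ForceFieldParams}
#' @export
presetForceField <- function(preset = c("hoomd_style", "java_style")) {
  p <- presetValues(match.arg(preset))
  ForceFieldParams(epsSoft = p$eps_soft, ljEpsilon = p$lj_epsilon)
}

#' Integrator parameters for a preset
#' @param preset preset name
#' @param crowderTemperature effective temperature factor of the crowder
#'   thermostat group (1 = thermal)
#' @param seed RNG seed
#' @return an \linkS4class{IntegratorParams}
#' @export
presetIntegrator <- function(preset = c("hoomd_style", "java_style"),
                             crowderTemperature = 1, seed = 1) {
  preset <- match.arg(preset)
  p <- presetValues(preset)
  IntegratorParams(
    dt = p$dt,
    temperatures = c(default = 1, crowder = crowderTemperature),
    dragRule = p$drag_rule,
    viscosity = if (is.null(p$viscosity)) 0.03 else p$viscosity,
    referenceDiameter = if (is.null(p$reference_diameter)) 12.6
                        else p$reference_diameter,
    seed = seed,
    # the physical-units preset takes thermal steps of ~0.5 nm per axis, so
    # the guard must sit beyond the reach of pure noise over long runs
    maxStepFrac = if (p$drag_rule == "stokes") 0.5 else 0.25)
}

#' Bonding parameters for a preset
#' @param preset preset name
#' @param koff dissociation rate constant; defaults to the preset's first
#'   listed value (hoomd: 0.001 per tau; java: 26 per s)
#' @return a \linkS4class{BondingParams}
#' @export
presetBonding <- function(preset = c("hoomd_style", "java_style"),
                          koff = NULL) {
  preset <- match.arg(preset)
  p <- presetValues(preset)
  if (is.null(koff)) koff <- p$koff[1]
  BondingParams(
    # a missing kon means diffusion-limited binding (probability 1 on contact)
    kon = if (is.null(p$kon)) Inf else p$kon,
    koff = koff, dBind = p$d_bind, bindCriterion = p$bind_criterion,
    updaterPeriod = p$updater_period, bondSpringK = p$bond_spring_k,
    bondRestLength = p$bond_rest_length,
    javaMode = identical(preset, "java_style"))
}

#' Compression schedule for a preset
#' @param preset preset name
#' @param scale desk-scale factor applied to both edges (lengths scale as
#'   \code{scale^(1/3)}) and, proportionally, to the step count
#' @return a \linkS4class{CompressionSchedule}
#' @export
presetCompression <- function(preset = c("hoomd_style", "java_style"),
                              scale = 1) {
  p <- presetValues(match.arg(preset))
  init <- if (is.null(p$compression_initial_edge)) 1400
          else p$compression_initial_edge
  nst <- if (is.null(p$compression_steps)) 5e5 else p$compression_steps
  CompressionSchedule(init * scale^(1 / 3), p$box_edge * scale^(1 / 3),
                      max(1000, round(nst * scale)))
}
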