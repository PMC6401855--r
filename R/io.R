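# Configuration parsing, state-point and sweep execution, and output
# serialization (profile TSV + JSON summary).

.default_config <- function() {
  list(
    system = list(sequence = "A6G6", sigma_p = 0.005, nacl_mM = 10,
                  mgcl2_mM = 3, pH = 7, T_K = 298),
    chemistry = list(dG_AMg = -32.1, dG_GMg = -35.6, dG_ANa = 0, dG_GNa = 0,
                     pKa_A = 3.5, pKa_G = 1.6, pKw = 14,
                     vw = 0.030, vH = 0.030, vOH = 0.030,
                     vNa = 0.05, vMg = 0.18, vCl = 0.05,
                     v_A = 0.30, v_G = 0.30, eps_r = 78.5),
    geometry = list(bond_length = 0.6, bond_angle = 112,
                    torsion_trans = 180, torsion_gauche_plus = 60,
                    torsion_gauche_minus = -60),
    grid = list(n_layers = 100, dz = 0.3),
    ensemble = list(rotations_per_state = 20, max_conformations = 0,
                    seed = 20181403),
    solver = list(tol = 1e-8, max_iter = 200, jacobian = "analytic"),
    sweep = list(sigma_p = numeric(0), mgcl2_mM = numeric(0)),
    output = list(dir = ".")
  )
}

.validate_config <- function(cfg) {
  defaults <- .default_config()
  for (sec in names(cfg)) {
    if (!sec %in% names(defaults))
      stop("unknown config section: ", sec)
    extra <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(extra))
      stop("unknown config key(s) in [", sec, "]: ",
           paste(extra, collapse = ", "))
  }
  full <- utils::modifyList(defaults, cfg)
  with(full$system, {
    if (sigma_p < 0) stop("validation error: sigma_p must be >= 0")
    if (nacl_mM < 0) stop("validation error: nacl_mM must be >= 0")
    if (mgcl2_mM < 0) stop("validation error: mgcl2_mM must be >= 0")
    if (pH <= 0 || pH >= 14) stop("validation error: pH must be in (0, 14)")
  })
  if (full$grid$n_layers < 3) stop("validation error: n_layers must be >= 3")
  if (full$grid$dz <= 0) stop("validation error: dz must be > 0")
  if (any(unlist(full$sweep) < 0)) stop("validation error: sweep values must be >= 0")
  full
}

#' Load and validate a run configuration
#'
#' YAML file with sections system, chemistry, geometry, grid, ensemble,
#' solver, sweep and output; omitted keys take documented defaults, unknown
#' keys are rejected, and overrides (e.g. from CLI flags) beat file values.
#'
#' @param path YAML config file, or `NULL` for pure defaults/overrides.
#' @param overrides named nested list applied on top of the file.
#' @return fully resolved config list (class `run_config`) with a
#'   `provenance` attribute marking each section as default or user.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  cfg <- utils::modifyList(cfg, overrides)
  full <- .validate_config(cfg)
  user_keys <- lapply(names(cfg), function(s) names(cfg[[s]]))
  names(user_keys) <- names(cfg)
  attr(full, "provenance") <- user_keys
  class(full) <- c("run_config", class(full))
  full
}

.config_objects <- function(cfg) {
  ch <- cfg$chemistry
  catalog <- species_catalog(vw = ch$vw, vH = ch$vH, vOH = ch$vOH,
                             vNa = ch$vNa, vMg = ch$vMg, vCl = ch$vCl,
                             v_A = ch$v_A, v_G = ch$v_G, eps_r = ch$eps_r)
  constants <- binding_constants(dG_AMg = ch$dG_AMg, dG_GMg = ch$dG_GMg,
                                 dG_ANa = ch$dG_ANa, dG_GNa = ch$dG_GNa,
                                 pKa_A = ch$pKa_A, pKa_G = ch$pKa_G,
                                 T = cfg$system$T_K, vw = ch$vw)
  geometry <- chain_geometry(
    bond_length = cfg$geometry$bond_length,
    bond_angle = cfg$geometry$bond_angle,
    dihedral_states = c(trans = cfg$geometry$torsion_trans,
                        gauche_plus = cfg$geometry$torsion_gauche_plus,
                        gauche_minus = cfg$geometry$torsion_gauche_minus))
  grid <- scft_grid(cfg$grid$n_layers, cfg$grid$dz)
  list(catalog = catalog, constants = constants, geometry = geometry,
       grid = grid)
}

# deterministic numeric formatting for reproducible outputs
.fmt <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

#' Write the per-layer profile table for a solution
#'
#' Tab-separated, one row per layer; header comment lines echo the resolved
#' parameters and package version. Layers without polymer have empty
#' fraction fields.
#'
#' @param sol an `scft_solution`.
#' @param path output TSV path.
#' @param params optional named list echoed into the header.
#' @export
write_profiles <- function(sol, path, params = list()) {
  has_p <- sol$rho_A + sol$rho_G > 0
  fpm <- deprotonated_fraction_profile(sol)
  mask <- function(x) ifelse(has_p, x, NA_real_)
  tab <- data.frame(
    z_nm = sol$grid$z,
    phi_polymer = sol$phi_p,
    phi_water = sol$phi_free[, "w"],
    phi_Na = sol$phi_free[, "Na"],
    phi_Mg = sol$phi_free[, "Mg"],
    phi_Cl = sol$phi_free[, "Cl"],
    f_A_minus = mask(sol$fractions$A[, "minus"]),
    f_A_H = mask(sol$fractions$A[, "H"]),
    f_A_Na = mask(sol$fractions$A[, "Na"]),
    f_A_Mg = mask(sol$fractions$A[, "Mg"]),
    f_G_minus = mask(sol$fractions$G[, "minus"]),
    f_G_H = mask(sol$fractions$G[, "H"]),
    f_G_Na = mask(sol$fractions$G[, "Na"]),
    f_G_Mg = mask(sol$fractions$G[, "Mg"]),
    f_P_minus = fpm,
    psi_kT_per_e = sol$fields$psi,
    pi_kT_per_nm3 = sol$fields$pi,
    pH_local = local_ph_profile(sol),
    rho_q = sol$rho_q
  )
  hdr <- c(sprintf("# brushscft %s profile table",
                   as.character(utils::packageVersion("brushscft"))),
           sprintf("# %s: %s", names(params), vapply(params, function(p)
             paste(format(p, digits = 15), collapse = ","), "")))
  body <- c(paste(names(tab), collapse = "\t"),
            apply(tab, 1, function(r) paste(.fmt(as.numeric(r)), collapse = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Run one state point from a configuration
#'
#' Generates (or reuses) the conformational ensemble, solves the bulk and the
#' fields with continuation, computes the observables, and writes the profile
#' TSV plus a JSON report into the output directory. Outputs are byte-stable
#' for identical (config, seed).
#'
#' @param cfg a [load_config()] result.
#' @param ensemble optional pre-generated ensemble (reused across a sweep).
#' @param init optional warm-start fields.
#' @param write set `FALSE` to skip file output.
#' @param tag file-name tag, default derived from the state point.
#' @return list with `solution`, `report`, and output `paths`.
#' @export
run_state_point <- function(cfg, ensemble = NULL, init = NULL, write = TRUE,
                            tag = NULL) {
  obj <- .config_objects(cfg)
  seq <- build_sequence(cfg$system$sequence)
  if (is.null(ensemble)) {
    mc <- cfg$ensemble$max_conformations
    ensemble <- generate_ensemble(
      seq, obj$geometry, obj$grid,
      rotations_per_state = cfg$ensemble$rotations_per_state,
      seed = cfg$ensemble$seed,
      max_conformations = if (mc > 0) mc else Inf)
  }
  sol <- solve_state_point(
    ensemble, sigma_p = cfg$system$sigma_p,
    cNaCl = cfg$system$nacl_mM / 1000, cMgCl2 = cfg$system$mgcl2_mM / 1000,
    pH = cfg$system$pH, T = cfg$system$T_K,
    constants = obj$constants, catalog = obj$catalog,
    init = init, control = cfg$solver)
  sol$ensemble_meta$sequence <- cfg$system$sequence
  rep <- state_point_report(sol)
  paths <- list()
  if (write) {
    dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(tag))
      tag <- sprintf("%s_sp%s_mg%s", gsub("[()]", "", cfg$system$sequence),
                     .fmt(cfg$system$sigma_p), .fmt(cfg$system$mgcl2_mM))
    params <- c(cfg$system,
                list(version = as.character(utils::packageVersion("brushscft")),
                     ensemble_seed = cfg$ensemble$seed,
                     n_conformations = ensemble$n_conformations))
    paths$profiles <- file.path(cfg$output$dir, paste0(tag, "_profiles.tsv"))
    write_profiles(sol, paths$profiles, params)
    paths$report <- file.path(cfg$output$dir, paste0(tag, "_report.json"))
    jsonlite::write_json(
      c(unclass(rep), list(parameters = params)),
      paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(solution = sol, report = rep, paths = paths)
}

#' Run a sweep over grafting density and MgCl2 concentration
#'
#' Ascending sigma_p, then ascending MgCl2, warm-starting each solve from the
#' previous converged fields. Writes per-state-point outputs plus one
#' aggregate TSV.
#'
#' @param cfg a [load_config()] result with non-empty `sweep` lists.
#' @param write write outputs (default TRUE).
#' @return data.frame of scalar observables, one row per state point.
#' @export
run_sweep <- function(cfg, write = TRUE) {
  sps <- sort(if (length(cfg$sweep$sigma_p)) cfg$sweep$sigma_p
              else cfg$system$sigma_p)
  mgs <- sort(if (length(cfg$sweep$mgcl2_mM)) cfg$sweep$mgcl2_mM
              else cfg$system$mgcl2_mM)
  obj <- .config_objects(cfg)
  seq <- build_sequence(cfg$system$sequence)
  mc <- cfg$ensemble$max_conformations
  ensemble <- generate_ensemble(
    seq, obj$geometry, obj$grid,
    rotations_per_state = cfg$ensemble$rotations_per_state,
    seed = cfg$ensemble$seed,
    max_conformations = if (mc > 0) mc else Inf)
  rows <- list()
  for (sp in sps) {
    init <- NULL
    for (mg in mgs) {
      cfg_i <- cfg
      cfg_i$system$sigma_p <- sp
      cfg_i$system$mgcl2_mM <- mg
      out <- run_state_point(cfg_i, ensemble = ensemble, init = init,
                             write = write)
      init <- out$solution$fields
      r <- out$report
      rows[[length(rows) + 1]] <- data.frame(
        sequence = cfg$system$sequence, sigma_p = sp, mgcl2_mM = mg,
        N_Mg_per_chain = r$N_Mg_per_chain, N_Na_per_chain = r$N_Na_per_chain,
        brush_height_nm = r$brush_height_nm,
        pH_min = r$pH_min, pH_max = r$pH_max,
        phi_p_peak = r$phi_p_peak, f_Pminus_max = r$f_Pminus_max,
        converged = r$converged)
    }
  }
  agg <- do.call(rbind, rows)
  if (write) {
    dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(cfg$output$dir, "sweep_summary.tsv")
    utils::write.table(agg, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  agg
}
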