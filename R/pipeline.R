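# End-to-end pipeline driver: runs the analysis stages over synthetic
# inputs with one seed, echoes the resolved configuration and serializes
# per-stage JSON results.

.config_schema <- list(
  top = c("seed", "stages", "pore", "kinetics", "decomposition", "mixing",
          "power", "trajectory"),
  pore = c("m", "n", "d", "probe_radius"),
  kinetics = c("temperature", "period_ps", "damping_ratio", "noise_sd"),
  decomposition = c("a", "b", "c", "noise_sd", "n"),
  mixing = c("dC_step", "dC_max", "ideal", "hs", "msa", "dC_eval"),
  power = c("U_diff_mV", "conductance_nS", "noise_sd", "n_points",
            "patch_edge_nm", "pore_area_A2"),
  trajectory = c("n_episodes", "timestep_ps", "n_events")
)

check_config_keys <- function(block, name) {
  allowed <- .config_schema[[name]]
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", name,
                 paste(bad, collapse = ", ")))
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file whose keys follow the schema of [run_pipeline()].
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

default_run_config <- function() {
  list(
    seed = 1,
    stages = c("pore", "kinetics", "decomposition", "mixing", "power",
               "trajectory"),
    pore = list(m = 0, n = 1, d = 3.35, probe_radius = 0.35),
    kinetics = list(temperature = 300, period_ps = 0.4, damping_ratio = 0.05,
                    noise_sd = 0.01),
    decomposition = list(a = 1.2, b = -2.55, c = 0.4, noise_sd = 0.3, n = 200),
    mixing = list(dC_step = 0.005, dC_max = 0.5, ideal = TRUE, hs = TRUE,
                  msa = TRUE, dC_eval = 0.16),
    power = list(U_diff_mV = 73.1, conductance_nS = 0.024, noise_sd = 0.02,
                 n_points = 11, patch_edge_nm = 10, pore_area_A2 = 32),
    trajectory = list(n_episodes = 40, timestep_ps = 2, n_events = 10)
  )
}

# fill missing entries of cfg from defaults, after key validation
merge_config <- function(cfg) {
  check_config_keys(cfg, "top")
  def <- default_run_config()
  for (blk in setdiff(.config_schema$top, c("seed", "stages"))) {
    if (!is.null(cfg[[blk]])) {
      check_config_keys(cfg[[blk]], blk)
      def[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    }
  }
  if (!is.null(cfg$seed)) def$seed <- cfg$seed
  if (!is.null(cfg$stages)) {
    bad <- setdiff(cfg$stages, def$stages)
    if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
    def$stages <- cfg$stages
  }
  def
}

#' Run the full analysis pipeline over synthetic inputs
#'
#' Executes the selected stages - pore construction, transition-state-theory
#' kinetics, barrier decomposition, mixing thermodynamics, power figures and
#' trajectory statistics - on seeded synthetic data, writes one JSON result
#' per stage plus a resolved-config echo and a human-readable summary under
#' `out_dir`, and returns the result bundle. Identical config and seed give
#' identical results.
#'
#' @param config nested configuration list (see `.config_schema` keys);
#'   unknown keys are rejected. Missing entries take package defaults.
#' @param out_dir output directory (created if needed), or NULL to skip
#'   writing.
#' @return named list of per-stage results, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- merge_config(config)
  seed <- cfg$seed
  results <- list(resolved_config = cfg)
  log <- function(...) message(sprintf(...))

  if ("pore" %in% cfg$stages) {
    p <- cfg$pore
    model <- build_bilayer(p$m, p$n, p$d)
    results$pore <- list(
      label = model$label, d_A = model$d,
      n_atoms = nrow(model$layer1$atoms) + nrow(model$layer2$atoms),
      carbonyl_positions_L1 = model$layer1$carbonyl_positions,
      carbonyl_positions_L2 = model$layer2$carbonyl_positions,
      footprint_A = round(model$layer1$footprint, 2),
      effective_area_A2 = effective_pore_area(model$layer1,
                                              probe_radius = p$probe_radius),
      n_configs_ordered = length(enumerate_configs("none")),
      n_configs_swap = length(enumerate_configs("layer_swap")))
    log("pore: %s built, effective area %.1f A^2", model$label,
        results$pore$effective_area_A2)
  }

  if ("kinetics" %in% cfg$stages) {
    k <- cfg$kinetics
    pmf_K <- gen_pmf_potassium(seed = seed)
    pmf_Na <- gen_pmf_sodium(seed = seed + 1)
    dG_K <- rate_determining_barrier(pmf_K)
    dG_Na <- rate_determining_barrier(pmf_Na)
    vs <- gen_oscillator_velocities(k$period_ps, k$damping_ratio,
                                    n_periods = 12, noise_sd = k$noise_sd,
                                    seed = seed + 2)
    tau <- attempt_period_from_vacf(vs)
    k_K <- permeation_rate(dG_K, tau, k$temperature)
    k_Na <- permeation_rate(dG_Na, tau, k$temperature)
    results$kinetics <- list(
      barrier_K_kcal_mol = dG_K, barrier_Na_kcal_mol = dG_Na,
      attempt_period_ps = tau, temperature_K = k$temperature,
      rate_K_per_s = k_K, rate_Na_per_s = k_Na,
      selectivity_ratio = selectivity_ratio(k_K, k_Na))
    log("kinetics: barriers %.2f / %.2f kcal/mol, SR = %.3g",
        dG_K, dG_Na, results$kinetics$selectivity_ratio)
  }

  if ("decomposition" %in% cfg$stages) {
    d <- cfg$decomposition
    smp <- gen_decomposition_samples(d$a, d$b, d$c, d$noise_sd, d$n,
                                     seed = seed + 3)
    fit <- fit_decomposition(smp)
    results$decomposition <- list(
      coefficients = as.list(fit$coefficients),
      std_errors = as.list(fit$std_errors),
      true = list(water = d$a, carbonyl = d$b, membrane = d$c),
      n = d$n)
    log("decomposition: carbonyl coefficient %.3f (true %.3f)",
        fit$coefficients["carbonyl"], d$b)
  }

  if ("mixing" %in% cfg$stages) {
    m <- cfg$mixing
    flags <- c(ideal = isTRUE(m$ideal), hs = isTRUE(m$hs), msa = isTRUE(m$msa))
    grid <- seq(0, m$dC_max, by = m$dC_step)
    kpm <- mixing_curve("KPM", grid, flags)
    fre <- mixing_curve("free_mix", grid, flags)
    dC0 <- spontaneous_terminus(kpm)
    eff <- efficiency(kpm, fre, m$dC_eval)
    results$mixing <- list(
      dC0_M = dC0, dC_eval_M = m$dC_eval,
      ON = eff$ON, OP = eff$OP, eta_percent = 100 * eff$eta,
      normalization = kpm$normalization, model_flags = as.list(flags))
    log("mixing: dC0 = %.3f M, eta = %.1f%% at dC = %.2f M",
        dC0, 100 * eff$eta, m$dC_eval)
  }

  if ("power" %in% cfg$stages) {
    pw <- cfg$power
    iv <- gen_iv(pw$U_diff_mV, pw$conductance_nS, pw$noise_sd, pw$n_points,
                 seed = seed + 4)
    fit <- fit_iv(iv)
    dens <- pore_density_from_pitch(pw$patch_edge_nm)
    p1 <- single_pore_power(fit$I_diff_pA, fit$U_diff_mV)
    results$power <- list(
      I_diff_pA = fit$I_diff_pA, U_diff_mV = fit$U_diff_mV,
      conductance_nS = fit$conductance_nS,
      single_pore_power_W = p1, pore_density_m2 = dens,
      power_density_W_m2 = power_density(p1, dens),
      porosity = porosity(pw$pore_area_A2, dens),
      dual_ion_coulomb_kcal_mol = coulomb_energy(1, 1, 3.9))
    log("power: U_diff %.1f mV, %.3g W/m^2", fit$U_diff_mV,
        results$power$power_density_W_m2)
  }

  if ("trajectory" %in% cfg$stages) {
    tr <- cfg$trajectory
    tt <- gen_triplet_trajectory(n_episodes = tr$n_episodes,
                                 timestep_ps = tr$timestep_ps,
                                 seed = seed + 5)
    cls <- classify_triplets(tt)
    pt <- gen_permeation_trajectory(tr$n_events, seed = seed + 6)
    ev <- detect_permeation_events(pt)
    results$trajectory <- list(
      triplet_fraction_n1 = cls$summary$fraction_n1,
      triplet_mean_lifetime_n1_ps = cls$summary$mean_lifetime_n1,
      triplet_mean_lifetime_n2_ps = cls$summary$mean_lifetime_n2,
      n_episodes = cls$summary$n_episodes,
      permeation_events_detected = nrow(ev),
      permeation_events_scripted = attr(pt, "ground_truth")$n_events)
    log("trajectory: %d/%d episodes n=1, %d permeation events",
        sum(cls$events$n_waters == 1), cls$summary$n_episodes, nrow(ev))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      jsonlite::write_json(results[[nm]],
                           file.path(out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    summary_lines <- c(
      "kpore pipeline summary",
      sprintf("stages: %s", paste(cfg$stages, collapse = ", ")),
      sprintf("seed: %d", seed),
      if (!is.null(results$mixing))
        sprintf("dC0 = %.3f M, eta = %.1f%%", results$mixing$dC0_M,
                results$mixing$eta_percent),
      if (!is.null(results$kinetics))
        sprintf("selectivity ratio (synthetic barriers) = %.3g",
                results$kinetics$selectivity_ratio))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  invisible(results)
}
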