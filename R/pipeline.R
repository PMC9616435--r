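#' Run the full generation pipeline from a YAML configuration
#'
#' Orchestrates the data-driven construction end to end: build the
#' stylized city, assemble constraints, obtain edge probabilities (sparse
#' closed form or exact solve), sample an ensemble, analyse degrees, and
#' write every artifact plus a JSON run manifest to `out_dir`. A single
#' root seed in the configuration drives all stages; stage sub-seeds are
#' derived deterministically and recorded in the manifest, so a run can
#' be reproduced exactly from its manifest.
#'
#' Configuration keys (YAML): `mode` (`sparse` | `exact`), `seed`,
#' `n_graphs`, and a `city` block with `n`, `radius_km`, `tile_side_km`,
#' `spatial_density`, `fitness` (`family` plus parameters), `target_mu`,
#' `beta` and optional `age_fractions`.
#'
#' Failures raise classed conditions: `fcbm_config_error` (invalid
#' configuration), `fcbm_infeasible_error` (unsatisfiable constraints),
#' `fcbm_convergence_error` (exact solver did not converge).
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   named list.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly; artifacts written: `population.csv`,
#'   `delta.csv`, `K.csv`, `degrees_target.csv`, `fitness.csv`,
#'   `multipliers_{x,y,partition}.csv`, `graphs/graph_###.csv` (+
#'   `.graphml`), `degree_distribution.csv`, `degree_estimates.csv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "graphs"), showWarnings = FALSE)

  city <- tryCatch(
    build_city(cfg$city),
    error = function(e) {
      stop(fcbm_condition(
        "fcbm_infeasible_error",
        sprintf("city construction failed: %s", conditionMessage(e))
      ))
    }
  )
  constraints <- city$constraints

  solver_report <- NULL
  if (cfg$mode == "sparse") {
    model <- sparse_fcbm(constraints)
  } else {
    fit <- solve_fcbm(constraints, seed = cfg$stage_seeds[["solver"]])
    if (!fit$report$converged) {
      stop(fcbm_condition(
        "fcbm_convergence_error",
        sprintf(
          "solver did not converge (max residual %.3g after %d iterations)",
          fit$report$max_residual, fit$report$iterations
        )
      ))
    }
    model <- fit$model
    solver_report <- fit$report
  }

  graphs <- sample_ensemble(model, cfg$n_graphs, seed = cfg$stage_seeds[["sampler"]])

  # artifacts
  write_csv_plain(city$population, file.path(out_dir, "population.csv"))
  write_matrix_csv(unclass(city$delta), file.path(out_dir, "delta.csv"))
  write_matrix_csv(constraints$K, file.path(out_dir, "K.csv"))
  write_vertex_csv(constraints$k, file.path(out_dir, "degrees_target.csv"), name = "k")
  write_vertex_csv(city$fitness, file.path(out_dir, "fitness.csv"), name = "fitness")
  write_model_csv(model, file.path(out_dir, "multipliers"))
  for (i in seq_along(graphs)) {
    stem <- file.path(out_dir, "graphs", sprintf("graph_%03d", i))
    write_edgelist_csv(graphs[[i]], paste0(stem, ".csv"))
    write_graphml(graphs[[i]], paste0(stem, ".graphml"))
  }

  emp <- empirical_degree_distribution(graphs)
  mus <- block_mean_degrees(constraints)
  sizes <- constraints$part$sizes
  est_block <- degree_pdf_blockwise(emp$k, city$fitness_dist, mus, sizes)
  est_global <- degree_pdf_global(emp$k, city$fitness_dist, cfg$city$target_mu)
  write_csv_plain(emp, file.path(out_dir, "degree_distribution.csv"))
  write_csv_plain(
    data.frame(
      k = emp$k,
      blockwise = as.numeric(est_block),
      global = est_global
    ),
    file.path(out_dir, "degree_estimates.csv")
  )

  manifest <- list(
    config = cfg$raw,
    mode = cfg$mode,
    seed = cfg$seed,
    stage_seeds = cfg$stage_seeds,
    graph_seeds = as.list(attr(graphs, "seeds")),
    n_graphs = cfg$n_graphs,
    n_blocks = constraints$part$n,
    density_p = city$p,
    dropped_weight = city$dropped_weight,
    clipped_pairs = attr(model, "clipped_pairs"),
    mean_degree = mean(vapply(graphs, function(g) 2 * nrow(g$edges) / g$N, numeric(1))),
    solver = if (is.null(solver_report)) NULL else unclass(solver_report),
    ks_blockwise = ks_distance(emp, function(k) {
      degree_pdf_blockwise(k, city$fitness_dist, mus, sizes)
    }),
    ks_global = ks_distance(emp, function(k) {
      degree_pdf_global(k, city$fitness_dist, cfg$city$target_mu)
    }),
    files = list.files(out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(out_dir)
}

fcbm_condition <- function(class, message) {
  structure(
    class = c(class, "fcbm_error", "error", "condition"),
    list(message = message, call = NULL)
  )
}

load_pipeline_config <- function(config) {
  raw <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop(fcbm_condition(
        "fcbm_config_error",
        sprintf("config file not found: %s", config)
      ))
    }
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop(fcbm_condition("fcbm_config_error", "config must be a path or a list"))
  }

  get_or <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]
  mode <- get_or(raw, "mode", "sparse")
  if (!mode %in% c("sparse", "exact")) {
    stop(fcbm_condition("fcbm_config_error", "mode must be 'sparse' or 'exact'"))
  }
  seed <- as.integer(get_or(raw, "seed", 1L))
  n_graphs <- as.integer(get_or(raw, "n_graphs", 1L))
  if (n_graphs < 1L) {
    stop(fcbm_condition("fcbm_config_error", "n_graphs must be >= 1"))
  }
  cc <- get_or(raw, "city", list())
  # YAML 1.1 parses an unquoted key `n:` as the boolean FALSE; map it
  # back, and accept `population` as an alias
  if (is.null(cc$n)) {
    if (!is.null(cc[["FALSE"]])) cc$n <- cc[["FALSE"]]
    if (!is.null(cc$population)) cc$n <- cc$population
  }
  fit_cfg <- get_or(cc, "fitness", list(family = "lognormal"))
  fd <- tryCatch(
    do.call(fitness_distribution, fit_cfg),
    error = function(e) {
      stop(fcbm_condition(
        "fcbm_config_error",
        sprintf("invalid fitness configuration: %s", conditionMessage(e))
      ))
    }
  )
  stage_seeds <- as.list(derive_seeds(seed + 7L, 2L))
  names(stage_seeds) <- c("solver", "sampler")
  n_city <- get_or(cc, "n", 1000L)
  mu_city <- get_or(cc, "target_mu", 25)
  if (mu_city >= n_city - 1) {
    stop(fcbm_condition(
      "fcbm_infeasible_error",
      sprintf(
        "target mean degree %.4g is not attainable with %d vertices",
        mu_city, as.integer(n_city)
      )
    ))
  }
  city <- tryCatch(
    city_config(
      N = n_city,
      radius = get_or(cc, "radius_km", 2.5),
      side = get_or(cc, "tile_side_km", 0.5),
      spatial_density = get_or(cc, "spatial_density", "uniform"),
      fitness = fd,
      target_mu = mu_city,
      beta = get_or(cc, "beta", 1),
      age_fractions = unlist(get_or(
        cc, "age_fractions",
        c(0.15, 0.20, 0.25, 0.25, 0.15)
      )),
      seed = seed
    ),
    error = function(e) {
      if (inherits(e, "fcbm_error")) stop(e)
      stop(fcbm_condition(
        "fcbm_config_error",
        sprintf("invalid city configuration: %s", conditionMessage(e))
      ))
    }
  )
  list(
    raw = raw, mode = mode, seed = seed, n_graphs = n_graphs,
    city = city, stage_seeds = stage_seeds
  )
}
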