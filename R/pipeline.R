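#' Assemble and validate a pipeline configuration
#'
#' A single configuration drives [run_pipeline()]. Inputs are either paths
#' (`topology` PDB + sidecar, `trajectory` XYZ/DCD) or a `simulate` block
#' generating a toy system; a seed is mandatory either way. Referenced
#' paths are checked at validation time.
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param simulate Optional list: `n_residues`, `atoms_per_residue`,
#'   `n_frames`, `weights` (anchor stationary probabilities),
#'   `anchor_shift` (A), `noise_sd` (A), `switch_prob`.
#' @param topology,trajectory Optional input paths (ignored when
#'   `simulate` is given).
#' @param regions Named list of residue ranges or a YAML path; required for
#'   interdomain features when the topology carries none.
#' @param probe List with `atom_i`, `atom_j` (+ optional `at`) or YAML path.
#' @param states List: `k_range`, `temperature`, `restarts`.
#' @param energy List: `cutoff`, `combiner`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir,
                            simulate = NULL, topology = NULL,
                            trajectory = NULL, regions = NULL, probe = NULL,
                            states = list(), energy = list()) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  if (is.null(simulate)) {
    for (p in c(topology, trajectory))
      if (!is.null(p) && !file.exists(p)) abort(paste("missing input:", p))
    if (is.null(topology) || is.null(trajectory))
      abort("either a simulate block or topology+trajectory paths are required")
  }
  defaults <- list(k_range = 2:4, temperature = 300, restarts = 3)
  states <- utils::modifyList(defaults, states)
  energy <- utils::modifyList(list(cutoff = 12, combiner = "sum"), energy)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, topology = topology,
                 trajectory = trajectory, regions = regions, probe = probe,
                 states = states, energy = energy),
            class = "pipeline_config")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a system, compute trajectory metrics, project onto
#' collective variables, fit the mixture state model and extract core-state
#' populations, evaluate the ligand-protein interaction-energy profile and
#' the per-residue projected electric field, and write per-stage CSV/JSON
#' artifacts plus a manifest (input checksums, seed, package version).
#' Re-running with the same configuration reproduces the artifacts
#' bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results (`topology`,
#'   `trajectory`, `crmsd`, `features`, `projection`, `gmm`, `assignment`,
#'   `populations`, `lie`, `lie_summary`, `ef`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  od <- config$out_dir
  wcsv <- function(x, f) utils::write.csv(x, file.path(od, f),
                                          row.names = FALSE)

  sim <- config$simulate
  res <- list()
  if (!is.null(sim)) {
    run_stage("simulate", od, {
      defaults <- list(n_residues = 20, atoms_per_residue = 3,
                       n_frames = 500, weights = c(0.5, 0.3, 0.2),
                       anchor_shift = 4, noise_sd = 0.3, switch_prob = 0.05)
      sim <- utils::modifyList(defaults, sim)
      sys <- build_toy_complex(toy_complex_spec(
        n_residues = sim$n_residues,
        atoms_per_residue = sim$atoms_per_residue, seed = config$seed))
      k <- length(sim$weights)
      # anchors: reference plus rigid shifts of the ligand+nearby region
      anchors <- lapply(seq_len(k), function(i) {
        a <- sys$reference
        shift <- (i - 1) * sim$anchor_shift
        a[sys$topology$is_ligand, 1] <- a[sys$topology$is_ligand, 1] + shift
        half <- sys$topology$resid <= max(sys$topology$resid) / 2 &
          !sys$topology$is_ligand
        a[half, 2] <- a[half, 2] + shift / 2
        a
      })
      tr <- simulate_toy_trajectory(sys$topology, anchors, sim$weights,
                                    langevin_params(n_steps = sim$n_frames,
                                                    seed = config$seed + 1L),
                                    noise_sd = sim$noise_sd,
                                    switch_prob = sim$switch_prob)
      write_structure(sys$topology, sys$reference,
                      file.path(od, "topology.pdb"))
      write_xyz_trajectory(tr$trajectory, file.path(od, "trajectory.xyz"),
                           names = sys$topology$name)
      wcsv(tr$labels, "true_labels.csv")
      res$topology <- sys$topology
      res$reference <- sys$reference
      res$trajectory <- tr$trajectory
      res$true_labels <- tr$labels
    })
  } else {
    run_stage("load", od, {
      st <- read_structure(config$topology)
      regions <- config$regions
      if (is.character(regions)) regions <- read_regions_yaml(regions)
      if (!is.null(regions))
        st$topology <- new_md_topology(st$topology, regions = regions)
      res$topology <- st$topology
      res$reference <- st$reference
      res$trajectory <- if (grepl("\\.dcd$", config$trajectory))
        read_dcd_trajectory(config$trajectory)
      else read_xyz_trajectory(config$trajectory)
    })
  }

  run_stage("metrics", od, {
    sel <- if (any(res$topology$name %in% c("N", "CA", "C")))
      "backbone" else "protein"
    res$crmsd <- c_rmsd(res$trajectory, res$reference, res$topology,
                         selection = sel)
    wcsv(res$crmsd, "crmsd.csv")
    if (any(res$topology$is_ligand)) {
      res$drmsd <- d_rmsd(res$trajectory, res$reference, res$topology)
      wcsv(res$drmsd, "drmsd.csv")
    }
    res$rmsf <- rmsf(res$trajectory, res$topology)
    wcsv(res$rmsf, "rmsf.csv")
    regions <- attr(res$topology, "regions")
    if (length(regions) == 4) {
      res$features <- interdomain_features(res$trajectory, res$topology)
      wcsv(res$features, "interdomain.csv")
    }
  })

  run_stage("reduce", od, {
    coords <- backbone_features(res$trajectory, res$reference, res$topology,
                                selection = "protein")
    res$projection <- pca_fit_transform(coords, k = 2)
    wcsv(res$projection$scores, "pc_scores.csv")
  })

  run_stage("states", od, {
    res$gmm <- gmm_fit(res$projection$scores,
                        k_range = config$states$k_range,
                        restarts = config$states$restarts,
                        seed = config$seed)
    res$assignment <- extract_core_states(res$gmm, res$projection$scores)
    res$populations <- state_populations(res$assignment,
                                          n_states = res$gmm$k)
    res$surface <- free_energy_surface(res$gmm,
                                        temperature = config$states$temperature,
                                        points = res$projection$scores)
    res$pathway <- order_states_by_energy(res$gmm, res$populations,
                                           config$states$temperature)
    wcsv(res$assignment, "state_labels.csv")
    wcsv(as.data.frame(res$surface), "fes_grid.csv")
    jsonlite::write_json(list(
      percent = res$populations$percent,
      total = attr(res$populations, "total_percent"),
      pathway = res$pathway$state),
      file.path(od, "populations.json"), auto_unbox = TRUE, digits = NA)
  })

  if (any(res$topology$is_ligand)) {
    run_stage("lie", od, {
      res$lie <- lie_profile(res$trajectory, res$topology,
                              cutoff = config$energy$cutoff,
                              combiner = config$energy$combiner)
      res$lie_summary <- summarize_profile(res$lie)
      wcsv(res$lie, "lie_profile.csv")
      jsonlite::write_json(as.list(res$lie_summary),
                           file.path(od, "lie_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      # export TB/LB snapshots
      for (tag in c("tb", "lb")) {
        f <- res$lie_summary[[paste0(tag, "_frame")]]
        write_structure(res$topology, frame_coords(res$trajectory, f),
                        file.path(od, paste0(tag, "_frame.pdb")))
      }
    })
    run_stage("efield", od, {
      probe <- config$probe
      if (is.character(probe)) probe <- read_probe_yaml(probe, res$topology)
      if (is.null(probe)) {
        # default: metal bead and the nearest protein atom
        m <- which(res$topology$is_ligand)[
          which.max(res$topology$mass[res$topology$is_ligand])]
        prot <- which(!res$topology$is_ligand)
        d <- sqrt(rowSums(sweep(res$reference[prot, , drop = FALSE], 2,
                                res$reference[m, ])^2))
        probe <- bond_probe(prot[which.min(d)], m)
      } else if (!inherits(probe, "bond_probe")) {
        probe <- bond_probe(probe$atom_i, probe$atom_j,
                            at = probe$at %||% "midpoint")
      }
      res$ef <- per_residue_efield(res$trajectory, res$topology, probe)
      wcsv(res$ef, "efield_profile.csv")
      ranked <- rank_residues(res$ef)
      wcsv(ranked, "efield_ranked.csv")
      jsonlite::write_json(list(total_ef = attr(ranked, "total_ef"),
                                threshold = attr(ranked, "threshold")),
                           file.path(od, "efield_totals.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  run_stage("manifest", od, {
    arts <- setdiff(list.files(od), "manifest.json")
    res$manifest <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("metaldyn")),
      checksums = as.list(tools::md5sum(file.path(od, sort(arts)))))
    names(res$manifest$checksums) <- sort(arts)
    jsonlite::write_json(res$manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(res)
}

#' Render paper-style summary tables from pipeline artifacts
#'
#' Stable column order with rounding applied only at render time:
#' reactivity descriptors to 2 decimals, state populations and distances
#' and fields to 1 decimal. Every rendered number is re-derivable from the
#' stage outputs.
#'
#' @param descriptors Output of [compute_descriptors()].
#' @return A tibble, descriptors as rows and one column per input label.
#' @export
render_descriptor_table <- function(descriptors) {
  rows <- c(e_lumo = "E_LUMO (eV)", e_homo = "E_HOMO (eV)",
            ip = "Ionization potential, IP (eV)",
            ea = "Electron affinity, EA (eV)",
            e_g = "Band gap, E_g (eV)",
            mu = "Chemical potential, mu (eV)",
            eta = "Chemical hardness, eta (eV)",
            s = "Global softness, S (1/eV)",
            omega = "Electrophilicity, omega (eV)",
            chi = "Electronegativity, chi (eV)")
  if ("dipole" %in% names(descriptors))
    rows <- c(rows, dipole = "Dipole moment (D)")
  out <- tibble(descriptor = unname(rows))
  for (i in seq_len(nrow(descriptors)))
    out[[descriptors$label[i]]] <-
      round(as.numeric(descriptors[i, names(rows)]), 2)
  out
}

#' @param populations A `state_populations` (or a list of them, named by
#'   system).
#' @rdname render_descriptor_table
#' @export
render_population_table <- function(populations) {
  if (inherits(populations, "state_populations"))
    populations <- list(system = populations)
  k <- max(c(1, vapply(populations, nrow, 1L)))
  rows <- lapply(names(populations), function(nm) {
    p <- populations[[nm]]
    pct <- p$percent[match(seq_len(k), p$state)]
    v <- c(round(pct, 1), round(attr(p, "total_percent"), 1))
    names(v) <- c(paste0("S", seq_len(k)), "total")
    mutate(as_tibble(as.list(v)), system = nm, .before = 1)
  })
  bind_rows(rows)
}

#' @param interdomain Output of [summarize_interdomain_by_state()].
#' @rdname render_descriptor_table
#' @export
render_interdomain_table <- function(interdomain) {
  interdomain |>
    mutate(value = sprintf("%.1f +/- %.1f", .data$mean, .data$sd)) |>
    select("state", "pair", "value") |>
    tidyr::pivot_wider(names_from = "state", names_prefix = "S",
                       values_from = "value")
}

#' @param ef_ranked Output of [rank_residues()].
#' @rdname render_descriptor_table
#' @export
render_ef_table <- function(ef_ranked) {
  ef_ranked |>
    mutate(mean = round(.data$mean, 1), sd = round(.data$sd, 1)) |>
    select("resid", "mean", "sd")
}
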