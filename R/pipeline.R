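# Reproducible multi-stage runs over synthetic or user data.
#
# A run config is a plain list (or YAML file) naming the stages to execute
# and their parameters; every stage draws its own item seeds from the run
# seed, so a config reproduces bit-identically. Items are isolated: one
# failing input yields an error row, never an aborted batch.

#' Default demonstration configuration
#'
#' A small end-to-end run covering all four stages: device transport at two
#' head differences plus a pure-diffusion gradient, aligned-vs-random fiber
#' images, FRAP sequences at known speeds, and gradient-exposed vs control
#' cyst populations.
#'
#' @param seed Run seed.
#' @param out_dir Optional output directory.
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1, out_dir = NULL) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("transport", "fibers", "frap", "cysts"),
    transport = list(
      preset = "aligned", grid_spacing = 2.5e-5,
      heads_mm = c(2, 10, 20), gradient_hours = 24, n_snapshots = 49,
      # homogenized micropore row calibrated to the physiological ceiling:
      # 20 um/s Darcy speed at a 20 mm H2O head difference
      target_velocity_um_s = 20, reference_head_mm = 20
    ),
    fibers = list(
      n_per_group = 2,
      groups = list(aligned = list(mean_angle = 90, concentration = 6),
                    random = list(mean_angle = 90, concentration = 0))
    ),
    frap = list(speeds_um_s = c(2, 10), n_per_speed = 2),
    cysts = list(
      n_per_group = 3,
      groups = list(
        gradient = list(ruffle_top = 8, ruffle_bottom = 0,
                        protrusion_angles = c(60, 90, 120)),
        control = list(ruffle_top = 3, ruffle_bottom = 3,
                       protrusion_angles = numeric(0))
      )
    )
  )
}

# Deterministic per-item seed below 2^31.
item_seed <- function(seed, stage_offset, i) {
  (as.integer(seed) %% 100000L) * 10000L + stage_offset * 1000L + i
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stages and returns per-item result tables. When
#' `config$out_dir` is set, the tables, the fully-resolved config, a data
#' dictionary, and a one-line-per-item log are written there.
#'
#' @param config A config list (see [demo_config()]) or path to a YAML file.
#' @return A `fluidmorph_run`: `tables` (named list of tibbles, one row per
#'   analyzed object, with provenance columns), `config`, `seed`,
#'   `dictionary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  seed <- config$seed
  if (length(config$stages) == 0) {
    rlang::warn("no stages selected: returning an empty run")
  }
  tables <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  if ("transport" %in% config$stages) {
    tables$transport <- run_stage_transport(config$transport, note)
  }
  if ("fibers" %in% config$stages) {
    tables$fibers <- run_stage_fibers(config$fibers, seed, note)
  }
  if ("frap" %in% config$stages) {
    tables$frap <- run_stage_frap(config$frap, seed, note)
  }
  if ("cysts" %in% config$stages) {
    tables$cysts <- run_stage_cysts(config$cysts, seed, note)
  }

  run <- structure(
    list(tables = tables, config = config, seed = seed,
         dictionary = result_dictionary(), log = log),
    class = "fluidmorph_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

validate_config <- function(config) {
  if (!is.list(config)) stop_fm("config must be a list or a YAML file path")
  problems <- character(0)
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    problems <- c(problems, "`seed` (integer) is required")
  }
  known <- c("transport", "fibers", "frap", "cysts")
  config$stages <- config$stages %||% intersect(known, names(config))
  bad <- setdiff(config$stages, known)
  if (length(bad)) {
    problems <- c(problems, paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  for (st in config$stages) {
    if (is.null(config[[st]])) {
      problems <- c(problems, paste0("stage `", st, "` has no parameter block"))
    }
  }
  if (length(problems)) {
    stop_fm("invalid config:\n", paste0("  - ", problems, collapse = "\n"))
  }
  config$seed <- as.integer(config$seed)
  config
}

run_stage_transport <- function(p, note) {
  geom <- device_preset(p$preset %||% "aligned",
                        grid_spacing = p$grid_spacing %||% 2.5e-5)
  props <- porous_medium()
  if (!is.null(p$target_velocity_um_s)) {
    g_cal <- calibrate_pore_conductance(
      geom, props, p$target_velocity_um_s * 1e-6,
      p$reference_head_mm %||% 20
    )
    geom$pore_conductance <- g_cal
    note("transport: pore conductance calibrated to ", format(g_cal))
  }
  heads <- p$heads_mm %||% c(2, 20)
  rows <- purrr::map(heads, function(hd) {
    tryCatch({
      flow <- solve_darcy(geom, props, pressure_boundary(hd, 0))
      rp <- reynolds_peclet(flow)
      note("transport head ", hd, " mm: ok")
      tibble(
        head_mm = hd, delta_p_pa = flow$delta_p,
        v_max_um_s = rp$speed_max * 1e6, v_mean_um_s = rp$speed_mean * 1e6,
        re_max = rp$Re_max, pe_max = rp$Pe_max, error = NA_character_
      )
    }, error = function(e) {
      note("transport head ", hd, " mm: ERROR ", conditionMessage(e))
      tibble(head_mm = hd, delta_p_pa = NA_real_, v_max_um_s = NA_real_,
             v_mean_um_s = NA_real_, re_max = NA_real_, pe_max = NA_real_,
             error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)

  # pure-diffusion gradient experiment
  hours <- p$gradient_hours %||% 24
  grad <- tryCatch({
    flow0 <- solve_darcy(geom, props, pressure_boundary(0, 0))
    conc <- solve_transport(
      flow0, transport_params(total_time = hours * 3600),
      times = seq(0, hours * 3600, length.out = p$n_snapshots %||% 49)
    )
    gm <- gradient_metrics(conc)
    note("transport gradient: formed at ", gm$formation_time, " s")
    tibble(head_mm = 0, formation_time_s = gm$formation_time,
           maintained_24h = gm$maintained)
  }, error = function(e) {
    note("transport gradient: ERROR ", conditionMessage(e))
    tibble(head_mm = 0, formation_time_s = NA_real_, maintained_24h = NA)
  })
  dplyr::left_join(
    dplyr::bind_rows(out, tibble(head_mm = 0)), grad, by = "head_mm"
  )
}

run_stage_fibers <- function(p, seed, note) {
  n <- p$n_per_group %||% 2
  rows <- list()
  gi <- 0L
  for (gname in names(p$groups)) {
    g <- p$groups[[gname]]
    gi <- gi + 1L
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", gname, i)
      rows[[id]] <- tryCatch({
        gen <- gen_fiber_image(item_seed(seed, 1L + gi, i),
                               mean_angle = g$mean_angle %||% 90,
                               concentration = g$concentration %||% 4)
        smp <- estimate_orientations(gen$image)
        ac <- alignment_coefficient(smp)
        note("fibers ", id, ": coefficient ", round(ac$coefficient, 3))
        tibble(
          item = id, group = gname,
          coefficient = ac$coefficient, mean_angle = ac$mean_angle,
          n_angles = ac$n,
          fraction_70_110 = fraction_in_range(smp, 70, 110),
          true_concentration = g$concentration %||% 4,
          error = NA_character_
        )
      }, error = function(e) {
        note("fibers ", id, ": ERROR ", conditionMessage(e))
        tibble(item = id, group = gname, coefficient = NA_real_,
               mean_angle = NA_real_, n_angles = NA_integer_,
               fraction_70_110 = NA_real_,
               true_concentration = g$concentration %||% 4,
               error = conditionMessage(e))
      })
    }
  }
  dplyr::bind_rows(rows)
}

run_stage_frap <- function(p, seed, note) {
  speeds <- p$speeds_um_s %||% c(2, 10)
  n <- p$n_per_speed %||% 2
  rows <- list()
  for (si in seq_along(speeds)) {
    for (i in seq_len(n)) {
      id <- sprintf("v%g_%02d", speeds[si], i)
      rows[[id]] <- tryCatch({
        gen <- gen_frap_sequence(item_seed(seed, 10L + si, i),
                                 velocity = c(speeds[si], 0))
        est <- estimate_velocity(track_centroid(gen$sequence))
        note("frap ", id, ": ", round(est$speed, 2), " um/s")
        dplyr::bind_cols(tibble(item = id, true_speed = speeds[si]),
                         tidy(est), tibble(error = NA_character_))
      }, error = function(e) {
        note("frap ", id, ": ERROR ", conditionMessage(e))
        tibble(item = id, true_speed = speeds[si], speed = NA_real_,
               error = conditionMessage(e))
      })
    }
  }
  dplyr::bind_rows(rows)
}

run_stage_cysts <- function(p, seed, note) {
  n <- p$n_per_group %||% 3
  rows <- list()
  gi <- 0L
  for (gname in names(p$groups)) {
    g <- p$groups[[gname]]
    gi <- gi + 1L
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", gname, i)
      rows[[id]] <- tryCatch({
        pang <- g$protrusion_angles %||% numeric(0)
        prot <- if (length(pang)) {
          tibble(angle = pang, prominence = g$protrusion_prominence %||% 12,
                 width = 12)
        } else {
          NULL
        }
        gen <- gen_cyst_mask(item_seed(seed, 20L + gi, i),
                             semi_major = g$semi_major %||% 55,
                             semi_minor = g$semi_minor %||% 45,
                             protrusions = prot,
                             ruffle_amplitude_top = g$ruffle_top %||% 0,
                             ruffle_amplitude_bottom = g$ruffle_bottom %||% 0)
        shape <- cyst_shape(gen$mask, gen$pixel_size)
        sm <- shape_metrics(shape)
        pr <- detect_protrusions(shape)
        cr <- cyst_curvature_ratio(shape)
        pct_top <- if (nrow(pr) > 0) {
          percent_protrusions_top(pr, shape)$top_pct
        } else {
          NA_real_
        }
        note("cysts ", id, ": ", nrow(pr), " protrusions, ratio ",
             round(cr$ratio, 2))
        dplyr::bind_cols(
          tibble(item = id, group = gname), sm,
          tibble(n_protrusions = nrow(pr), pct_top = pct_top,
                 curvature_ratio = cr$ratio, error = NA_character_)
        )
      }, error = function(e) {
        note("cysts ", id, ": ERROR ", conditionMessage(e))
        tibble(item = id, group = gname, error = conditionMessage(e))
      })
    }
  }
  dplyr::bind_rows(rows)
}

result_dictionary <- function() {
  tibble::tribble(
    ~table, ~column, ~unit, ~description,
    "transport", "head_mm", "mm H2O", "applied head difference",
    "transport", "delta_p_pa", "Pa", "cross-chamber pressure difference",
    "transport", "v_max_um_s", "um/s", "maximum Darcy speed",
    "transport", "v_mean_um_s", "um/s", "mean Darcy speed",
    "transport", "re_max", "-", "maximum Reynolds number",
    "transport", "pe_max", "-", "maximum Peclet number",
    "transport", "formation_time_s", "s", "gradient formation time (10% criterion)",
    "transport", "maintained_24h", "-", "gradient maintained through 24 h",
    "fibers", "coefficient", "-", "alignment coefficient in [0,1]",
    "fibers", "mean_angle", "deg", "mean fiber orientation [0,180)",
    "fibers", "fraction_70_110", "-", "weighted fraction of angles in [70,110)",
    "frap", "true_speed", "um/s", "generator ground-truth speed",
    "frap", "speed", "um/s", "recovered convective speed",
    "frap", "direction", "deg", "recovered flow direction [0,360)",
    "frap", "fit_r2", "-", "pooled R2 of the centroid regression",
    "cysts", "area", "um^2", "projected cyst area",
    "cysts", "perimeter", "um", "contour perimeter",
    "cysts", "aspect_ratio", "-", "ellipse major/minor",
    "cysts", "roundness", "-", "4A/(pi major^2)",
    "cysts", "shape_factor", "-", "circularity 4 pi A / P^2",
    "cysts", "orientation_angle", "deg", "major-axis angle [0,180)",
    "cysts", "n_protrusions", "count", "detected protrusions",
    "cysts", "pct_top", "%", "protrusions in the top (gradient-facing) half",
    "cysts", "curvature_ratio", "-", "mean |kappa| top / bottom"
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    run$config, file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  for (nm in names(run$tables)) {
    write.csv(run$tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(run$dictionary, file.path(out_dir, "data_dictionary.csv"),
            row.names = FALSE)
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.fluidmorph_run <- function(x, ...) {
  cat("<fluidmorph_run> seed", x$seed, "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %s: %d rows x %d cols\n", nm, nrow(x$tables[[nm]]),
                ncol(x$tables[[nm]])))
  }
  invisible(x)
}

#' Flatten a pipeline run into a compact metric table
#'
#' One row per headline number of the run (per-head velocities and Reynolds
#' numbers, gradient formation, per-group mean alignment coefficient,
#' per-speed mean recovered FRAP speed, per-group mean cyst metrics), used
#' for regression-testing a demo run against its stored reference.
#'
#' @param run A `fluidmorph_run`.
#' @return Tibble: `metric`, `value`.
#' @export
demo_summary <- function(run) {
  stopifnot(inherits(run, "fluidmorph_run"))
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1L]] <<- tibble(metric = metric,
                                         value = as.numeric(value))
  }
  tr <- run$tables$transport
  if (!is.null(tr)) {
    for (i in seq_len(nrow(tr))) {
      if (is.finite(tr$v_max_um_s[i] %||% NA)) {
        add(sprintf("transport.v_max_um_s.head%g", tr$head_mm[i]),
            tr$v_max_um_s[i])
        add(sprintf("transport.re_max.head%g", tr$head_mm[i]), tr$re_max[i])
      }
    }
    ft <- tr$formation_time_s[is.finite(tr$formation_time_s)]
    if (length(ft)) add("transport.formation_time_s", ft[1])
  }
  fb <- run$tables$fibers
  if (!is.null(fb)) {
    s <- summarize_groups(fb)
    for (gr in unique(s$group)) {
      add(paste0("fibers.coefficient.", gr),
          s$mean[s$group == gr & s$column == "coefficient"])
    }
  }
  fr <- run$tables$frap
  if (!is.null(fr)) {
    for (v in sort(unique(fr$true_speed))) {
      add(sprintf("frap.speed_um_s.true%g", v),
          mean(fr$speed[fr$true_speed == v], na.rm = TRUE))
    }
  }
  cy <- run$tables$cysts
  if (!is.null(cy)) {
    s <- summarize_groups(cy)
    for (gr in unique(s$group)) {
      for (col in c("curvature_ratio", "shape_factor", "roundness")) {
        val <- s$mean[s$group == gr & s$column == col]
        if (length(val)) add(paste0("cysts.", col, ".", gr), val)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Group means with standard errors
#'
#' Per-group n, mean, and SEM for every numeric column, in long format. A
#' group of one reports `NA` SEM and is flagged.
#'
#' @param table A result tibble (one row per object).
#' @param grouping Name of the grouping column.
#' @return A tibble: `group`, `column`, `n`, `mean`, `sem`,
#'   `single_observation`.
#' @export
summarize_groups <- function(table, grouping = "group") {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) {
    return(tibble(group = character(0), column = character(0),
                  n = integer(0), mean = numeric(0), sem = numeric(0),
                  single_observation = logical(0)))
  }
  if (!grouping %in% names(table)) {
    stop_fm("grouping column `", grouping, "` not found")
  }
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  table |>
    dplyr::select(dplyr::all_of(c(grouping, num_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "column") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data[[grouping]], .data$column) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = ifelse(dplyr::n() > 1, sd(.data$value) / sqrt(dplyr::n()),
                   NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_observation = .data$n == 1) |>
    dplyr::rename(group = dplyr::all_of(grouping))
}
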