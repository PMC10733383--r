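# Named, configured end-to-end reproductions of the in-silico experiments:
# each registry entry builds its tissues, relaxes them and writes the tables
# underlying the corresponding figure panels (per-seed and pooled summaries,
# never styled figures). Two tiers: "smoke" runs every experiment on a
# reduced lattice in minutes; "full" uses the original lattice sizes.

# registry: name -> function(tier, seeds) returning list(tables, summary)
experiment_registry_impl <- function() {
  list(
    fig3b_relax = function(tier, seeds) {
      geom <- if (tier == "full") c(100L, 60L, 60L, 20L) else
        c(50L, 30L, 30L, 10L)
      res <- lapply(seeds, function(sd) {
        tz <- build_hex_lattice(geom[1L], geom[2L], geom[3L], geom[4L])
        tz <- assign_constriction(tz, sim_config2d("uniform", pc = 0.5,
                                                   seed = sd))
        a0 <- tissue_measures(tz)[, "area"]
        r <- relax2d(tz, sim_config2d(mode = "minimize"))
        st <- plate_cell_stats(r$tissue)
        sel <- tz$region == "plate" & !tz$constricting
        af <- tissue_measures(r$tissue)[, "area"]
        list(cells = cbind(seed = sd, st$cells),
             hist = cbind(seed = sd, st$angle_hist),
             summary = data.frame(seed = sd, mean_angle = st$mean_angle,
                                  sd_angle = st$sd_angle,
                                  mean_kappa = st$mean_kappa,
                                  area_ratio = mean(af[sel]) / mean(a0[sel])))
      })
      per_seed <- do.call(rbind, lapply(res, `[[`, "summary"))
      list(tables = list(cell_stats = do.call(rbind,
                                              lapply(res, `[[`, "cells")),
                         angle_hist = do.call(rbind,
                                              lapply(res, `[[`, "hist")),
                         per_seed = per_seed),
           summary = as.list(colMeans(per_seed[-1L])))
    },
    fig3c_angles = function(tier, seeds) {
      # same computation as fig3b_relax; kept as its own registry name so
      # the angle-distribution tables can be regenerated alone
      experiment_registry_impl()$fig3b_relax(tier, seeds)
    },
    fig3d_pc_sweep = function(tier, seeds) {
      geom <- if (tier == "full") c(100L, 60L, 60L, 20L) else
        c(50L, 30L, 30L, 10L)
      pcs <- c(0, 0.25, 0.5, 0.75, 1)
      ref <- relax2d(build_hex_lattice(geom[1L], geom[2L], geom[3L],
                                       geom[4L]),
                     sim_config2d(mode = "minimize"))$tissue
      rows <- do.call(rbind, lapply(seeds, function(sd) {
        do.call(rbind, lapply(pcs, function(pc) {
          tz <- build_hex_lattice(geom[1L], geom[2L], geom[3L], geom[4L])
          tz <- assign_constriction(tz, sim_config2d("uniform", pc = pc,
                                                     seed = sd))
          r <- relax2d(tz, sim_config2d(mode = "minimize"))
          pd <- plate_dimensions(r$tissue, ref)
          data.frame(seed = sd, pc = pc, length = pd[["length"]],
                     width = pd[["width"]])
        }))
      }))
      pooled <- aggregate(cbind(length, width) ~ pc, rows, mean)
      list(tables = list(per_run = rows, pooled = pooled),
           summary = list(
             length_monotone = all(diff(pooled$length) <= 1e-6),
             width_monotone = all(diff(pooled$width) <= 1e-6),
             length_at_pc_half = pooled$length[pooled$pc == 0.5],
             width_at_pc_half = pooled$width[pooled$pc == 0.5]))
    },
    fig3ef_alpha_sweep = function(tier, seeds) {
      n_alpha <- if (tier == "full") 16L else 5L
      target_n <- if (tier == "full") 1200 else 300
      margin <- if (tier == "full") 40L else 14L
      alphas <- exp(seq(log(1 / 3), log(3), length.out = n_alpha))
      rows <- do.call(rbind, lapply(seeds, function(sd) {
        do.call(rbind, lapply(alphas, function(al) {
          nx <- max(4L, round(sqrt(target_n / al)))
          ny <- max(4L, round(al * nx))
          tz <- build_hex_lattice(nx + margin, ny + margin, nx, ny)
          tz <- assign_constriction(tz, sim_config2d("uniform", pc = 0.5,
                                                     seed = sd))
          r <- relax2d(tz, sim_config2d(mode = "minimize"))
          st <- plate_cell_stats(r$tissue)
          data.frame(seed = sd, alpha = ny / nx, nx = nx, ny = ny,
                     n_cells = sum(tz$region == "plate" & !tz$constricting),
                     mean_angle = st$mean_angle, sd_angle = st$sd_angle,
                     mean_kappa = st$mean_kappa)
        }))
      }))
      pooled <- aggregate(cbind(mean_angle, mean_kappa) ~ alpha, rows, mean)
      list(tables = list(per_run = rows, pooled = pooled),
           summary = list(
             angle_low_alpha = pooled$mean_angle[1L],
             angle_high_alpha = pooled$mean_angle[nrow(pooled)],
             kappa_extremes_exceed_center =
               min(pooled$mean_kappa[c(1L, nrow(pooled))]) >
                 pooled$mean_kappa[which.min(abs(pooled$alpha - 1))]))
    },
    supp_geometry = function(tier, seeds) {
      base <- if (tier == "full") list(nx = 60L, ny = 20L) else
        list(nx = 30L, ny = 10L)
      variants <- if (tier == "full") {
        list(default = c(100L, 60L), aspect_matched = c(100L, 34L),
             square = c(100L, 100L), square_large = c(180L, 180L))
      } else {
        list(default = c(50L, 30L), aspect_matched = c(50L, 17L),
             square = c(50L, 50L))
      }
      rows <- do.call(rbind, lapply(names(variants), function(vn) {
        g <- variants[[vn]]
        do.call(rbind, lapply(seeds, function(sd) {
          tz <- build_hex_lattice(g[1L], g[2L], base$nx, base$ny)
          tz <- assign_constriction(tz, sim_config2d("uniform", pc = 0.5,
                                                     seed = sd))
          r <- relax2d(tz, sim_config2d(mode = "minimize"))
          st <- plate_cell_stats(r$tissue)
          data.frame(variant = vn, seed = sd, npx = g[1L], npy = g[2L],
                     mean_angle = st$mean_angle, sd_angle = st$sd_angle,
                     mean_kappa = st$mean_kappa)
        }))
      }))
      pooled <- aggregate(mean_angle ~ variant, rows, mean)
      list(tables = list(per_run = rows, pooled = pooled),
           summary = as.list(setNames(pooled$mean_angle, pooled$variant)))
    },
    supp_hinges = function(tier, seeds) {
      geom <- if (tier == "full") c(100L, 60L, 60L, 20L) else
        c(60L, 44L, 30L, 20L)
      rows <- do.call(rbind, lapply(seeds, function(sd) {
        tz <- build_hex_lattice(geom[1L], geom[2L], geom[3L], geom[4L])
        cfg <- sim_config2d("hinge", pc = 0.2, ph = 0.5, seed = sd)
        tz <- assign_constriction(tz, cfg)
        r <- relax2d(tz, sim_config2d(mode = "minimize"))
        st <- plate_cell_stats(r$tissue)
        hy <- sqrt(3) * hex_side()
        d <- abs(tz$centers[, "y"] - tz$plate_centerline) / hy
        in_band <- d > geom[4L] / 2 - cfg$band_width
        sel <- tz$region == "plate" & !tz$constricting
        data.frame(
          seed = sd,
          mean_angle_hinge = mean(st$cells$theta_deg[sel & in_band]),
          mean_angle_between = mean(st$cells$theta_deg[sel & !in_band]),
          sd_angle_between = sd(st$cells$theta_deg[sel & !in_band]))
      }))
      list(tables = list(per_seed = rows),
           summary = list(
             mean_angle_hinge = mean(rows$mean_angle_hinge),
             mean_angle_between = mean(rows$mean_angle_between)))
    },
    fig3hij_3d = function(tier, seeds) {
      geom <- if (tier == "full") c(20L, 40L) else c(10L, 24L)
      pcs <- c(0, 0.5, 1)
      rows <- do.call(rbind, lapply(seeds, function(sd) {
        do.call(rbind, lapply(pcs, function(pc) {
          tz <- build_prism_tissue(geom[1L], geom[2L], 3L, pc = pc,
                                   seed = sd)
          r <- relax3d(tz, "minimize")
          fp <- furrow_profile(r$tissue)
          ap <- apical_shape_stats(r$tissue)
          sel <- ap$hinge & !ap$constricting
          data.frame(seed = sd, pc = pc, depth = fp$depth,
                     mean_apical_angle_hinge =
                       if (any(sel)) mean(ap$theta_deg[sel]) else NA_real_)
        }))
      }))
      pooled <- aggregate(depth ~ pc, rows, mean)
      list(tables = list(per_run = rows, pooled = pooled),
           summary = list(depth_pc0 = pooled$depth[pooled$pc == 0],
                          depth_pc_half = pooled$depth[pooled$pc == 0.5],
                          depth_pc1 = pooled$depth[pooled$pc == 1]))
    }
  )
}

#' List the registered in-silico experiments
#' @return Character vector of registry names.
#' @export
list_experiments <- function() names(experiment_registry_impl())

#' Run a named in-silico experiment
#'
#' Executes a registry entry end to end (deterministic given `seeds`) and,
#' when `out_dir` is given, writes a result bundle: `config.json` (name,
#' tier, seeds, package version, config hash), one CSV per table, and
#' `summary.json` with the pooled summary.
#'
#' @param name Registry name; see [list_experiments()].
#' @param tier "smoke" (reduced lattice) or "full" (original sizes).
#' @param seeds Integer vector of RNG seeds.
#' @param out_dir Optional output directory (created if missing).
#' @return List: `name`, `tier`, `seeds`, `tables`, `summary`.
#' @export
run_experiment <- function(name, tier = c("smoke", "full"), seeds = 1L,
                           out_dir = NULL) {
  tier <- match.arg(tier)
  reg <- experiment_registry_impl()
  if (!name %in% names(reg)) {
    stop("unknown experiment '", name, "'; registry: ",
         paste(names(reg), collapse = ", "))
  }
  res <- reg[[name]](tier, as.integer(seeds))
  out <- list(name = name, tier = tier, seeds = as.integer(seeds),
              tables = res$tables, summary = res$summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- list(name = name, tier = tier, seeds = as.integer(seeds),
                package_version = as.character(utils::packageVersion("nfvm")),
                scaled_down = tier == "smoke")
    cfg$config_hash <- config_hash(cfg)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    for (tn in names(res$tables)) {
      write.csv(res$tables[[tn]], file.path(out_dir, paste0(tn, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# stable hash of a config list (md5 of its canonical JSON)
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(cfg[order(names(cfg))],
                                           auto_unbox = TRUE)), tf)
  unname(tools::md5sum(tf))
}
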