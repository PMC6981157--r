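#' Study configuration
#'
#' Bundles every constant of the end-to-end analysis: phantom geometry,
#' healing rule, loading model, threshold ladder, material law, analysis
#' controls and the global seed. All defaults mirror the reference
#' protocol: Gaussian filter sigma 1.2 / support 1, ladder 395..720 by 25
#' mg HA/cm^3, debris threshold 645 mg HA/cm^3, soft tissue 3 MPa, bone
#' 4-14 GPa, Poisson 0.3, 1% compression stiffness probe, 10.5 um voxels.
#'
#' @param geometry A [phantom_geometry()] (or NULL when `input_paths` point
#'   at existing image series).
#' @param rule A [healing_rule()]; its `rng_seed` is overridden by the
#'   study-level seed fan-out.
#' @param loading A [phantom_loading()].
#' @param ladder A [threshold_ladder()].
#' @param n_steps Number of healing steps (transitions); 0 gives a
#'   single-frame study with empty kinetics/overlay tables.
#' @param material Material constants: `E_soft`, `E_low`, `E_high` (MPa)
#'   and `nu`.
#' @param analysis Analysis controls: `sigma`, `support` (filter),
#'   `debris_threshold`, `heatmap_grid`, `fe_tol`, `roc_thresholds`
#'   (subset of the ladder; NULL = all).
#' @param image_noise_sigma CT-noise level added to the synthetic frames
#'   before analysis, mg HA/cm^3.
#' @param input_paths Optional character vector of MetaImage files (one per
#'   frame) to analyse instead of simulating.
#' @param seed Global RNG seed; per-stage seeds are derived from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(geometry = phantom_geometry(),
                         rule = healing_rule(),
                         loading = phantom_loading(),
                         ladder = threshold_ladder(),
                         n_steps = 5L,
                         material = list(E_soft = 3, E_low = 4000,
                                         E_high = 14000, nu = 0.3),
                         analysis = list(),
                         image_noise_sigma = 0,
                         input_paths = NULL,
                         seed = 1L) {
  analysis_defaults <- list(sigma = 1.2, support = 1L,
                            debris_threshold = 645, heatmap_grid = 64L,
                            fe_tol = 1e-6, roc_thresholds = NULL)
  analysis <- utils::modifyList(analysis_defaults, analysis)
  if (!("roc_thresholds" %in% names(analysis)))
    analysis["roc_thresholds"] <- list(NULL)
  cfg <- structure(list(geometry = geometry, rule = rule, loading = loading,
                        ladder = ladder, n_steps = as.integer(n_steps),
                        material = material, analysis = analysis,
                        image_noise_sigma = image_noise_sigma,
                        input_paths = input_paths,
                        seed = as.integer(seed)),
                   class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  m <- cfg$material
  for (key in c("E_soft", "E_low", "E_high", "nu"))
    if (is.null(m[[key]]) || !is.numeric(m[[key]]))
      stop(sprintf("study config is missing material constant `%s`", key))
  if (m$E_soft <= 0) stop("soft-tissue modulus must be positive")
  if (!(m$nu > 0 && m$nu < 0.5)) stop("Poisson's ratio must be in (0, 0.5)")
  if (m$E_low <= m$E_soft || m$E_high <= m$E_low)
    stop("bone moduli must satisfy E_soft < E_low < E_high")
  if (cfg$n_steps < 0L) stop("`n_steps` must be >= 0")
  if (cfg$image_noise_sigma < 0) stop("image noise sigma must be >= 0")
  stopifnot(inherits(cfg$ladder, "threshold_ladder"))
  if (is.null(cfg$input_paths)) stopifnot(inherits(cfg$geometry, "phantom_geometry"))
  invisible(cfg)
}

# deterministic seed fan-out; offsets keep the derived seeds below 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(rule = 101L, noise = 211L)
  (abs(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run a full phantom study
#'
#' Orchestrates the complete pipeline: phantom generation and healing
#' simulation (or loading an input image series), optional CT noise,
#' Gaussian filtering, ladder segmentation, VOI definition on the post-op
#' frame, per-frame micro-FE strain solves with two-spring boundary
#' conditions, ROC and surface-remodelling statistics, and kinetics tables.
#' Writes tidy CSVs, MetaImage volumes, a JSON manifest of every constant,
#' and a run log; deterministic under a fixed config seed.
#'
#' @param config A [study_config()].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with the result tables and the output path.
#' @export
run_study <- function(config, output_dir) {
  validate_study_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(output_dir, "run.log")
  cat(sprintf("run_study seed %d\n", config$seed), file = logf)
  logmsg <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage <- "phantom"
  result <- tryCatch({
    # ---- acquire the series ----
    if (is.null(config$input_paths)) {
      rule <- config$rule
      rule$rng_seed <- stage_seed(config$seed, "rule")
      postop <- build_phantom(config$geometry)
      if (config$n_steps >= 1L) {
        sim <- simulate_healing(postop, rule, config$loading,
                                config$n_steps, config$geometry,
                                ladder = config$ladder)
        series <- sim$series
        events <- sim$events
      } else {
        series <- list(postop)
        events <- NULL
      }
      if (config$image_noise_sigma > 0) {
        series <- lapply(seq_along(series), function(i)
          add_image_noise(series[[i]], config$image_noise_sigma,
                          stage_seed(config$seed, "noise") + i))
      }
    } else {
      series <- lapply(seq_along(config$input_paths), function(i)
        read_density_mha(config$input_paths[i], frame = i - 1L))
      events <- NULL
    }
    n_frames <- length(series)
    logmsg("series: %d frames of %s voxels", n_frames,
           paste(dim(series[[1]]$values), collapse = "x"))

    stage <- "imageproc"
    smooth <- lapply(series, gaussian_smooth, sigma = config$analysis$sigma,
                     support = config$analysis$support)
    masks <- lapply(smooth, apply_ladder, ladder = config$ladder)

    stage <- "voi"
    # VOIs come from the unfiltered post-op frame: the 645 threshold sits
    # ~10 noise SD above soft tissue, while filtering a sharp osteotomy
    # edge drags the end slices to ~0.707 x cortical density, i.e. onto
    # the threshold knife edge
    vois <- define_vois(series[[1]],
                        threshold = config$analysis$debris_threshold)
    write_voi_mha(vois, file.path(output_dir, "voi.mha"))
    logmsg("VOI: TV_defect %.4g mm^3, TV_fragment %.4g mm^3",
           vois$TV_defect, vois$TV_fragment)

    stage <- "kinetics"
    taus <- as.numeric(config$ladder)
    overlays <- list()
    if (n_frames >= 2L) {
      for (t in seq_len(n_frames - 1L)) {
        for (k in seq_along(taus)) {
          overlays[[length(overlays) + 1L]] <-
            overlay(masks[[t]][[k]], masks[[t + 1L]][[k]])
        }
      }
    }
    bvtv <- bvtv_timecourse(masks, vois)
    rates <- if (length(overlays)) remodelling_rates(overlays, vois) else
      data.frame()
    write.csv(bvtv, file.path(output_dir, "bvtv.csv"), row.names = FALSE)
    write.csv(rates, file.path(output_dir, "rates.csv"), row.names = FALSE)

    stage <- "microfe"
    roc_taus <- config$analysis$roc_thresholds
    if (is.null(roc_taus)) roc_taus <- taus
    strain_fields <- list()
    defect_region <- vois$FC | interpolate_periosteum(vois$FC)
    if (n_frames >= 2L) {
      for (t in seq_len(n_frames - 1L)) {
        mat <- material_from_image(smooth[[t]], ladder = config$ladder,
                                   E_soft = config$material$E_soft,
                                   E_low = config$material$E_low,
                                   E_high = config$material$E_high,
                                   nu = config$material$nu)
        probe <- axial_stiffness(mat, region = defect_region,
                                 tol = config$analysis$fe_tol)
        spr <- spring_model(config$loading$k_fixator, probe$k)
        est <- structure(list(F_axial = config$loading$F_axial, M_bend = 0),
                         class = "load_estimate")
        bc <- boundary_displacements(est, spr, dim(mat$E), mat$voxel_size)
        field <- fe_solve(mat, bc, tol = config$analysis$fe_tol)
        strain_fields[[t]] <- field
        write_mha(field$eff_strain,
                  file.path(output_dir, sprintf("eff_strain_%02d.mha", t - 1L)),
                  mat$voxel_size, "float")
        logmsg("frame %d: k_callus %.3g N/mm, closure %.4g mm, %d CG it",
               t - 1L, probe$k, attr(bc, "closure"), field$iterations)
      }
    }

    stage <- "mechreg"
    roc_rows <- list()
    ccr_rows <- list()
    dcdp <- vois$DC | vois$DP
    if (n_frames >= 2L) {
      for (t in seq_len(n_frames - 1L)) {
        for (k in which(taus %in% roc_taus)) {
          ov <- overlays[[(t - 1L) * length(taus) + k]]
          roc <- tryCatch(roc_analysis(strain_fields[[t]], ov, dcdp),
                          error = function(e) NULL)
          roc_rows[[length(roc_rows) + 1L]] <- data.frame(
            frame_from = t - 1L, frame_to = t, threshold = taus[k],
            auc = if (is.null(roc)) NA_real_ else roc$auc,
            tpr_opt = if (is.null(roc)) NA_real_ else roc$tpr_opt,
            fpr_opt = if (is.null(roc)) NA_real_ else roc$fpr_opt,
            T_opt = if (is.null(roc)) NA_real_ else roc$T_opt,
            n_pos = if (is.null(roc)) 0L else roc$n_pos,
            n_neg = if (is.null(roc)) 0L else roc$n_neg)
          sm <- extract_surface_states(ov, strain_fields[[t]])
          hm <- tryCatch(ccr_heatmap(sm, config$analysis$heatmap_grid),
                         error = function(e) NULL)
          ccr_rows[[length(ccr_rows) + 1L]] <- data.frame(
            frame_from = t - 1L, frame_to = t, threshold = taus[k],
            max_ccr = if (is.null(hm)) NA_real_ else hm$max_ccr,
            T_R_opt = if (is.null(hm)) NA_real_ else hm$T_R_opt,
            T_F_opt = if (is.null(hm)) NA_real_ else hm$T_F_opt,
            n_surface = length(sm$index))
        }
      }
    }
    roc_tab <- if (length(roc_rows)) do.call(rbind, roc_rows) else data.frame()
    ccr_tab <- if (length(ccr_rows)) do.call(rbind, ccr_rows) else data.frame()
    write.csv(roc_tab, file.path(output_dir, "roc.csv"), row.names = FALSE)
    write.csv(ccr_tab, file.path(output_dir, "ccr.csv"), row.names = FALSE)

    stage <- "manifest"
    manifest <- list(
      seed = config$seed,
      n_frames = n_frames,
      voxel_size_um = series[[1]]$voxel_size,
      ladder = as.numeric(config$ladder),
      debris_threshold = config$analysis$debris_threshold,
      filter = list(sigma = config$analysis$sigma,
                    support = config$analysis$support),
      material = config$material,
      loading = list(F_axial = config$loading$F_axial,
                     k_fixator = config$loading$k_fixator,
                     closure = config$loading$closure),
      rule = if (is.null(config$input_paths))
        unclass(config$rule) else NULL,
      geometry = if (is.null(config$input_paths))
        unclass(config$geometry) else NULL,
      analysis = config$analysis[c("heatmap_grid", "fe_tol")],
      image_noise_sigma = config$image_noise_sigma)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    logmsg("done")
    list(path = output_dir, bvtv = bvtv, rates = rates, roc = roc_tab,
         ccr = ccr_tab, vois = vois, series = series, events = events,
         strain_fields = strain_fields)
  }, error = function(e) {
    cat(sprintf("FAILED at stage %s: %s\n", stage, conditionMessage(e)),
        file = logf, append = TRUE)
    stop(sprintf("run_study failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Generate a summary report from a results directory
#'
#' Renders the CSV tables written by [run_study()] into a Markdown summary
#' plus PNG panels (BV/TV time courses, AUC per threshold over time, and a
#' CCR heat-map style summary). Every reported number is read from the
#' CSVs; nothing is recomputed. Regeneration is idempotent.
#'
#' @param results_dir Directory produced by [run_study()].
#' @return Path of the report file, invisibly.
#' @export
make_report <- function(results_dir) {
  manifest_path <- file.path(results_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("not a results directory (missing manifest.json): ", results_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  tabs <- list()
  for (nm in c("bvtv", "rates", "roc", "ccr")) {
    p <- file.path(results_dir, paste0(nm, ".csv"))
    tabs[[nm]] <- if (file.exists(p) && file.size(p) > 3) read.csv(p) else
      data.frame()
  }
  rp <- file.path(results_dir, "report.md")
  lines <- c("# Study report", "",
             sprintf("- frames: %s", manifest$n_frames),
             sprintf("- voxel size: %s um", manifest$voxel_size_um),
             sprintf("- seed: %s", manifest$seed), "")
  if (nrow(tabs$bvtv)) {
    lines <- c(lines, "## BV/TV by VOI (lowest and highest threshold)", "")
    sub <- tabs$bvtv[tabs$bvtv$threshold %in%
                       range(tabs$bvtv$threshold), ]
    lines <- c(lines, df_to_md(sub))
    png_path <- file.path(results_dir, "bvtv.png")
    grDevices::png(png_path, 900, 600)
    plot_bvtv(tabs$bvtv)
    grDevices::dev.off()
    lines <- c(lines, "", "![BV/TV](bvtv.png)", "")
  } else {
    lines <- c(lines, "## BV/TV", "", "_no kinetics: single-frame study_", "")
  }
  if (nrow(tabs$roc)) {
    lines <- c(lines, "## Strain-mineralisation association (ROC)", "",
               df_to_md(tabs$roc), "")
  } else {
    lines <- c(lines, "## ROC", "", "_not available_", "")
  }
  if (nrow(tabs$ccr)) {
    lines <- c(lines, "## Surface remodelling classification (CCR)", "",
               df_to_md(tabs$ccr), "")
  }
  writeLines(lines, rp)
  invisible(rp)
}

df_to_md <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 5))
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}

plot_bvtv <- function(bvtv) {
  vois <- unique(bvtv$voi)
  graphics::par(mfrow = c(2, 2))
  for (v in vois) {
    sub <- bvtv[bvtv$voi == v, ]
    taus <- sort(unique(sub$threshold))
    cols <- grDevices::hcl.colors(length(taus), "viridis")
    graphics::plot(NULL, xlim = range(sub$frame), ylim = range(sub$BVTV),
                   xlab = "week", ylab = "BV/TV", main = v)
    for (i in seq_along(taus)) {
      s2 <- sub[sub$threshold == taus[i], ]
      graphics::lines(s2$frame, s2$BVTV, col = cols[i])
    }
  }
}
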