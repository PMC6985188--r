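#' Quantification parameters
#'
#' One bag of knobs for the per-well pipeline. Intensity channels (DAPI, TF)
#' and the actin channel are background-corrected with a flat scalar estimate
#' (a low percentile of the image) by default: the colony is a wide plateau,
#' and a morphological (rolling-ball) background would absorb the cytoplasmic
#' signal itself on structures wider than the ball. The rolling-ball mode
#' remains available per channel for images with uneven illumination.
#'
#' @param bg_method,bg_param background method and parameter for the DAPI/TF
#'   channels (see [subtract_background()]).
#' @param actin_bg_method,actin_bg_param same for the actin channel.
#' @param min_area minimum nucleus area, µm².
#' @param split_touching,tolerance watershed controls ([segment_nuclei()]).
#' @param exclusion_dilate_px perinuclear exclusion: nuclear ROIs are grown by
#'   this many pixels before being subtracted from the cytoplasmic region in
#'   [nc_ratio()].
#' @param n_zones equal-area zones per well.
#' @param n_lines diameters for the actin profile.
#' @param contrast_threshold,flatness_cv actin classification thresholds
#'   ([classify_architecture()]).
#' @param control_gap,control_width unconfined control annulus geometry, µm
#'   beyond the well radius.
#' @return list of class `quant_params`.
#' @export
quant_params <- function(bg_method = "flat_percentile", bg_param = 25,
                         actin_bg_method = "flat_percentile", actin_bg_param = 25,
                         min_area = 20, split_touching = TRUE, tolerance = 0.5,
                         exclusion_dilate_px = 3,
                         n_zones = 4, n_lines = 8,
                         contrast_threshold = 1.25, flatness_cv = 0.15,
                         control_gap = 20, control_width = 100) {
  structure(as.list(environment()), class = "quant_params")
}

#' Quantify one microwell image
#'
#' The full single-well pipeline: per-channel background subtraction, nucleus
#' segmentation from DAPI, tissue mask from actin, equal-area zone assignment
#' and densities, per-nucleus TF intensities and N:C ratios (cytoplasm taken
#' within the well disc, nuclei excluded through a dilated perinuclear
#' buffer), normalization of well nuclear intensity to the surrounding
#' unconfined control ring, and the folded radial actin profile with its
#' architecture class.
#'
#' @param image a [multichannel_image] with channels `dapi`, `actin` and any
#'   of `tf1`, `tf2`.
#' @param well a [well_geometry()] in µm; `NULL` uses the image centre and
#'   requires `well_radius`.
#' @param well_radius fallback radius when `well` is NULL.
#' @param params a [quant_params()].
#' @return list of class `well_quant`: `records` (per-nucleus data.frame with
#'   zone, radial position, per-TF nuclear means and N:C), `zone_summary`,
#'   `nc` (named colony-level N:C per TF), `normalized` (named well/control
#'   intensity ratio per TF), `n_well`, `n_control`, `actin_profile`,
#'   `actin_class`, `well`, `params`.
#' @export
quantify_well <- function(image, well = NULL, well_radius = NULL,
                          params = quant_params()) {
  stopifnot(inherits(image, "multichannel_image"))
  px <- image$pixel_size
  if (is.null(well)) {
    if (is.null(well_radius)) stop("supply `well` or `well_radius`")
    d <- dim(image$channels[[1]])
    well <- well_geometry(((d[2] - 1) / 2) * px, ((d[1] - 1) / 2) * px,
                          well_radius)
  }
  dapi <- subtract_background(get_channel(image, "dapi"),
                              params$bg_method, params$bg_param)
  actin <- subtract_background(get_channel(image, "actin"),
                               params$actin_bg_method, params$actin_bg_param)
  tf_roles <- intersect(c("tf1", "tf2"), names(image$channels))
  tf_bs <- lapply(tf_roles, function(ch)
    subtract_background(get_channel(image, ch), params$bg_method,
                        params$bg_param))
  names(tf_bs) <- tf_roles

  rois <- segment_nuclei(dapi, px, min_area = params$min_area,
                         split_touching = params$split_touching,
                         tolerance = params$tolerance)
  tissue <- segment_tissue(actin, px)

  zones <- equal_area_zones(well$R, params$n_zones)
  records <- assign_zones(rois, well, zones)
  in_well <- !records$outside
  ctrl_in <- well$R + params$control_gap
  ctrl_out <- ctrl_in + params$control_width
  in_ctrl <- records$r_um >= ctrl_in & records$r_um <= ctrl_out
  records$region <- ifelse(in_well, "well", ifelse(in_ctrl, "control", "outside"))

  zone_summary <- zone_densities(records[in_well, , drop = FALSE], zones)

  nc <- stats::setNames(rep(NA_real_, length(tf_roles)), tf_roles)
  normalized <- nc
  if (nrow(records) > 0 && length(tf_roles) > 0) {
    excl <- dilate_rois(rois, params$exclusion_dilate_px, px)
    g <- pixel_grids(nrow(dapi), ncol(dapi), px)
    disc <- sqrt((g$x - well$cx)^2 + (g$y - well$cy)^2) <= well$R
    colony_mask <- tissue$mask & disc
    for (ch in tf_roles) {
      means <- nuclear_intensities(tf_bs[[ch]], rois)
      records[[paste0(ch, "_mean")]] <- means
      if (any(in_well) && sum(colony_mask) > 0) {
        well_rois <- subset_rois(rois, records$id[in_well])
        well_excl <- subset_rois(excl, records$id[in_well])
        # edge nuclei overhang the disc-clipped mask by construction; the
        # clipping warning is only meaningful for user-supplied masks
        res <- tryCatch(
          withCallingHandlers(
            nc_ratio(tf_bs[[ch]], well_rois, colony_mask,
                     exclusion = well_excl),
            warning = function(w) {
              if (grepl("fall outside the tissue mask", conditionMessage(w)))
                invokeRestart("muffleWarning")
            }),
          error = function(e) NULL)
        if (!is.null(res)) {
          nc[[ch]] <- res$colony
          percell <- rep(NA_real_, nrow(records))
          percell[in_well] <- res$per_nucleus
          records[[paste0(ch, "_nc")]] <- percell
        }
      }
      if (any(in_well) && any(in_ctrl)) {
        nrm <- normalize_to_control(means[in_well], means[in_ctrl])
        normalized[[ch]] <- nrm$normalized
        perc <- rep(NA_real_, nrow(records))
        perc[in_well] <- nrm$per_cell
        records[[paste0(ch, "_normalized")]] <- perc
      }
    }
  }

  prof <- radial_profile(actin, well, px, n_lines = params$n_lines)
  cls <- classify_architecture(prof, params$contrast_threshold,
                               params$flatness_cv)

  structure(list(records = records, zone_summary = zone_summary,
                 nc = nc, normalized = normalized,
                 n_well = sum(in_well), n_control = sum(in_ctrl),
                 actin_profile = prof, actin_class = cls,
                 well = well, params = params),
            class = "well_quant")
}

# Restrict a nucleus_rois object to a subset of ids (renumbered 1..n).
subset_rois <- function(rois, ids) {
  keep <- rois$table$id %in% ids
  relab <- integer(max(rois$table$id, 1L))
  relab[rois$table$id[keep]] <- seq_len(sum(keep))
  labels <- rois$labels
  sel <- labels > 0L
  mapped <- integer(length(labels))
  mapped[sel] <- ifelse(labels[sel] <= length(relab), relab[labels[sel]], 0L)
  labels[sel] <- mapped[sel]
  tab <- rois$table[keep, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(labels = labels, table = tab), class = "nucleus_rois")
}

#' @export
print.well_quant <- function(x, ...) {
  cat(sprintf(
    "<well_quant> R = %.0f um: %d nuclei in well, %d in control; actin %s\n",
    x$well$R, x$n_well, x$n_control, x$actin_class$class))
  invisible(x)
}

#' Read a pipeline configuration
#'
#' Configurations are YAML with top-level blocks `seed`, `output_dir`,
#' `params` (overrides for [quant_params()]), and exactly one input block:
#' `synthetic` (list `wells:` of `{diameter, n, actin_class, nc_ratio,
#' noise_sd}` entries, each optionally repeated via `count`) or `images`
#' (`dir`, `well_radius_um`, optional `channels` role order).
#'
#' @param path YAML file path, or an already-parsed list.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  has_syn <- !is.null(cfg$synthetic); has_img <- !is.null(cfg$images)
  if (has_syn == has_img)
    stop("config must have exactly one input block: `synthetic` or `images`")
  if (has_syn && is.null(cfg$seed))
    stop("synthetic input requires a `seed`")
  if (has_img) {
    if (is.null(cfg$images$dir) || !dir.exists(cfg$images$dir))
      stop("images$dir missing or does not exist")
  }
  if (is.null(cfg$output_dir)) stop("output_dir is required")
  cfg$params <- do.call(quant_params, as.list(cfg$params))
  structure(cfg, class = c("pipeline_config", "list"))
}

# Expand a synthetic config block into one spec per well.
expand_synthetic_wells <- function(cfg) {
  specs <- list()
  seed <- cfg$seed
  i <- 0L
  for (w in cfg$synthetic$wells) {
    count <- if (is.null(w$count)) 1L else w$count
    for (k in seq_len(count)) {
      i <- i + 1L
      args <- list(
        well_diameter = w$diameter,
        # per-well seed derived from the global one, kept within integer range
        seed = as.integer((as.numeric(seed) * 10007 + i) %%
                            .Machine$integer.max)
      )
      if (!is.null(w$n)) args$n_cells <- w$n
      if (!is.null(w$actin_class)) args$actin_class <- w$actin_class
      if (!is.null(w$nc_ratio)) args$tf_nc_ratio <- w$nc_ratio
      if (!is.null(w$tf_nuclear_mean)) args$tf_nuclear_mean <- w$tf_nuclear_mean
      if (!is.null(w$tf_control_mean)) args$tf_control_mean <- w$tf_control_mean
      if (!is.null(w$noise_sd)) args$noise_sd <- w$noise_sd
      if (!is.null(w$min_separation_frac))
        args$min_separation_frac <- w$min_separation_frac
      if (!is.null(w$control_density)) args$control_density <- w$control_density
      sp <- do.call(synthetic_well_spec, args)
      specs[[i]] <- list(spec = sp, well_id = i,
                         timepoint = if (is.null(w$timepoint)) NA else w$timepoint)
    }
  }
  specs
}

#' Run the quantification pipeline from a configuration
#'
#' Synthetic mode renders every configured well (seeded deterministically from
#' the global seed) and quantifies it; image mode reads every TIFF in the
#' input directory. Writes `per_nucleus.csv`, `per_zone.csv`, `per_well.csv`,
#' `actin_labels.csv`, `stats.csv` (ANOVA/Tukey of the normalized TF1
#' intensity across well diameters, when more than one diameter is present)
#' and `manifest.yaml` to `output_dir`. Reruns with identical config and seed
#' produce byte-identical outputs.
#'
#' @param config path to a YAML config or a config list
#'   (see [read_pipeline_config()]).
#' @return invisibly, a list with the assembled tables and output paths.
#' @export
run_quantification <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  jobs <- if (!is.null(cfg$synthetic)) {
    lapply(expand_synthetic_wells(cfg), function(j) {
      r <- render_microwell_image(j$spec)
      list(image = r$image, well_id = j$well_id,
           well = well_geometry(r$truth$well$cx, r$truth$well$cy,
                                r$truth$well$R),
           diameter = j$spec$well_diameter, timepoint = j$timepoint)
    })
  } else {
    paths <- sort(list.files(cfg$images$dir, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0)
      stop(sprintf("no TIFF images found in %s", cfg$images$dir))
    lapply(seq_along(paths), function(i) {
      img <- read_image_tiff(paths[i],
                             channel_names = cfg$images$channels,
                             pixel_size = cfg$images$pixel_size)
      for (role in c("dapi", "actin"))
        if (!role %in% names(img$channels))
          stop(sprintf("channel role '%s' missing in %s", role, paths[i]))
      d <- dim(img$channels[[1]]); px <- img$pixel_size
      list(image = img, well_id = i,
           well = well_geometry(((d[2] - 1) / 2) * px, ((d[1] - 1) / 2) * px,
                                cfg$images$well_radius_um),
           diameter = 2 * cfg$images$well_radius_um, timepoint = NA)
    })
  }

  per_nucleus <- list(); per_zone <- list(); per_well <- list(); labels <- list()
  for (j in jobs) {
    q <- quantify_well(j$image, well = j$well, params = cfg$params)
    rec <- q$records
    if (nrow(rec) > 0) rec <- cbind(well_id = j$well_id, rec)
    per_nucleus[[length(per_nucleus) + 1L]] <- rec
    per_zone[[length(per_zone) + 1L]] <-
      cbind(well_id = j$well_id, diameter_um = j$diameter, q$zone_summary)
    per_well[[length(per_well) + 1L]] <- data.frame(
      well_id = j$well_id, diameter_um = j$diameter,
      timepoint = j$timepoint,
      n_nuclei = q$n_well, n_control = q$n_control,
      density_cells_mm2 = q$n_well / (pi * (j$diameter / 2)^2) * 1e6,
      tf1_nc = if ("tf1" %in% names(q$nc)) q$nc[["tf1"]] else NA_real_,
      tf2_nc = if ("tf2" %in% names(q$nc)) q$nc[["tf2"]] else NA_real_,
      tf1_normalized = if ("tf1" %in% names(q$normalized))
        q$normalized[["tf1"]] else NA_real_,
      tf2_normalized = if ("tf2" %in% names(q$normalized))
        q$normalized[["tf2"]] else NA_real_
    )
    labels[[length(labels) + 1L]] <- data.frame(
      well_id = j$well_id, diameter_um = j$diameter, timepoint = j$timepoint,
      actin_class = q$actin_class$class,
      center_mean = q$actin_class$center_mean,
      edge_mean = q$actin_class$edge_mean,
      cv = q$actin_class$cv, weak = q$actin_class$weak)
  }
  tables <- list(
    per_nucleus = do.call(rbind, per_nucleus),
    per_zone = do.call(rbind, per_zone),
    per_well = do.call(rbind, per_well),
    actin_labels = do.call(rbind, labels)
  )

  stats_tab <- data.frame(comparison = character(0), statistic = numeric(0),
                          p = numeric(0), p_adj = numeric(0),
                          tier = character(0))
  pw <- tables$per_well
  if (length(unique(pw$diameter_um)) >= 2 &&
      any(is.finite(pw$tf1_normalized))) {
    groups <- split(pw$tf1_normalized[is.finite(pw$tf1_normalized)],
                    pw$diameter_um[is.finite(pw$tf1_normalized)])
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) >= 2 && stats::var(unlist(groups)) > 0) {
      at <- one_way_anova_tukey(groups)
      stats_tab <- rbind(
        data.frame(comparison = "ANOVA tf1_normalized ~ diameter",
                   statistic = at$F, p = at$p, p_adj = NA_real_,
                   tier = at$tier),
        data.frame(comparison = paste("Tukey", at$tukey$comparison),
                   statistic = at$tukey$diff, p = NA_real_,
                   p_adj = at$tukey$p_adj, tier = at$tukey$tier))
    }
  }
  tables$stats <- stats_tab

  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(cfg$output_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  manifest <- list(seed = cfg$seed,
                   n_wells = length(jobs),
                   package = "wellquant",
                   version = as.character(utils::packageVersion("wellquant")),
                   params = unclass(cfg$params),
                   input = if (!is.null(cfg$synthetic)) "synthetic" else "images")
  mp <- file.path(cfg$output_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  paths["manifest"] <- mp
  invisible(list(tables = tables, paths = paths))
}

#' Synthetic validation: recover generator truth through the full pipeline
#'
#' Renders the configured synthetic cohort, pushes every well through
#' [quantify_well()], joins the estimates against the generator ground truth
#' and scores them against the configured tolerances.
#'
#' @param config config path or list; must use the `synthetic` input block
#'   and carry a `tolerances` block with `count_exact` (logical), `nc_rel_tol`
#'   (relative N:C error bound) and `actin_min_accuracy`.
#' @return list of class `recovery_report`: `wells` (per-well truth vs
#'   estimate table; wells with no cells are marked `empty`), `summary`
#'   (named metrics), `pass` (named logicals against the tolerances).
#' @export
run_synthetic_validation <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$synthetic)) stop("synthetic validation needs synthetic input")
  tol <- cfg$tolerances
  if (is.null(tol)) stop("tolerances block missing")
  rows <- list()
  for (j in expand_synthetic_wells(cfg)) {
    r <- render_microwell_image(j$spec)
    truth <- r$truth
    if (j$spec$n_cells == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = j$well_id, diameter_um = j$spec$well_diameter,
        status = "empty", n_true = 0L, n_est = NA_integer_,
        count_ok = NA, zones_exact = NA,
        nc_true = NA_real_, nc_est = NA_real_, nc_rel_err = NA_real_,
        actin_true = truth$actin_class, actin_est = NA_character_,
        actin_ok = NA)
      next
    }
    q <- quantify_well(r$image,
                       well = well_geometry(truth$well$cx, truth$well$cy,
                                            truth$well$R),
                       params = cfg$params)
    est_counts <- q$zone_summary$count
    nc_true <- truth$true_nc[["tf1"]]
    nc_est <- q$nc[["tf1"]]
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = j$well_id, diameter_um = j$spec$well_diameter,
      status = "ok", n_true = j$spec$n_cells, n_est = q$n_well,
      count_ok = q$n_well == j$spec$n_cells,
      zones_exact = all(est_counts == truth$zone_counts),
      nc_true = nc_true, nc_est = nc_est,
      nc_rel_err = abs(nc_est - nc_true) / nc_true,
      actin_true = truth$actin_class, actin_est = q$actin_class$class,
      actin_ok = q$actin_class$class == truth$actin_class)
  }
  wells <- do.call(rbind, rows)
  ok <- wells$status == "ok"
  summary <- c(
    n_wells = nrow(wells), n_empty = sum(!ok),
    count_accuracy = if (any(ok)) mean(wells$count_ok[ok]) else NA_real_,
    zone_accuracy = if (any(ok)) mean(wells$zones_exact[ok]) else NA_real_,
    nc_median_rel_err = if (any(ok)) stats::median(wells$nc_rel_err[ok],
                                                   na.rm = TRUE) else NA_real_,
    actin_accuracy = if (any(ok)) mean(wells$actin_ok[ok]) else NA_real_
  )
  pass <- c(
    counts = !isTRUE(tol$count_exact) || isTRUE(summary[["count_accuracy"]] == 1),
    nc = is.null(tol$nc_rel_tol) ||
      isTRUE(summary[["nc_median_rel_err"]] <= tol$nc_rel_tol),
    actin = is.null(tol$actin_min_accuracy) ||
      isTRUE(summary[["actin_accuracy"]] >= tol$actin_min_accuracy)
  )
  structure(list(wells = wells, summary = summary, pass = pass),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(round(x$summary, 4))
  cat("pass:", paste(names(x$pass), x$pass, collapse = ", "), "\n")
  invisible(x)
}

#' Cohort simulation of the diameter significance pattern
#'
#' Simulates repeated experiments comparing the nuclear:cytoplasmic TF ratio
#' across well diameters against an unconfined control, at the study's group
#' sizes (21 / 13 / 9 wells for 150 / 300 / 500 µm), and scores how often the
#' configured pattern — the two smaller diameters significantly elevated
#' versus control, the 500 µm wells not — is recovered by the ANOVA + Tukey
#' analysis.
#'
#' The simulation is two-level. First the per-well N:C *estimation* error of
#' the imaging pipeline is calibrated by rendering and fully quantifying
#' `n_calibration` synthetic wells. Each cohort replicate then draws per-well
#' true values (group mean plus between-well biological variation
#' `well_sd`), applies calibrated estimation noise, and runs the actual
#' [one_way_anova_tukey()] code on the resulting four groups.
#'
#' @param n_replicates cohort replicates (default 100).
#' @param group_sizes named well counts for the three diameters.
#' @param n_control unconfined control wells per cohort.
#' @param nc_elevated true N:C of the elevated groups (150 and 300 µm).
#' @param nc_base true N:C of the 500 µm wells and the control.
#' @param well_sd between-well biological sd of the true N:C.
#' @param n_calibration wells rendered to calibrate estimation error.
#' @param calibration_diameter diameter (µm) of the calibration wells.
#' @param noise_sd imaging noise of the calibration renders (a.u.).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return list of class `cohort_sim`: `pattern_rate` (fraction of replicates
#'   recovering the full pattern), `rate_150`, `rate_300`, `rate_500_null`
#'   (per-comparison rates), `calibration` (mean/sd of relative estimation
#'   error), `n_replicates`.
#' @export
simulate_significance_cohort <- function(n_replicates = 100,
                                         group_sizes = c(`150` = 21, `300` = 13,
                                                         `500` = 9),
                                         n_control = 10,
                                         nc_elevated = 2.4,
                                         nc_base = 1.5,
                                         well_sd = 0.15,
                                         n_calibration = 8,
                                         calibration_diameter = 150,
                                         noise_sd = 5,
                                         alpha = 0.05,
                                         seed = 1L) {
  set.seed(seed)
  cal_levels <- rep(c(nc_base, nc_elevated), length.out = n_calibration)
  rel_err <- vapply(seq_len(n_calibration), function(i) {
    sp <- synthetic_well_spec(well_diameter = calibration_diameter,
                              tf_nc_ratio = cal_levels[i],
                              noise_sd = noise_sd,
                              seed = sample.int(.Machine$integer.max, 1))
    r <- render_microwell_image(sp, channels = c("dapi", "actin", "tf1"))
    q <- quantify_well(r$image,
                       well = well_geometry(r$truth$well$cx, r$truth$well$cy,
                                            r$truth$well$R))
    (q$nc[["tf1"]] - cal_levels[i]) / cal_levels[i]
  }, numeric(1))
  err_mean <- mean(rel_err); err_sd <- stats::sd(rel_err)

  truth_means <- c(`150` = nc_elevated, `300` = nc_elevated, `500` = nc_base)
  hits <- matrix(FALSE, n_replicates, 3,
                 dimnames = list(NULL, c("150", "300", "500")))
  for (r in seq_len(n_replicates)) {
    groups <- lapply(names(group_sizes), function(g) {
      true <- stats::rnorm(group_sizes[[g]], truth_means[[g]], well_sd)
      true * (1 + stats::rnorm(group_sizes[[g]], err_mean, err_sd))
    })
    names(groups) <- names(group_sizes)
    ctrl <- stats::rnorm(n_control, nc_base, well_sd)
    groups$control <- ctrl * (1 + stats::rnorm(n_control, err_mean, err_sd))
    at <- one_way_anova_tukey(groups)
    tk <- at$tukey
    p_vs_ctrl <- function(g) {
      sel <- grepl("control", tk$comparison) & grepl(g, tk$comparison)
      tk$p_adj[sel][1]
    }
    hits[r, "150"] <- p_vs_ctrl("150") < alpha
    hits[r, "300"] <- p_vs_ctrl("300") < alpha
    hits[r, "500"] <- p_vs_ctrl("500") >= alpha
  }
  structure(list(
    pattern_rate = mean(rowSums(hits) == 3L),
    rate_150 = mean(hits[, "150"]), rate_300 = mean(hits[, "300"]),
    rate_500_null = mean(hits[, "500"]),
    calibration = c(mean = err_mean, sd = err_sd),
    n_replicates = n_replicates
  ), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim> pattern recovered in %.0f%% of %d replicates (150: %.2f, 300: %.2f, 500 null: %.2f)\n",
    100 * x$pattern_rate, x$n_replicates, x$rate_150, x$rate_300,
    x$rate_500_null))
  invisible(x)
}
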