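#' Pipeline run configuration
#'
#' Assembles all inputs and tuning parameters of the end-to-end analysis.
#' Interval-1 (baseline to binge) analyses are carried out on the
#' baseline group-wise template, interval-2 (binge to recovery) analyses
#' on the binge template; the two are never mixed.
#'
#' @param manifest path to the cohort manifest CSV (`subject`, `group`,
#'   `scan1`..`scan3`).
#' @param template,template_mask NIfTI paths: skull-strip template and its
#'   brain mask.
#' @param atlas_labels,atlas_lut,atlas_tissue atlas files (see
#'   [load_atlas()]).
#' @param atlas_intensity optional atlas-space intensity image; defaults
#'   to `template` (appropriate when the atlas is defined in template
#'   space, as for the phantom's own label map).
#' @param outdir output directory.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param reg,strip_reg [reg_params()] for interval/group-wise and
#'   skull-strip registrations.
#' @param n_outer_groupwise outer iterations of template construction.
#' @param denoise_strength see [denoise()].
#' @param voxel_p,alpha,connectivity,n_perm,n_sim statistical settings
#'   (voxel threshold, family-wise rate, cluster connectivity,
#'   permutations, Monte-Carlo simulations).
#' @param threshold_pct ROI relevance threshold (percent).
#' @param midplane_axis left-right axis index.
#' @param histogram_match match the earlier scan's intensity profile to the
#'   later scan before each interval registration. With large focal volume
#'   changes, whole-histogram matching shifts tissue intensities
#'   group-specifically; the registration's own foreground-median
#'   normalisation is the robust alternative.
#' @return a `run_config` list.
#' @export
run_config <- function(manifest, template, template_mask,
                       atlas_labels, atlas_lut, atlas_tissue = NULL,
                       atlas_intensity = template,
                       outdir, seed = 1L,
                       reg = reg_params(),
                       strip_reg = reg_params(iterations = c(20, 10, 5)),
                       n_outer_groupwise = 3,
                       denoise_strength = 1,
                       voxel_p = 0.01, alpha = 0.05, connectivity = 6,
                       n_perm = 5000, n_sim = 500,
                       threshold_pct = 10, midplane_axis = 1,
                       histogram_match = TRUE) {
  cfg <- list(manifest = manifest, template = template,
              template_mask = template_mask, atlas_labels = atlas_labels,
              atlas_lut = atlas_lut, atlas_tissue = atlas_tissue,
              atlas_intensity = atlas_intensity, outdir = outdir,
              seed = as.integer(seed), reg = reg, strip_reg = strip_reg,
              n_outer_groupwise = n_outer_groupwise,
              denoise_strength = denoise_strength, voxel_p = voxel_p,
              alpha = alpha, connectivity = connectivity, n_perm = n_perm,
              n_sim = n_sim, threshold_pct = threshold_pct,
              midplane_axis = midplane_axis,
              histogram_match = isTRUE(histogram_match))
  for (f in c("manifest", "template", "template_mask", "atlas_labels", "atlas_lut")) {
    if (!file.exists(cfg[[f]])) stop("missing input file for '", f, "': ", cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys match the [run_config()] arguments
#'   (registration parameter blocks `reg` and `strip_reg` are passed to
#'   [reg_params()]).
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("reg", "strip_reg")) if (!is.null(y[[nm]]))
    y[[nm]] <- do.call(reg_params, y[[nm]])
  do.call(run_config, y)
}

right_hemisphere_mask <- function(d, axis) {
  m <- array(FALSE, d)
  n <- d[axis]
  idx <- (floor(n / 2) + 1):n
  if (axis == 1) m[idx, , ] <- TRUE else if (axis == 2) m[, idx, ] <- TRUE else
    m[, , idx] <- TRUE
  m
}

#' Run the full morphometry pipeline
#'
#' Executes, per the comparison plan: preprocessing (denoise, bias
#' correction, skull strip, second bias pass, rigid alignment to the
#' template), per-interval intensity matching and non-rigid registration
#' into log-Jacobian maps, group-wise template construction per
#' timepoint, transport and bilateral averaging of the maps, voxel-wise
#' one-tailed permutation tests on the right hemisphere with Monte-Carlo
#' cluster-extent correction, cluster-to-atlas mapping, and per-ROI
#' overlap tables with reversible/enduring pattern labels. Every
#' stochastic step is seeded from `config$seed`; outputs and a checksum
#' manifest are written under `config$outdir`.
#'
#' @param config a [run_config()].
#' @param keep_volumes also serialize templates and cluster masks as
#'   NIfTI (default TRUE).
#' @return invisibly, a list with `tables` (per comparison family),
#'   `interval_tables`, `thresholds`, `clusters`, `templates`, `log`.
#' @export
run_pipeline <- function(config, keep_volumes = TRUE) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  t_start <- Sys.time()
  stage <- function(name, subject = NA_character_, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s'%s failed: %s", name,
                   if (is.na(subject)) "" else paste0(" (subject ", subject, ")"),
                   conditionMessage(e)), call. = FALSE))
    log[[length(log) + 1]] <<- data.frame(
      stage = name, subject = subject,
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      stringsAsFactors = FALSE)
    res
  }

  manifest <- read.csv(cfg$manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "group", "scan1", "scan2", "scan3") %in% names(manifest)))
  if (min(table(manifest$group)) < 2) stop("need >= 2 subjects per group")

  template <- read_volume(cfg$template)
  tmask <- read_volume(cfg$template_mask)
  template$mask <- array(tmask$data > 0.5, dim(template$data))

  atlas <- stage("load_atlas", expr = load_atlas(
    cfg$atlas_labels, cfg$atlas_lut, cfg$atlas_tissue,
    intensity_file = cfg$atlas_intensity))

  # --- preprocessing ------------------------------------------------------
  pre <- list()
  for (si in seq_len(nrow(manifest))) {
    sid <- manifest$subject[si]
    pre[[sid]] <- vector("list", 3)
    for (tp in 1:3) {
      scan <- read_volume(manifest[[paste0("scan", tp)]][si])
      scan <- stage("denoise", sid, denoise(scan, cfg$denoise_strength))
      scan <- stage("bias_1", sid, correct_bias(scan)$corrected)
      scan <- stage("skull_strip", sid, skull_strip(scan, template,
                                                    params = cfg$strip_reg))
      scan <- stage("bias_2", sid, correct_bias(scan)$corrected)
      scan <- stage("rigid_align", sid, rigid_align(scan, template)$resampled)
      pre[[sid]][[tp]] <- scan
    }
  }

  # --- interval log-Jacobian maps on the earlier scan's grid --------------
  jmaps <- list()  # jmaps[[interval]][[subject]]
  for (iv in 1:2) {
    jmaps[[iv]] <- list()
    for (sid in manifest$subject) {
      earlier <- pre[[sid]][[iv]]
      later <- pre[[sid]][[iv + 1]]
      matched <- if (cfg$histogram_match) {
        stage("match_intensity", sid, match_intensity(earlier, later))
      } else earlier
      fld <- stage("register_interval", sid,
                   register_nonrigid(matched, later, cfg$reg))
      jmaps[[iv]][[sid]] <- stage("log_jacobian", sid,
                                  log_jacobian(fld, provenance = list(
                                    subject = sid, interval = iv)))
    }
  }

  # --- group-wise templates per timepoint pair ----------------------------
  gw <- list()
  for (iv in 1:2) {
    vols <- lapply(manifest$subject, function(sid) pre[[sid]][[iv]])
    gw[[iv]] <- stage(paste0("groupwise_t", iv), expr = build_groupwise_template(
      vols, cfg$reg, n_outer_iter = cfg$n_outer_groupwise))
  }

  # --- transport, bilateral averaging -------------------------------------
  tmaps <- list()
  for (iv in 1:2) {
    tmaps[[iv]] <- list()
    for (si in seq_along(manifest$subject)) {
      sid <- manifest$subject[si]
      m <- to_template_space(jmaps[[iv]][[sid]], gw[[iv]]$fields[[si]])
      tmaps[[iv]][[sid]] <- bilateral_average(m, cfg$midplane_axis)
    }
  }

  # --- comparisons ---------------------------------------------------------
  groups <- manifest$group
  plan <- list(
    between_1 = list(interval = 1, type = "two_sample", subjects = manifest$subject),
    between_2 = list(interval = 2, type = "two_sample", subjects = manifest$subject),
    within_EtOH_1 = list(interval = 1, type = "one_sample",
                         subjects = manifest$subject[groups == "EtOH"]),
    within_EtOH_2 = list(interval = 2, type = "one_sample",
                         subjects = manifest$subject[groups == "EtOH"]),
    within_Con_1 = list(interval = 1, type = "one_sample",
                        subjects = manifest$subject[groups == "Con"]),
    within_Con_2 = list(interval = 2, type = "one_sample",
                        subjects = manifest$subject[groups == "Con"]))

  thresholds <- list()
  clusters <- list()
  atlas_masks <- list()
  t2a_fields <- list()
  for (iv in 1:2) {
    t2a_fields[[iv]] <- stage(paste0("register_template_to_atlas_t", iv),
                              expr = register_nonrigid(atlas$intensity,
                                                       gw[[iv]]$template, cfg$reg))
  }

  for (cname in names(plan)) {
    pl <- plan[[cname]]
    iv <- pl$interval
    maps <- tmaps[[iv]][pl$subjects]
    design <- if (pl$type == "two_sample") {
      list(type = "two_sample", groups = groups)
    } else list(type = "one_sample")
    d <- dim(maps[[1]]$values)
    hemi <- right_hemisphere_mask(d, cfg$midplane_axis)
    brain <- gw[[iv]]$template$mask
    mask <- hemi & brain
    seed_c <- child_seed(cfg$seed, "perm", cname)

    pm_g <- stage(paste0("perm_", cname, "_greater"), expr = permutation_p(
      maps, design, "greater", n_perm = cfg$n_perm, seed = seed_c, mask = mask))
    pm_l <- stage(paste0("perm_", cname, "_less"), expr = permutation_p(
      maps, design, "less", n_perm = cfg$n_perm, seed = seed_c, mask = mask))

    X <- maps_matrix(maps)
    mm <- array(rowMeans(X), d)
    if (pl$type == "two_sample") {
      res <- lapply(seq_along(maps), function(i) {
        gmean <- rowMeans(X[, groups == groups[i], drop = FALSE])
        array(X[, i] - gmean, d)
      })
    } else {
      res <- lapply(seq_along(maps), function(i) array(X[, i], d) - mm)
    }
    fw <- stage(paste0("fwhm_", cname), expr = estimate_fwhm(
      res, mask, maps[[1]]$spacing))
    thr <- stage(paste0("mc_threshold_", cname), expr = mc_cluster_threshold(
      geometry = list(dim = d, spacing = maps[[1]]$spacing), mask = mask,
      fwhm_mm = fw$fwhm_mm, voxel_p = cfg$voxel_p, alpha = cfg$alpha,
      connectivity = cfg$connectivity, n_sim = cfg$n_sim,
      seed = child_seed(cfg$seed, "mc", cname)))
    thresholds[[cname]] <- data.frame(
      comparison = cname, voxel_p = cfg$voxel_p,
      fwhm_x = fw$fwhm_mm[1], fwhm_y = fw$fwhm_mm[2], fwhm_z = fw$fwhm_mm[3],
      alpha = cfg$alpha, min_cluster_size = thr$min_cluster_size,
      n_sim = cfg$n_sim, seed = thr$seed, stringsAsFactors = FALSE)

    cs_e <- extract_clusters(pm_g, cfg$voxel_p, thr$min_cluster_size,
                             cfg$connectivity, comparison = cname)
    cs_s <- extract_clusters(pm_l, cfg$voxel_p, thr$min_cluster_size,
                             cfg$connectivity, comparison = cname)
    clusters[[cname]] <- list(expand = cs_e, shrink = cs_s)
    atlas_masks[[cname]] <- list(
      expand = map_clusters_to_atlas(cs_e, t2a_fields[[iv]],
                                     midplane_axis = cfg$midplane_axis),
      shrink = map_clusters_to_atlas(cs_s, t2a_fields[[iv]],
                                     midplane_axis = cfg$midplane_axis))
  }

  # --- ROI overlap tables --------------------------------------------------
  interval_tables <- lapply(names(plan), function(cname) {
    roi_overlap_table(atlas_masks[[cname]]$expand, atlas_masks[[cname]]$shrink,
                      atlas, plan[[cname]]$interval)
  })
  names(interval_tables) <- names(plan)
  families <- list(
    between = c("between_1", "between_2"),
    within_EtOH = c("within_EtOH_1", "within_EtOH_2"),
    within_Con = c("within_Con_1", "within_Con_2"))
  tables <- lapply(families, function(fam)
    combine_interval_tables(interval_tables[[fam[1]]], interval_tables[[fam[2]]],
                            cfg$threshold_pct))

  log_df <- do.call(rbind, log)
  result <- list(tables = tables, interval_tables = interval_tables,
                 thresholds = do.call(rbind, thresholds),
                 clusters = clusters, templates = lapply(gw, `[[`, "template"),
                 log = log_df,
                 total_seconds = as.numeric(Sys.time() - t_start, units = "secs"))
  write_report(result, cfg, keep_volumes = keep_volumes)
  invisible(result)
}

#' Write the report bundle
#'
#' Emits, under `config$outdir`: one CSV per comparison family in the
#' printed-table column order (display twin with empty cells where no
#' significant cluster overlapped the ROI, machine twin with zeros), the
#' per-comparison threshold report, a pattern summary text grouping ROIs
#' at or above the relevance threshold, the run log, the effective
#' configuration, and a checksum manifest of all written files.
#'
#' @param result pipeline result list (see [run_pipeline()]).
#' @param config the [run_config()] used.
#' @param keep_volumes serialize templates as NIfTI.
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, config, keep_volumes = TRUE) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, mode = 2) != 0) stop("output directory not writable: ", outdir)
  paths <- character(0)
  put <- function(p) { paths[[length(paths) + 1]] <<- p; p }
  for (fam in names(result$tables)) {
    tab <- result$tables[[fam]]
    machine <- file.path(outdir, paste0("table_", fam, ".csv"))
    write.csv(tab, put(machine), row.names = FALSE)
    disp <- tab
    for (cc in c("expand_vol_1", "expand_pct_1", "shrink_vol_1", "shrink_pct_1",
                 "expand_vol_2", "expand_pct_2", "shrink_vol_2", "shrink_pct_2")) {
      vol_col <- sub("pct", "vol", cc)
      nd <- tab[[vol_col]] == 0
      disp[[cc]] <- as.character(disp[[cc]])
      disp[[cc]][nd] <- ""
    }
    write.csv(disp, put(file.path(outdir, paste0("table_", fam, "_display.csv"))),
              row.names = FALSE)
  }
  for (cname in names(result$interval_tables)) {
    write.csv(result$interval_tables[[cname]],
              put(file.path(outdir, paste0("overlap_", cname, ".csv"))),
              row.names = FALSE)
  }
  write.csv(result$thresholds, put(file.path(outdir, "cluster_thresholds.csv")),
            row.names = FALSE)
  # pattern summary in the style of the results headings
  con <- file(put(file.path(outdir, "pattern_summary.txt")), "w")
  for (fam in names(result$tables)) {
    tab <- result$tables[[fam]]
    writeLines(sprintf("== %s ==", fam), con)
    for (pat in c("reversible_expansion", "reversible_shrinkage",
                  "enduring_shrinkage", "enduring_expansion",
                  "enduring_fluid_expansion", "mixed")) {
      rois <- tab$roi[tab$pattern == pat]
      if (length(rois) > 0)
        writeLines(sprintf("%s: %s", pat, paste(rois, collapse = ", ")), con)
    }
    writeLines("", con)
  }
  close(con)
  write.csv(result$log, put(file.path(outdir, "run_log.csv")), row.names = FALSE)
  cfg_out <- config
  cfg_out$reg <- unclass(cfg_out$reg); cfg_out$strip_reg <- unclass(cfg_out$strip_reg)
  yaml::write_yaml(lapply(unclass(cfg_out), function(x) if (is.list(x)) x else unname(x)),
                   put(file.path(outdir, "effective_config.yaml")))
  if (keep_volumes && !is.null(result$templates)) {
    for (iv in seq_along(result$templates)) {
      write_volume(result$templates[[iv]],
                   put(file.path(outdir, sprintf("template_t%d.nii", iv))))
    }
  }
  sums <- data.frame(file = basename(unlist(paths)),
                     md5 = unname(tools::md5sum(unlist(paths))),
                     stringsAsFactors = FALSE)
  write.csv(sums, file.path(outdir, "output_manifest.csv"), row.names = FALSE)
  invisible(paths)
}
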