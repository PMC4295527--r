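#' Run configuration for the end-to-end pipeline
#'
#' Builds (and validates) the configuration driving [run_features()] and
#' [run_analysis()]: input paths or simulation settings, model
#' parameters, statistics parameters and the master seed. Accepts a YAML
#' or JSON file path, or a named list; unknown keys are rejected,
#' missing keys take the documented defaults.
#'
#' @param config file path or named list.
#' @param ... key overrides applied on top (flags beat config keys).
#' @return Object of class `run_config`.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    frames_dir = NULL,          # PNG directory; NULL = simulate frames
    volume_dirs = NULL,         # list of per-subject NIfTI dirs; NULL = simulate
    output_dir = "rsavp_output",
    n_frames = 40, frame_size = c(64, 64),
    n_subjects = 5, grid = c(16, 16, 16),
    w_a = 1, w_b = 0.5, noise_sd = 0.3,
    n_prototypes = 32, patch_sizes = c(4, 8),
    n_words = 64, sift_stride = 8, sift_patch = 16,
    n_levels = 10, gabor_size = 11,
    n_perm = 199, alpha = 0.05, min_cluster_size = 25,
    connectivity = 6, smooth_sd = 1,
    analyses = c("hmax", "bow", "vd", "low"),
    seed = 1)
  over <- list(...)
  unknown <- setdiff(c(names(config), names(over)), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(utils::modifyList(defaults, config,
                                             keep.null = TRUE),
                           over, keep.null = TRUE)
  stopifnot(cfg$n_prototypes > 0, cfg$n_words > 0, cfg$n_perm > 0)
  for (p in c(cfg$frames_dir, unlist(cfg$volume_dirs)))
    if (!is.null(p) && !dir.exists(p))
      stop("configured path does not exist: ", p)
  structure(cfg, class = "run_config")
}

#' Feature-extraction stage of the pipeline
#'
#' Ingests (or simulates) the stimulus frames and computes the four
#' per-stimulus feature matrices -- `f_gabor`, `f_vdhmax` (HMAX C1 / C2)
#' and `f_sift`, `f_vdbow` (dense SIFT / BoW histogram) -- persisting
#' them as CSV together with the dictionaries and a provenance manifest
#' (parameters, seed, content hashes).
#'
#' @param config a [run_config].
#' @return List with `frames`, the four [feature_matrix] objects,
#'   `dictionary`, `codebook` and `manifest` (invisible side effect:
#'   files under `config$output_dir/features`).
#' @export
run_features <- function(config) {
  cfg <- run_config(unclass(config))
  frames <- if (is.null(cfg$frames_dir))
    generate_frames(cfg$n_frames, cfg$frame_size, seed = cfg$seed)
  else read_frames(cfg$frames_dir)
  bank <- gabor_bank(size = cfg$gabor_size)
  dict <- sample_prototypes(frames, n_prototypes = cfg$n_prototypes,
                            patch_sizes = cfg$patch_sizes,
                            seed = derive_seed(cfg$seed, 1L), bank = bank,
                            n_levels = cfg$n_levels)
  hm <- hmax_features(frames, dict = dict, bank = bank,
                      n_levels = cfg$n_levels)
  dss <- lapply(frames$frames, dense_sift, stride = cfg$sift_stride,
                patch = cfg$sift_patch)
  cb <- learn_codebook(dss, n_words = cfg$n_words,
                       seed = derive_seed(cfg$seed, 2L))
  bw <- bow_features(frames, codebook = cb, stride = cfg$sift_stride,
                     patch = cfg$sift_patch)
  out_dir <- file.path(cfg$output_dir, "features")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- list(f_gabor = hm$f_gabor, f_vdhmax = hm$f_vdhmax,
                f_sift = bw$f_sift, f_vdbow = bw$f_vdbow)
  files <- character(0)
  for (nm in names(feats)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(unclass(feats[[nm]])), f,
                     row.names = FALSE)
    files[nm] <- f
  }
  saveRDS(dict, file.path(out_dir, "prototypes.rds"))
  utils::write.csv(as.data.frame(cb$centers),
                   file.path(out_dir, "codebook.csv"), row.names = FALSE)
  manifest <- list(
    seed = cfg$seed, n_frames = length(frames$frames),
    frame_size = frames$common_size,
    n_prototypes = cfg$n_prototypes, n_words = cfg$n_words,
    codebook_inertia = cb$inertia,
    content_hashes = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(frames = frames, f_gabor = hm$f_gabor,
                 f_vdhmax = hm$f_vdhmax, f_sift = bw$f_sift,
                 f_vdbow = bw$f_vdbow, dictionary = dict, codebook = cb,
                 manifest = manifest))
}

#' Analysis stage: RDMs, voxel-wise partitioning, group inference
#'
#' Builds the four model RDMs, then for each configured analysis --
#' `"hmax"` (Gabor vs HMAX dictionary), `"bow"` (SIFT vs BoW dictionary),
#' `"vd"` (the two dictionaries against each other) and `"low"` (Gabor vs
#' SIFT) -- runs voxel-wise variation partitioning with permutation
#' inference for every subject, cluster-extent correction of the
#' full-model p-map, the across-subject consistency map, and the ROI
#' summary table. Results are written under `config$output_dir` and a
#' manifest JSON records every seed and parameter.
#'
#' @param config a [run_config].
#' @param features optional [run_features()] result (recomputed
#'   otherwise).
#' @param cohort optional list of `synthetic_brain` subjects; otherwise
#'   read from `config$volume_dirs` or simulated.
#' @return List per analysis: `vp` (per-subject [voxelwise_partition]
#'   results), `reports`, `consistency`, `roi_table`; plus `manifest`.
#' @export
run_analysis <- function(config, features = NULL, cohort = NULL) {
  cfg <- run_config(unclass(config))
  if (is.null(features)) features <- run_features(cfg)
  rdms <- list(
    f_gabor = compute_rdm(features$f_gabor, source = "F_gabor"),
    f_vdhmax = compute_rdm(features$f_vdhmax, source = "F_vdhmax"),
    f_sift = compute_rdm(features$f_sift, source = "F_sift"),
    f_vdbow = compute_rdm(features$f_vdbow, source = "F_vdbow"))
  if (is.null(cohort)) {
    cohort <- if (!is.null(cfg$volume_dirs))
      lapply(cfg$volume_dirs, read_brain)
    else generate_cohort(cfg$n_subjects, features$frames,
                         features$f_vdhmax, features$f_vdbow,
                         w_a = cfg$w_a, w_b = cfg$w_b,
                         noise_sd = cfg$noise_sd, grid = cfg$grid,
                         seed = derive_seed(cfg$seed, 3L))
  }
  dm <- dim(cohort[[1]]$volumes)
  if (dm[4] != nrow(features$f_gabor))
    stop(sprintf("volume series length %d does not match %d stimuli",
                 dm[4], nrow(features$f_gabor)))
  pairs <- list(hmax = c("f_gabor", "f_vdhmax"),
                bow = c("f_sift", "f_vdbow"),
                vd = c("f_vdhmax", "f_vdbow"),
                low = c("f_gabor", "f_sift"))
  out <- list()
  for (an in intersect(cfg$analyses, names(pairs))) {
    pa <- pairs[[an]]
    vp <- lapply(seq_along(cohort), function(s)
      voxelwise_partition(cohort[[s]], rdms[[pa[1]]], rdms[[pa[2]]],
                          n_perm = cfg$n_perm,
                          seed = derive_seed(cfg$seed, 100L + s),
                          labels = pa))
    reports <- lapply(vp, function(v)
      cluster_threshold(v$maps$p_full, alpha = cfg$alpha,
                        min_size = cfg$min_cluster_size,
                        connectivity = cfg$connectivity))
    cons <- consistency_map(reports, smooth_sd = cfg$smooth_sd,
                            alpha = cfg$alpha,
                            seed = derive_seed(cfg$seed, 200L))
    roi <- roi_summary(lapply(vp, function(v) v$maps$r2_full), reports,
                       cohort[[1]]$roi_labels)
    an_dir <- file.path(cfg$output_dir, an)
    dir.create(an_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_along(vp))
      write_stat_volumes(vp[[s]]$maps, an_dir,
                         prefix = sprintf("sub%02d", s))
    utils::write.csv(roi, file.path(an_dir, "roi_table.csv"),
                     row.names = FALSE)
    out[[an]] <- list(vp = vp, reports = reports, consistency = cons,
                      roi_table = roi)
  }
  manifest <- list(seed = cfg$seed, n_perm = cfg$n_perm,
                   alpha = cfg$alpha,
                   min_cluster_size = cfg$min_cluster_size,
                   analyses = intersect(cfg$analyses, names(pairs)),
                   n_subjects = length(cohort),
                   grid = dm[1:3], n_stimuli = dm[4])
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "analysis_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  out
}
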