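#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end study (phantom generation ->
#' acquisition blur -> PVC -> SUVR quantification -> group networks ->
#' classification) into one structure that round-trips losslessly through
#' YAML. All randomness flows from `seed` via per-stage derived seeds.
#'
#' @param out_dir output directory for all stage products.
#' @param seed global integer seed.
#' @param shape,spacing phantom grid dimensions and voxel size (mm).
#' @param n_regions,groups,n_blocks,within_r,between_r,base_activity,uplift,
#'   amyloid_frac,activity_cv,noise_sd passed to [cohort_spec()].
#' @param fwhm_mm acquisition/correction PSF FWHM in mm.
#' @param je_weight,je_iters joint-entropy deconvolution weight and
#'   iteration cap.
#' @param vc_alpha,vc_tol,vc_iters Van Cittert step, termination threshold
#'   and iteration cap.
#' @param threshold_p proportional threshold for the group networks.
#' @param classifiers classifiers to run (subset of svm, lda, msd).
#' @param cv_folds,cv_repetitions cross-validation geometry.
#' @param contrast length-2 group names for the classification contrast
#'   (default the two most similar groups, the hardest contrast).
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(out_dir = "pvcnet_run",
                            seed = 1,
                            shape = c(48, 48, 48),
                            spacing = c(2, 2, 2),
                            n_regions = 90,
                            groups = c(NC = 20, EMCI = 20, LMCI = 20,
                                       AD = 20),
                            n_blocks = 6,
                            within_r = c(NC = 0.8, EMCI = 0.6, LMCI = 0.4,
                                         AD = 0.2),
                            between_r = 0,
                            base_activity = 6,
                            uplift = c(NC = 0, EMCI = 0.15, LMCI = 0.30,
                                       AD = 0.45),
                            amyloid_frac = 0.25,
                            activity_cv = 0.10,
                            noise_sd = 0.05 * base_activity,
                            fwhm_mm = 6,
                            je_weight = 3e3,
                            je_iters = 12,
                            vc_alpha = 1.5,
                            vc_tol = 0.01,
                            vc_iters = 100,
                            threshold_p = 0.1,
                            classifiers = c("svm", "lda", "msd"),
                            cv_folds = 10,
                            cv_repetitions = 20,
                            contrast = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              shape = as.integer(shape), spacing = as.numeric(spacing),
              n_regions = as.integer(n_regions),
              groups = as.list(groups), n_blocks = as.integer(n_blocks),
              within_r = as.list(within_r), between_r = between_r,
              base_activity = base_activity, uplift = as.list(uplift),
              amyloid_frac = amyloid_frac, activity_cv = activity_cv,
              noise_sd = noise_sd, fwhm_mm = fwhm_mm,
              je_weight = je_weight, je_iters = as.integer(je_iters),
              vc_alpha = vc_alpha, vc_tol = vc_tol,
              vc_iters = as.integer(vc_iters),
              threshold_p = threshold_p,
              classifiers = as.list(classifiers),
              cv_folds = as.integer(cv_folds),
              cv_repetitions = as.integer(cv_repetitions),
              contrast = if (is.null(contrast)) as.list(names(groups)[1:2])
                         else as.list(contrast))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return [pipeline_config()] (for `read_config`); `path` invisibly (for
#'   `write_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$shape <- as.integer(cfg$shape)
  cfg$seed <- as.integer(cfg$seed)
  # YAML collapses unnamed scalar sequences to vectors; restore list form
  for (fld in c("classifiers", "contrast", "groups", "within_r", "uplift"))
    cfg[[fld]] <- as.list(cfg[[fld]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# hash of the scientific configuration: the output location is excluded so
# equal configs written to different directories hash (and reproduce)
# identically
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

cohort_spec_from_config <- function(config) {
  cohort_spec(n_regions = config$n_regions,
              groups = unlist(config$groups),
              n_blocks = config$n_blocks,
              within_r = unlist(config$within_r),
              between_r = config$between_r,
              base_activity = config$base_activity,
              uplift = unlist(config$uplift),
              amyloid_frac = config$amyloid_frac,
              activity_cv = config$activity_cv,
              noise_sd = config$noise_sd,
              fwhm_mm = config$fwhm_mm,
              seed = derive_seed(config$seed, "phantom"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g",
                                                 digits = 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pvc_methods <- c("uncorrected", "JEPVC", "LSPVC", "GTM")

#' Run the end-to-end evaluation pipeline
#'
#' Executes the stages phantom -> pvc -> quantify -> network -> classify for
#' the conditions uncorrected / JEPVC (joint-entropy) / LSPVC (Van Cittert)
#' / GTM across all groups, writing TSV reports (regional SUVR statistics,
#' per-group network metric panels pre/post correction, betweenness
#' rankings, classification error tables) plus a run manifest. Each stage
#' rereads its inputs from `config$out_dir`, so stages can be rerun
#' independently; every stage is deterministic under `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("phantom", "pvc", "quantify", "network", "classify")`, in pipeline
#'   order.
#' @return The run manifest (named list), invisibly.
#' @export
run_pipeline <- function(config, stages = c("phantom", "pvc", "quantify",
                                            "network", "classify")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("pvcnet")),
                   seed = config$seed, stages = list(), outputs = character(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  for (st in stages) {
    t0 <- Sys.time()
    out <- tryCatch(
      switch(st,
             phantom = stage_phantom(config),
             pvc = stage_pvc(config),
             quantify = stage_quantify(config),
             network = stage_network(config),
             classify = stage_classify(config)),
      error = function(e) {
        manifest$failed_stage <- st
        yaml::write_yaml(manifest, file.path(config$out_dir,
                                             "manifest.yaml"))
        stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    manifest$stages[[st]] <- list(
      seed = derive_seed(config$seed, st),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2))
    manifest$outputs <- c(manifest$outputs, out)
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  write_config(config, file.path(config$out_dir, "config.yaml"))
  invisible(manifest)
}

subject_ids_of <- function(config) {
  lapply(names(config$groups), function(g)
    sprintf("%s_%02d", g, seq_len(config$groups[[g]])))
}

stage_phantom <- function(config) {
  dirp <- file.path(config$out_dir, "phantom")
  dir.create(dirp, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec_from_config(config)
  cohort <- generate_cohort(spec, shape = config$shape,
                            spacing = config$spacing)
  outs <- write_parcellation(cohort$parcellation,
                             file.path(dirp, "parcellation.nii.gz"),
                             file.path(dirp, "regions.tsv"))
  outs <- c(outs, write_volume(cohort$mr, file.path(dirp, "mr.nii.gz")))
  for (g in names(config$groups)) {
    f <- file.path(dirp, sprintf("activities_%s.tsv", g))
    write_intensity_tsv(cohort$activities[[g]], f)
    outs <- c(outs, f)
    for (j in seq_along(cohort$subjects[[g]])) {
      id <- sprintf("%s_%02d", g, j)
      f1 <- file.path(dirp, sprintf("true_%s.nii.gz", id))
      f2 <- file.path(dirp, sprintf("observed_%s.nii.gz", id))
      write_volume(cohort$subjects[[g]][[j]]$true_pet, f1)
      write_volume(cohort$subjects[[g]][[j]]$observed, f2)
      outs <- c(outs, f1, f2)
    }
  }
  outs
}

load_parcellation <- function(config) {
  dirp <- file.path(config$out_dir, "phantom")
  lab <- read_volume(file.path(dirp, "parcellation.nii.gz"))
  regions <- utils::read.table(file.path(dirp, "regions.tsv"), sep = "\t",
                               header = TRUE)
  structure(list(labels = array(as.integer(round(lab$values)),
                                dim(lab$values)),
                 tissue = NULL, regions = regions, spacing = lab$spacing),
            class = "parcellation")
}

stage_pvc <- function(config) {
  dirp <- file.path(config$out_dir, "phantom")
  dirc <- file.path(config$out_dir, "pvc")
  dir.create(dirc, showWarnings = FALSE, recursive = TRUE)
  parc <- load_parcellation(config)
  mr <- read_volume(file.path(dirp, "mr.nii.gz"))
  psf <- psf_model(config$fwhm_mm)
  gtm <- gtm_matrix(parc, psf)
  je_set <- deconv_settings(je_weight = config$je_weight,
                            max_iters = config$je_iters)
  vc_set <- deconv_settings(vc_alpha = config$vc_alpha,
                            vc_tol = config$vc_tol,
                            max_iters = config$vc_iters)
  outs <- character()
  for (g in names(config$groups)) {
    ids <- sprintf("%s_%02d", g, seq_len(config$groups[[g]]))
    obs <- lapply(ids, function(id)
      read_volume(file.path(dirp, sprintf("observed_%s.nii.gz", id))))
    # image-domain corrections
    traces <- list()
    for (i in seq_along(ids)) {
      je <- je_deconvolve(obs[[i]], mr, psf, je_set)
      traces[[ids[i]]] <- je$trace
      write_volume(je$corrected,
                   file.path(dirc, sprintf("je_%s.nii.gz", ids[i])))
      vc <- vc_deconvolve(obs[[i]], psf, vc_set)
      write_volume(vc, file.path(dirc, sprintf("vc_%s.nii.gz", ids[i])))
      outs <- c(outs, file.path(dirc, sprintf("je_%s.nii.gz", ids[i])),
                file.path(dirc, sprintf("vc_%s.nii.gz", ids[i])))
    }
    tr <- data.frame(subject = rep(names(traces),
                                   vapply(traces, length, 1L)),
                     iteration = unlist(lapply(traces, seq_along)) - 1L,
                     objective = unlist(traces), row.names = NULL)
    f <- file.path(dirc, sprintf("je_trace_%s.tsv", g))
    write_tsv(tr, f)
    # region-based correction (GTM): observed means -> true means
    im_obs <- region_mean_matrix(obs, parc, subject_ids = ids, group = g)
    corrected <- gtm_correct(im_obs$values, gtm)
    f2 <- file.path(dirc, sprintf("gtm_means_%s.tsv", g))
    write_intensity_tsv(intensity_matrix(corrected,
                                         region_labels = parc$regions$label,
                                         subject_ids = ids, group = g), f2)
    outs <- c(outs, f, f2)
  }
  outs
}

pipeline_volume_sets <- function(config, parc) {
  dirp <- file.path(config$out_dir, "phantom")
  dirc <- file.path(config$out_dir, "pvc")
  sets <- list()
  for (g in names(config$groups)) {
    ids <- sprintf("%s_%02d", g, seq_len(config$groups[[g]]))
    sets[[g]] <- list(
      ids = ids,
      uncorrected = lapply(ids, function(id)
        read_volume(file.path(dirp, sprintf("observed_%s.nii.gz", id)))),
      JEPVC = lapply(ids, function(id)
        read_volume(file.path(dirc, sprintf("je_%s.nii.gz", id)))),
      LSPVC = lapply(ids, function(id)
        read_volume(file.path(dirc, sprintf("vc_%s.nii.gz", id)))))
  }
  sets
}

stage_quantify <- function(config) {
  parc <- load_parcellation(config)
  ref <- reference_region(parc)
  dirq <- file.path(config$out_dir, "quantify")
  dir.create(dirq, showWarnings = FALSE, recursive = TRUE)
  sets <- pipeline_volume_sets(config, parc)
  stats <- list()
  outs <- character()
  for (g in names(config$groups)) {
    for (method in c("uncorrected", "JEPVC", "LSPVC")) {
      suvr <- lapply(sets[[g]][[method]], function(v)
        suvr_normalize(v, ref, parc))
      iqm <- region_iqm_matrix(suvr, parc, subject_ids = sets[[g]]$ids,
                               group = g)
      f <- file.path(dirq, sprintf("suvr_iqm_%s_%s.tsv", method, g))
      write_intensity_tsv(iqm, f)
      outs <- c(outs, f)
      stats[[paste(g, method)]] <- group_region_stats(iqm, method)
    }
    # GTM: corrected regional means, normalized by the reference region
    gm <- read_intensity_tsv(file.path(config$out_dir, "pvc",
                                       sprintf("gtm_means_%s.tsv", g)),
                             group = g)
    suvr_gtm <- sweep(gm$values, 2, gm$values[ref, ], "/")
    stats[[paste(g, "GTM")]] <-
      group_region_stats(intensity_matrix(suvr_gtm,
                                          region_labels = gm$region_labels,
                                          subject_ids = gm$subject_ids,
                                          group = g), "GTM")
  }
  f <- file.path(dirq, "suvr_stats.tsv")
  all_stats <- do.call(rbind, stats)
  all_stats$config_hash <- config_hash(config)
  write_tsv(all_stats, f)
  c(outs, f)
}

stage_network <- function(config) {
  parc <- load_parcellation(config)
  dirn <- file.path(config$out_dir, "network")
  dir.create(dirn, showWarnings = FALSE, recursive = TRUE)
  sets <- pipeline_volume_sets(config, parc)
  outs <- character()
  summaries <- list()
  rankings <- list()
  for (method in c("uncorrected", "JEPVC", "LSPVC", "GTM")) {
    nets <- list()
    for (g in names(config$groups)) {
      im <- if (method == "GTM")
        read_intensity_tsv(file.path(config$out_dir, "pvc",
                                     sprintf("gtm_means_%s.tsv", g)),
                           group = g)
      else region_mean_matrix(sets[[g]][[method]], parc,
                              subject_ids = sets[[g]]$ids, group = g)
      nets[[g]] <- standardize_columns(correlation_network(im))
    }
    # shared global max per condition (inter-group comparability), then the
    # per-network proportional threshold
    gm <- max(vapply(nets, function(w) max(w$weights), numeric(1)))
    for (g in names(config$groups)) {
      thr <- normalize_and_threshold(nets[[g]], p = config$threshold_p,
                                     global_max = gm)
      f <- file.path(dirn, sprintf("network_%s_%s.tsv", method, g))
      wdf <- as.data.frame(thr$weights)
      colnames(wdf) <- thr$node_labels
      write_tsv(wdf, f)
      outs <- c(outs, f)
      condition <- if (method == "uncorrected") "pre" else "post"
      nm <- network_metrics(thr, seed = derive_seed(config$seed, "network"),
                            group = g, condition = condition)
      nm$summary$method <- method
      summaries[[paste(method, g)]] <- nm$summary
      rk <- rank_betweenness(thr)
      rk$group <- g
      rk$method <- method
      rankings[[paste(method, g)]] <- rk
    }
  }
  sm <- do.call(rbind, summaries)
  sm$config_hash <- config_hash(config)
  f1 <- file.path(dirn, "metrics.tsv")
  write_tsv(sm, f1)
  rk <- do.call(rbind, rankings)
  f2 <- file.path(dirn, "betweenness.tsv")
  write_tsv(rk, f2)
  c(outs, f1, f2)
}

stage_classify <- function(config) {
  parc <- load_parcellation(config)
  dircl <- file.path(config$out_dir, "classify")
  dir.create(dircl, showWarnings = FALSE, recursive = TRUE)
  sets <- pipeline_volume_sets(config, parc)
  ga <- config$contrast[[1]]
  gb <- config$contrast[[2]]
  labels <- factor(rep(c(ga, gb), c(length(sets[[ga]]$ids),
                                    length(sets[[gb]]$ids))),
                   levels = c(ga, gb))
  vols <- function(method) c(sets[[ga]][[method]], sets[[gb]][[method]])
  region_feats <- function(method) {
    if (method == "GTM") {
      ms <- lapply(c(ga, gb), function(g)
        read_intensity_tsv(file.path(config$out_dir, "pvc",
                                     sprintf("gtm_means_%s.tsv", g)), g))
      t(cbind(ms[[1]]$values, ms[[2]]$values))
    } else {
      t(region_mean_matrix(vols(method), parc)$values)
    }
  }
  hog_feats <- function(method)
    do.call(rbind, lapply(vols(method), hog_features))
  outs <- character()
  rows <- list()
  for (clf in unlist(config$classifiers)) {
    # the corrected arm is the joint-entropy method's output throughout:
    # image classifiers read it through HOG, the graph-signal classifier
    # through regional means
    post_method <- "JEPVC"
    if (clf %in% c("svm", "lda")) {
      pre <- feature_set(hog_feats("uncorrected"), labels, "uncorrected",
                         "hog")
      post <- feature_set(hog_feats(post_method), labels, "corrected",
                          "hog")
    } else {
      pre <- feature_set(region_feats("uncorrected"), labels,
                         "uncorrected", "region_means")
      post <- feature_set(region_feats(post_method), labels, "corrected",
                          "region_means")
    }
    rep <- repeated_kfold(pre, post, clf, folds = config$cv_folds,
                          repetitions = config$cv_repetitions,
                          seed = derive_seed(config$seed,
                                             paste0("classify.", clf)))
    err <- rep$errors
    err$classifier <- clf
    err$post_method <- post_method
    rows[[clf]] <- err
    for (arm in c("pre", "post")) {
      ro <- rep[[paste0("roc_", arm)]]
      f <- file.path(dircl, sprintf("roc_%s_%s.tsv", clf, arm))
      write_tsv(ro$points, f)
      outs <- c(outs, f)
    }
  }
  err <- do.call(rbind, rows)
  err$config_hash <- config_hash(config)
  f <- file.path(dircl, "error_rates.tsv")
  write_tsv(err, f)
  c(outs, f)
}
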