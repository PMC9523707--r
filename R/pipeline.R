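#' Pipeline configuration
#'
#' Collects seeds, the study design, detection and matching thresholds and
#' rendering parameters, with validation. Configurations round-trip through
#' structured text (YAML-free name=value pairs are avoided; plain
#' `dput`-style R text via [write_run_config()]).
#'
#' @param design A `study_design`.
#' @param snr_min Peak-detection S/N threshold.
#' @param template_window Search window c(minutes, seconds).
#' @param template_dmf,template_rmf Spectral gates for template matching.
#' @param id_dmf,id_rmf,it_tol Identification gates.
#' @param sieve_threshold Fisher-ratio sieve threshold.
#' @param fuzzy_epsilon_k Fuzzy-ratio epsilon as a multiple of the composite
#'   noise SD.
#' @return Object of class `run_config`.
#' @export
run_config <- function(design = study_design(),
                       snr_min = 100,
                       template_window = c(0.30, 0.20),
                       template_dmf = 750, template_rmf = 750,
                       id_dmf = 900, id_rmf = 950, it_tol = 10,
                       sieve_threshold = 3.84,
                       fuzzy_epsilon_k = 3) {
  stopifnot(inherits(design, "study_design"),
            snr_min > 0, length(template_window) == 2,
            all(template_window > 0),
            template_dmf >= 0, template_dmf <= 999,
            template_rmf >= 0, template_rmf <= 999,
            id_dmf >= 0, id_dmf <= 999, id_rmf >= 0, id_rmf <= 999,
            it_tol > 0, sieve_threshold >= 0, fuzzy_epsilon_k > 0)
  structure(list(design = design, snr_min = snr_min,
                 template_window = template_window,
                 template_dmf = template_dmf, template_rmf = template_rmf,
                 id_dmf = id_dmf, id_rmf = id_rmf, it_tol = it_tol,
                 sieve_threshold = sieve_threshold,
                 fuzzy_epsilon_k = fuzzy_epsilon_k),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path Text file path.
#' @export
write_run_config <- function(config, path) {
  writeLines(deparse(unclass(config)), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- eval(parse(text = readLines(path)))
  class(obj$design) <- "study_design"
  do.call(run_config, obj)
}

pipeline_stages <- c("simulate", "detect", "align", "fingerprint", "sieve",
                     "compare", "stats")

#' Run the fingerprinting pipeline
#'
#' Executes the requested stages in canonical order
#' (simulate, detect, align, fingerprint, sieve, compare, stats), reading
#' and writing artifacts under `outdir` so partial re-runs work from disk
#' with no hidden state. Every artifact is recorded in `manifest.csv`
#' (stage, file, seed, md5 checksum); identical config and seed give
#' identical manifests.
#'
#' Stages: *simulate* writes the study's run containers and the alkane
#' calibration run; *detect* writes per-run peak tables; *align* builds the
#' reliable-peak template; *fingerprint* builds the composite, delineates
#' peak regions, assembles the feature table and assigns identities;
#' *sieve* writes the Fisher-sieved feature subset; *compare* writes
#' composite class images and pairwise fuzzy-ratio difference images;
#' *stats* writes PCA, correlation and response-ratio reports.
#'
#' @param config A `run_config`.
#' @param outdir Artifact directory.
#' @param stages Subset of the stage names (default: all).
#' @return Invisibly, the manifest data frame.
#' @export
run_pipeline <- function(config, outdir,
                         stages = pipeline_stages) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  manifest <- list()
  log_msg <- function(...) message("[gcxgcfp] ", ...)
  record <- function(stage, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path), seed = design$seed,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("missing prerequisite artifact '", basename(path),
           "': run stage '", stage, "' first")
    path
  }
  runs_dir <- file.path(outdir, "runs")
  meta_path <- file.path(outdir, "run_meta.csv")
  alkane_path <- file.path(runs_dir, "alkane_calibration.rds")
  peaks_path <- file.path(outdir, "peaks.rds")
  template_path <- file.path(outdir, "template.rds")
  finger_path <- file.path(outdir, "feature_table.rds")

  if ("simulate" %in% stages) {
    log_msg("simulate: ", sum(design$classes) + length(design$extra_analytical),
            " runs")
    st <- simulate_study(design, outdir = runs_dir)
    # store paths relative to outdir so artifacts are location-independent
    st$meta$path <- file.path("runs", basename(st$meta$path))
    write.csv(st$meta, meta_path, row.names = FALSE)
    ladder <- derive_alkane_ladder(load_target_library(
      gcxgcfp_example("target_library.csv")))
    alk <- simulate_alkane_run(setNames(ladder$rt1_min, ladder$carbons),
                               design = design)
    write_run(alk, alkane_path)
    record("simulate", meta_path)
    for (p in st$meta$path) record("simulate", file.path(outdir, p))
    record("simulate", alkane_path)
  }

  if ("detect" %in% stages) {
    meta <- read.csv(need(meta_path, "simulate"))
    log_msg("detect: S/N >= ", config$snr_min)
    peak_sets <- list(); rasters <- list()
    for (r in seq_len(nrow(meta))) {
      ch <- read_run(need(file.path(outdir, meta$path[r]), "simulate"))
      pk <- detect_peaks(ch, snr_min = config$snr_min)
      peak_sets[[r]] <- pk
      rasters[[r]] <- tic_raster(ch)
      tab_path <- file.path(outdir, paste0("peaks_", meta$sample_id[r],
                                           ".csv"))
      export_peak_table(pk, tab_path)
      record("detect", tab_path)
    }
    alk <- read_run(need(alkane_path, "simulate"))
    cal <- calibrate_from_run(alk, snr_min = config$snr_min)
    saveRDS(list(peak_sets = peak_sets, rasters = rasters, cal = cal,
                 meta = meta), peaks_path)
    record("detect", peaks_path)
    log_msg("detect: ", sum(vapply(peak_sets, nrow, integer(1))),
            " peaks across runs")
  }

  if ("align" %in% stages) {
    pk <- readRDS(need(peaks_path, "detect"))
    log_msg("align: building reliable-peak template")
    template <- build_template(pk$peak_sets,
                               window = config$template_window,
                               dmf_min = config$template_dmf,
                               rmf_min = config$template_rmf)
    saveRDS(template, template_path)
    record("align", template_path)
    log_msg("align: ", nrow(template$entries), " reliable peaks")
  }

  if ("fingerprint" %in% stages) {
    pk <- readRDS(need(peaks_path, "detect"))
    template <- readRDS(need(template_path, "align"))
    geometry <- attr(pk$peak_sets[[1]], "geometry")
    composite <- build_composite(pk$rasters, attr(template, "transforms"),
                                 geometry)
    regions <- delineate_regions(composite, template, geometry,
                                 snr_min = config$snr_min)
    lib <- load_target_library(gcxgcfp_example("target_library.csv"))
    ids <- assign_template_identities(template, lib, pk$cal,
                                      dmf_min = config$id_dmf,
                                      rmf_min = config$id_rmf,
                                      it_tol = config$it_tol)
    ft <- assemble_feature_table(template, regions, pk$peak_sets,
                                 pk$rasters, pk$meta,
                                 is_coords = design$internal_standards,
                                 identities = ids)
    saveRDS(list(ft = ft, composite = composite, regions = regions),
            finger_path)
    ft_csv <- file.path(outdir, "feature_table.csv")
    export_feature_table(ft, ft_csv)
    record("fingerprint", finger_path)
    record("fingerprint", ft_csv)
    log_msg("fingerprint: ", nrow(ft$features), " UT features (",
            sum(ft$features$kind == "targeted"), " targeted)")
  }

  if ("sieve" %in% stages) {
    fp <- readRDS(need(finger_path, "fingerprint"))
    sieved <- sieve(fp$ft, threshold = config$sieve_threshold)
    sieve_csv <- file.path(outdir, "feature_table_sieved.csv")
    export_feature_table(sieved, sieve_csv)
    record("sieve", sieve_csv)
    log_msg("sieve: ", nrow(sieved$features), " features with F > ",
            config$sieve_threshold)
  }

  if ("compare" %in% stages) {
    pk <- readRDS(need(peaks_path, "detect"))
    template <- readRDS(need(template_path, "align"))
    geometry <- attr(pk$peak_sets[[1]], "geometry")
    tr <- attr(template, "transforms")
    aligned <- lapply(seq_along(pk$rasters), function(j)
      warp_raster(pk$rasters[[j]], tr[[j]], geometry))
    cls <- split(seq_along(aligned), pk$meta$class_label)
    images <- lapply(cls, function(i) composite_class_image(aligned[i]))
    for (nm in names(images)) {
      p <- file.path(outdir, paste0("composite_", nm, ".png"))
      write_image_png(images[[nm]], p)
      record("compare", p)
    }
    ref <- intersect(c("herbage_low", "con"), names(images))[1]
    if (!is.na(ref)) {
      eps <- config$fuzzy_epsilon_k *
        max(suppressWarnings(estimate_noise(images[[ref]])), 1e-9)
      for (nm in setdiff(names(images), ref)) {
        di <- fuzzy_ratio_image(images[[nm]], images[[ref]], epsilon = eps)
        p <- file.path(outdir, paste0("fuzzy_", nm, "_vs_", ref, ".png"))
        write_image_png(di, p)
        record("compare", p)
      }
    }
    log_msg("compare: ", length(images), " composite class images")
  }

  if ("stats" %in% stages) {
    fp <- readRDS(need(finger_path, "fingerprint"))
    ft <- fp$ft
    classes <- ft$meta$class_label
    f <- fisher_ratios(ft$responses[, classes != "qc", drop = FALSE],
                       classes[classes != "qc"])
    pc <- pca_features(ft)
    co <- correlation_clustered_heatmap(ft$responses)
    rr <- tryCatch(response_ratio(ft, "lpar", "herbage_low"),
                   error = function(e) NULL)
    stats_csv <- file.path(outdir, "feature_stats.csv")
    write.csv(data.frame(ft$features,
                         f_calc = f,
                         ratio_lpar_herbage = if (is.null(rr)) NA else rr),
              stats_csv, row.names = FALSE)
    pca_csv <- file.path(outdir, "pca_scores.csv")
    write.csv(data.frame(sample = rownames(pc$scores),
                         class = classes,
                         pc$scores[, 1:min(5, ncol(pc$scores))],
                         check.names = FALSE),
              pca_csv, row.names = FALSE)
    flg_csv <- file.path(outdir, "correlated_pairs.csv")
    write.csv(co$flagged, flg_csv, row.names = FALSE)
    record("stats", stats_csv); record("stats", pca_csv)
    record("stats", flg_csv)
    log_msg("stats: PC1 ", round(100 * pc$explained[1], 2),
            "% / PC2 ", round(100 * pc$explained[2], 2), "% variance")
  }

  man <- do.call(rbind, manifest)
  man_path <- file.path(outdir, "manifest.csv")
  if (file.exists(man_path)) {
    old <- read.csv(man_path, colClasses = "character")
    old <- old[!(old$file %in% man$file), , drop = FALSE]
    if (nrow(old))
      man <- rbind(old[, names(man)], man)
  }
  write.csv(man, man_path, row.names = FALSE)
  invisible(man)
}

#' Closed-loop fingerprinting of a simulated study
#'
#' Convenience driver: simulates every run of a design (one at a time, so
#' cubes never accumulate in memory), detects peaks, builds the template,
#' composite, peak regions and feature table, and assigns identities from
#' the target library. This is the in-memory equivalent of the disk-based
#' [run_pipeline()] stages.
#'
#' @param design A `study_design`.
#' @param config A `run_config` (its design is ignored in favour of
#'   `design`).
#' @param lib Target library for identification.
#' @param progress Emit per-stage messages.
#' @return List with `meta`, `peak_sets`, `rasters`, `template`, `cal`,
#'   `composite`, `regions`, `identities`, `feature_table`.
#' @export
fingerprint_study <- function(design = study_design(),
                              config = run_config(design = design),
                              lib = load_target_library(
                                gcxgcfp_example("target_library.csv")),
                              progress = FALSE) {
  meta <- study_run_table(design)
  peak_sets <- vector("list", nrow(meta))
  rasters <- vector("list", nrow(meta))
  for (r in seq_len(nrow(meta))) {
    ch <- simulate_run(design, meta$class_label[r], meta$replicate_id[r],
                       meta$analytical_replicate[r], acq_order = r)
    peak_sets[[r]] <- detect_peaks(ch, snr_min = config$snr_min)
    rasters[[r]] <- tic_raster(ch)
    if (progress) message("run ", r, "/", nrow(meta), ": ",
                          nrow(peak_sets[[r]]), " peaks")
    rm(ch)
  }
  template <- build_template(peak_sets, window = config$template_window,
                             dmf_min = config$template_dmf,
                             rmf_min = config$template_rmf)
  geometry <- attr(peak_sets[[1]], "geometry")
  composite <- build_composite(rasters, attr(template, "transforms"),
                               geometry)
  regions <- delineate_regions(composite, template, geometry,
                               snr_min = config$snr_min)
  ladder <- derive_alkane_ladder(lib)
  identities <- assign_template_identities(template, lib, ladder,
                                           dmf_min = config$id_dmf,
                                           rmf_min = config$id_rmf,
                                           it_tol = config$it_tol)
  ft <- assemble_feature_table(template, regions, peak_sets, rasters, meta,
                               is_coords = design$internal_standards,
                               identities = identities)
  list(meta = meta, peak_sets = peak_sets, rasters = rasters,
       template = template, cal = ladder, composite = composite,
       regions = regions, identities = identities, feature_table = ft)
}
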