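# Full-analysis orchestration: maps -> classification -> overlap ->
# network tables -> reliability -> similarity, with provenance logging.

#' Assemble a pipeline run configuration
#'
#' @param mode `"synthetic"` (generate data from `dataset_spec`) or
#'   `"files"` (read NIfTI scans from disk).
#' @param dataset_spec A [dataset_spec()] (synthetic mode).
#' @param scans Tibble with `subject`, `session`, `path` (file mode).
#' @param mask_path,atlas_path NIfTI paths (file mode).
#' @param band Band-pass edges in Hz; applied to file-mode scans (synthetic
#'   scans are generated already band-limited).
#' @param apply_bandpass Filter the input series before analysis; defaults
#'   to `TRUE` in file mode, `FALSE` in synthetic mode.
#' @param hht An [hht_params()] list.
#' @param dvv A [dvv_params()] list.
#' @param strong_quantile Upper quantile defining the strong level
#'   (default 0.75, the third quartile).
#' @param overlap_denominator `"union"` or `"mask"`, see [strong_overlap()].
#' @param sessions_for_icc Session subset for reliability (default: all).
#' @param out_dir Output directory for maps, tables and the run log.
#' @param seed Global seed; every stochastic stage derives substreams from
#'   it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), dataset_spec = NULL,
                       scans = NULL, mask_path = NULL, atlas_path = NULL,
                       band = c(0.009, 0.08), apply_bandpass = NULL,
                       hht = hht_params(), dvv = dvv_params(),
                       strong_quantile = 0.75,
                       overlap_denominator = c("union", "mask"),
                       sessions_for_icc = NULL, out_dir = tempfile("dsdn_run_"),
                       seed = 1L) {
  mode <- match.arg(mode)
  overlap_denominator <- match.arg(overlap_denominator)
  if (mode == "synthetic") {
    if (is.null(dataset_spec)) abort("synthetic mode requires `dataset_spec`")
  } else {
    if (is.null(scans) || is.null(mask_path) || is.null(atlas_path)) {
      abort("file mode requires `scans`, `mask_path`, `atlas_path`")
    }
    missing <- c(scans$path, mask_path, atlas_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing)) {
      abort(sprintf("input files not found: %s", paste(missing, collapse = ", ")))
    }
  }
  check_scalar_number(strong_quantile, "strong_quantile", 0.5, 0.999)
  structure(list(mode = mode, dataset_spec = dataset_spec, scans = scans,
                 mask_path = mask_path, atlas_path = atlas_path, band = band,
                 apply_bandpass = apply_bandpass %||% (mode == "files"),
                 hht = hht, dvv = dvv, strong_quantile = strong_quantile,
                 overlap_denominator = overlap_denominator,
                 sessions_for_icc = sessions_for_icc, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full DS/DN profiling pipeline
#'
#' Stages: load or simulate scans; (optionally) band-pass; per-scan DS and
#' DN maps; group-average maps; quartile-fence classification on the group
#' maps; DS-by-DN overlap map and percentages; per-network strong
#' percentages, mean/variance tables and pairwise Welch tests; kernel
#' density summaries; voxel-wise ICC maps for DS and DN with their
#' correlation; between-network similarity matrices; slice-wise DS-DN
#' similarity. All maps (NIfTI), tables (TSV) and a machine-readable run
#' log (YAML) are written under `out_dir/{maps,tables,logs}`. Given the
#' same configuration and seed the TSV outputs are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, an object of class `dsdn_bundle` holding every stage
#'   result.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  out_dir <- config$out_dir
  for (d in file.path(out_dir, c("maps", "tables", "logs"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }

  loaded <- stage("load", {
    if (config$mode == "synthetic") {
      ds <- generate_dataset(config$dataset_spec)
      list(scans = ds$scans, geometry = ds$geometry,
           networks = atlas_networks(ds$atlas, ds$geometry), dataset = ds)
    } else {
      series <- purrr::map(config$scans$path, read_volume_series,
                           mask_path = config$mask_path)
      geom <- series[[1]]$geometry
      atlas <- load_network_atlas(config$atlas_path)
      sc <- dplyr::mutate(config$scans, series = series)
      list(scans = sc, geometry = geom,
           networks = atlas_networks(atlas, geom), dataset = NULL)
    }
  })
  geom <- loaded$geometry
  networks <- loaded$networks
  scans <- loaded$scans

  if (config$apply_bandpass) {
    scans$series <- stage("bandpass", purrr::map(
      scans$series, bandpass_filter,
      f_lo = config$band[1], f_hi = config$band[2]))
  }

  scan_maps <- stage("compute_maps", {
    purrr::pmap_dfr(scans[, c("subject", "session", "series")],
                    function(subject, session, series) {
      dsm <- ds_map(series, config$hht)
      scan_seed <- derive_seed(config$seed, subject * 1000 + session)
      dnm <- dn_map(series, config$dvv, seed = scan_seed)
      dplyr::left_join(dsm, dnm[, c("voxel", "dn", "n_valid_spans", "p_surrogate")],
                       by = "voxel") |>
        dplyr::mutate(subject = subject, session = session, .before = 1)
    })
  })

  group_maps <- stage("group_average", {
    scan_maps |>
      dplyr::group_by(.data$voxel, .data$i, .data$j, .data$k) |>
      dplyr::summarise(ds = mean(.data$ds), dn = mean(.data$dn),
                       .groups = "drop") |>
      dplyr::arrange(.data$voxel)
  })

  classification <- stage("classify", {
    probs <- c(1 - config$strong_quantile, config$strong_quantile)
    f_ds <- quartile_fences(group_maps$ds[is.finite(group_maps$ds)], probs)
    f_dn <- quartile_fences(group_maps$dn[is.finite(group_maps$dn)], probs)
    list(ds = suppressWarnings(classify_levels(group_maps, value = "ds", fences = f_ds)),
         dn = suppressWarnings(classify_levels(group_maps, value = "dn", fences = f_dn)))
  })

  overlap <- stage("overlap", strong_overlap(classification$ds, classification$dn,
                                             denominator = config$overlap_denominator))

  network_tables <- stage("network_tables", {
    strong_pct <- list(
      ds = network_strong_percentages(classification$ds, networks),
      dn = network_strong_percentages(classification$dn, networks),
      both = network_strong_percentages(overlap, networks))
    scan_net <- scan_maps |>
      dplyr::left_join(networks, by = "voxel") |>
      dplyr::filter(.data$network != "none") |>
      dplyr::group_by(.data$subject, .data$session, .data$network) |>
      dplyr::summarise(ds = mean(.data$ds, na.rm = TRUE),
                       dn = mean(.data$dn, na.rm = TRUE), .groups = "drop")
    summary_tbl <- scan_net |>
      tidyr::pivot_longer(c("ds", "dn"), names_to = "measure") |>
      dplyr::group_by(.data$measure, .data$network) |>
      dplyr::summarise(mean = mean(.data$value), variance = var(.data$value),
                       .groups = "drop")
    pairs <- utils::combn(network_names(), 2, simplify = FALSE)
    welch_tbl <- purrr::map_dfr(c("ds", "dn"), function(ms) {
      purrr::map_dfr(pairs, function(pr) {
        a <- scan_net[[ms]][scan_net$network == pr[1]]
        b <- scan_net[[ms]][scan_net$network == pr[2]]
        dplyr::mutate(welch_t(a, b), measure = ms,
                      network_a = pr[1], network_b = pr[2], .before = 1)
      })
    })
    list(strong_pct = strong_pct, scan_net = scan_net,
         summary = summary_tbl, welch = welch_tbl)
  })

  kde <- stage("density", {
    list(ds = density_estimate(group_maps$ds),
         dn = density_estimate(group_maps$dn))
  })

  reliability <- stage("reliability", {
    sess <- config$sessions_for_icc %||% sort(unique(scan_maps$session))
    panel <- scan_maps |> dplyr::filter(.data$session %in% sess)
    icc_ds <- icc_map(panel[, c("subject", "session", "voxel", "ds")] |>
                        dplyr::rename(value = "ds"))
    icc_dn <- icc_map(panel[, c("subject", "session", "voxel", "dn")] |>
                        dplyr::rename(value = "dn"))
    ok <- is.finite(icc_ds$icc) & is.finite(icc_dn$icc)
    icc_cor <- pearson_r(icc_ds$icc[ok], icc_dn$icc[ok])
    list(icc_ds = icc_ds, icc_dn = icc_dn, icc_cor = icc_cor, sessions = sess)
  })

  similarity <- stage("similarity", {
    net_long <- network_tables$scan_net
    sim_ds <- network_similarity_matrix(
      net_long[, c("subject", "session", "network", "ds")] |>
        dplyr::rename(value = "ds"))
    sim_dn <- network_similarity_matrix(
      net_long[, c("subject", "session", "network", "dn")] |>
        dplyr::rename(value = "dn"))
    slices <- slice_similarity(dplyr::rename(group_maps, ds = "ds"),
                               dplyr::rename(group_maps, dn = "dn"), geom)
    list(networks_ds = sim_ds, networks_dn = sim_dn, slices = slices)
  })

  stage("write_outputs", {
    mp <- function(f) file.path(out_dir, "maps", f)
    tb <- function(f) file.path(out_dir, "tables", f)
    safe_vals <- function(x) ifelse(is.finite(x), x, 0)
    suppressMessages({
      write_voxel_map(safe_vals(group_maps$ds), geom, mp("group_ds.nii.gz"))
      write_voxel_map(safe_vals(group_maps$dn), geom, mp("group_dn.nii.gz"))
      write_voxel_map(as.integer(classification$ds$level), geom, mp("level_ds.nii.gz"))
      write_voxel_map(as.integer(classification$dn$level), geom, mp("level_dn.nii.gz"))
      write_voxel_map(as.integer(overlap$category) - 1L, geom, mp("overlap.nii.gz"))
      write_voxel_map(safe_vals(reliability$icc_ds$icc), geom, mp("icc_ds.nii.gz"))
      write_voxel_map(safe_vals(reliability$icc_dn$icc), geom, mp("icc_dn.nii.gz"))
    })
    write_tsv_plain(scan_maps, tb("scan_maps.tsv"))
    write_tsv_plain(group_maps, tb("group_maps.tsv"))
    write_tsv_plain(dplyr::mutate(as_tibble(overlap),
                                  category = as.character(.data$category)),
                    tb("overlap_map.tsv"))
    write_tsv_plain(attr(overlap, "percentages"), tb("overlap_percentages.tsv"))
    for (nm in names(network_tables$strong_pct)) {
      write_tsv_plain(network_tables$strong_pct[[nm]],
                      tb(sprintf("strong_pct_%s.tsv", nm)))
    }
    write_tsv_plain(network_tables$summary, tb("network_summary.tsv"))
    write_tsv_plain(network_tables$welch, tb("network_welch_tests.tsv"))
    write_tsv_plain(kde$ds, tb("kde_ds.tsv"))
    write_tsv_plain(kde$dn, tb("kde_dn.tsv"))
    write_tsv_plain(reliability$icc_ds, tb("icc_ds.tsv"))
    write_tsv_plain(reliability$icc_dn, tb("icc_dn.tsv"))
    write_tsv_plain(reliability$icc_cor, tb("icc_ds_dn_correlation.tsv"))
    write_tsv_plain(tidy(similarity$networks_ds), tb("network_similarity_ds.tsv"))
    write_tsv_plain(tidy(similarity$networks_dn), tb("network_similarity_dn.tsv"))
    write_tsv_plain(similarity$slices, tb("slice_similarity.tsv"))
    log <- list(
      package = "dsdn",
      version = as.character(utils::packageVersion("dsdn")),
      seed = config$seed, mode = config$mode, band = config$band,
      apply_bandpass = config$apply_bandpass,
      hht = config$hht, dvv = config$dvv,
      strong_quantile = config$strong_quantile,
      overlap_denominator = config$overlap_denominator,
      sessions_for_icc = reliability$sessions,
      n_scans = nrow(scans), n_voxels = nrow(group_maps),
      n_time = ncol(scans$series[[1]]$values),
      dataset_spec = if (config$mode == "synthetic") {
        sp <- config$dataset_spec
        list(grid_dims = sp$grid_dims, n_subjects = sp$n_subjects,
             k_sessions = sp$k_sessions, n_time = sp$n_time, tr = sp$tr,
             sigma_b2 = sp$sigma_b2, sigma_w2 = sp$sigma_w2, snr = sp$snr,
             band = sp$band, seed = sp$seed,
             network_layout = as.data.frame(sp$network_layout))
      } else NULL)
    yaml::write_yaml(log, file.path(out_dir, "logs", "run_log.yaml"))
  })

  invisible(structure(
    list(config = config, geometry = geom, networks = networks,
         scan_maps = scan_maps, group_maps = group_maps,
         classification = classification, overlap = overlap,
         network_tables = network_tables, kde = kde,
         reliability = reliability, similarity = similarity,
         out_dir = out_dir),
    class = "dsdn_bundle"))
}

#' @export
print.dsdn_bundle <- function(x, ...) {
  cat(sprintf("<dsdn_bundle> %d scans, %d voxels; outputs in %s\n",
              length(unique(paste(x$scan_maps$subject, x$scan_maps$session))),
              nrow(x$group_maps), x$out_dir))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()] fields; synthetic mode nests a
#' `dataset_spec` block whose `network_layout` (optional) is a table of
#' block rows.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ds <- NULL
  if (!is.null(y$dataset_spec)) {
    a <- y$dataset_spec
    lay <- if (!is.null(a$network_layout)) {
      dplyr::bind_rows(lapply(a$network_layout, as_tibble))
    } else {
      default_network_layout(unlist(a$grid_dims %||% c(8, 8, 4)))
    }
    ds <- dataset_spec(
      grid_dims = unlist(a$grid_dims %||% c(8, 8, 4)),
      n_subjects = a$n_subjects %||% 5L, k_sessions = a$k_sessions %||% 3L,
      n_time = a$n_time %||% 256L, tr = a$tr %||% 2,
      sigma_b2 = a$sigma_b2 %||% 0.6, sigma_w2 = a$sigma_w2 %||% 0.4,
      snr = a$snr %||% 2, band = unlist(a$band %||% c(0.009, 0.08)),
      network_layout = lay, seed = a$seed %||% (y$seed %||% 1L))
  }
  scans <- if (!is.null(y$scans)) dplyr::bind_rows(lapply(y$scans, as_tibble))
  run_config(
    mode = y$mode %||% "synthetic", dataset_spec = ds, scans = scans,
    mask_path = y$mask_path, atlas_path = y$atlas_path,
    band = unlist(y$band %||% c(0.009, 0.08)),
    apply_bandpass = y$apply_bandpass,
    hht = do.call(hht_params, y$hht %||% list()),
    dvv = do.call(dvv_params, y$dvv %||% list()),
    strong_quantile = y$strong_quantile %||% 0.75,
    overlap_denominator = y$overlap_denominator %||% "union",
    sessions_for_icc = y$sessions_for_icc,
    out_dir = y$out_dir %||% tempfile("dsdn_run_"), seed = y$seed %||% 1L)
}
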