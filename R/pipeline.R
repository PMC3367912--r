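# Orchestration: simulate -> invert -> spectral -> cluster, with planted-
# effect recovery scoring against simulation ground truth. A master seed fans
# out deterministically to every stage and subject.

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list (YAML
#' round-trippable). Defaults: 9 subjects, 64 vertices per hemisphere
#' (128-vertex mesh), 32 sensors, a 360 s session of two
#' (Phoneme 60 s, Passive 30 s, Location 60 s, Passive 30 s) block cycles,
#' alpha power ratio 2 planted in pericalcarine and lingual ROIs, snr 3 /
#' depth 0.8 / loose 0.6 inverse, 1,500 randomizations.
#'
#' @param n_subjects number of synthetic subjects.
#' @return nested configuration list.
#' @export
default_config <- function(n_subjects = 9L) {
  list(
    n_subjects = as.integer(n_subjects),
    sampling_rate = 300,
    mesh = list(n_vertices_per_hemisphere = 64L),
    gain = list(n_sensors = 32L, smoothness = 10, falloff = 2,
                subject_gain_sd = 0.05),
    paradigm = default_paradigm(2L),
    truth = list(planted_rois = c("pericalcarine", "lingual"),
                 power_ratio = 2, effect_band = c(7, 13),
                 evoked_amplitude = 2, alpha_snr = 4,
                 artifact_frac = 0.08, subject_effect_sd = 0.1),
    noise = list(sigma = 1, rho = 0.3),
    inverse = list(snr = 3, depth_exponent = 0.8, loose_factor = 0.6,
                   loading_fraction = 0.05),
    spectral = list(freq_range = c(4, 80), tfr_freqs = seq(5, 79, by = 2),
                    n_cycles = 3, stride_s = 0.05, eog_threshold_uv = 100),
    stats = list(alpha = 0.05, n_randomizations = 1500L,
                 cluster_bands = c("theta", "alpha", "beta", "gamma"),
                 tfr_rois = NULL, run_tfr_stats = TRUE)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values found in the file override [default_config()] defaults
#' (recursively); anything omitted keeps its default.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Per-subject spectral analysis stage
#'
#' Epochs one session (sustained and time-frequency windows, with EOG
#' rejection), applies the inverse operator, and computes: sustained band
#' power per vertex (loose-orientation power summed over the three source
#' components), sign-aligned ROI band power in dB relative to Passive, and
#' the evoked-subtracted, baseline-normalized ROI time-frequency power for
#' the ROIs selected for cluster statistics.
#'
#' @param session \code{sensor_session}.
#' @param inv \code{inverse_operator} for the session's subject.
#' @param mesh \code{cortical_mesh}.
#' @param cfg pipeline configuration, see [default_config()].
#' @return list with \code{vertex_band} (per condition, bands x vertices),
#'   \code{roi_table} (long data frame of dB band power), \code{tfr} (per
#'   condition dB \code{power_estimate}), \code{tfr_units},
#'   \code{roi_units}, \code{kept_counts}.
#' @export
analyze_subject_session <- function(session, inv, mesh, cfg) {
  fs <- session$fs
  sched <- session$schedule
  bands <- band_definitions()
  nv <- mesh$n_vertices
  normal_idx <- seq(1L, 3L * nv, by = 3L)
  roi_units <- unique(data.frame(roi = mesh$roi,
                                 hemisphere = as.character(mesh$hemisphere),
                                 stringsAsFactors = FALSE))
  roi_units <- roi_units[order(roi_units$roi, roi_units$hemisphere), ]

  conds <- c("attend_phoneme", "attend_location", "passive")
  vertex_band <- list()   # per condition: bands x vertices
  roi_band <- list()      # per condition: units x bands
  kept_counts <- integer(0)

  # precompute ROI flip weights (sign alignment) once
  flip_w <- vector("list", nrow(roi_units))
  for (u in seq_len(nrow(roi_units))) {
    verts <- which(mesh$roi == roi_units$roi[u] &
                     mesh$hemisphere == roi_units$hemisphere[u])
    fl <- roi_sign_flips(mesh$normals[verts, , drop = FALSE])
    flip_w[[u]] <- list(verts = verts, w = fl / length(verts))
  }

  for (cond in conds) {
    ep <- segment_epochs(session$sensors, sched, sustained_window(), cond, fs)
    eog <- segment_epochs(session$eog, sched, sustained_window(), cond, fs)
    ep <- reject_artifacts(ep, eog, cfg$spectral$eog_threshold_uv)
    kept_counts[cond] <- length(ep$kept)
    nk <- length(ep$kept); nsamp <- dim(ep$data)[3]
    src_ep <- array(0, c(nk, 3L * nv, nsamp))
    roi_ep <- array(0, c(nk, nrow(roi_units), nsamp))
    for (i in seq_len(nk)) {
      s_all <- apply_inverse(inv, matrix(ep$data[ep$kept[i], , ], ncol = nsamp))
      src_ep[i, , ] <- s_all
      s_norm <- s_all[normal_idx, , drop = FALSE]
      for (u in seq_len(nrow(roi_units)))
        roi_ep[i, u, ] <- crossprod(s_norm[flip_w[[u]]$verts, , drop = FALSE],
                                    flip_w[[u]]$w)
    }
    src_set <- structure(list(data = src_ep, window = sustained_window(),
                              condition = cond, fs = fs, kept = seq_len(nk),
                              rejected = integer(0)), class = "epoch_set")
    pw <- sustained_power(src_set, cfg$spectral$freq_range)
    # collapse loose-orientation components: power summed over the 3
    # components of each vertex
    vert_pw <- pw$values[seq(1L, 3L * nv, 3L), , drop = FALSE] +
      pw$values[seq(2L, 3L * nv, 3L), , drop = FALSE] +
      pw$values[seq(3L, 3L * nv, 3L), , drop = FALSE]
    vert_est <- structure(list(values = vert_pw, freqs_hz = pw$freqs_hz,
                               times_s = NULL, normalization = "raw",
                               n_trials = pw$n_trials), class = "power_estimate")
    vb <- sapply(seq_len(nrow(bands)), function(b)
      band_average(vert_est, bands[b, ]))   # vertices x bands
    vertex_band[[cond]] <- t(vb)            # bands x vertices

    roi_set <- structure(list(data = roi_ep, window = sustained_window(),
                              condition = cond, fs = fs, kept = seq_len(nk),
                              rejected = integer(0)), class = "epoch_set")
    rpw <- sustained_power(roi_set, cfg$spectral$freq_range)
    rb <- sapply(seq_len(nrow(bands)), function(b) band_average(rpw, bands[b, ]))
    roi_band[[cond]] <- matrix(rb, nrow = nrow(roi_units))  # units x bands
  }

  roi_tbl <- do.call(rbind, lapply(c("attend_phoneme", "attend_location"),
    function(cond) {
      db <- 10 * log10(roi_band[[cond]] / roi_band[["passive"]])
      data.frame(subject = session$subject_id,
                 roi = rep(roi_units$roi, times = nrow(bands)),
                 hemisphere = rep(roi_units$hemisphere, times = nrow(bands)),
                 band = rep(bands$name, each = nrow(roi_units)),
                 condition = cond, value_db = as.vector(db),
                 stringsAsFactors = FALSE)
    }))

  # --- TFR of ROI time courses, evoked-subtracted, baseline-normalized ---
  tfr <- NULL
  tfr_units <- NULL
  if (isTRUE(cfg$stats$run_tfr_stats)) {
    tfr_rois <- cfg$stats$tfr_rois
    if (is.null(tfr_rois)) tfr_rois <- cfg$truth$planted_rois
    tu <- roi_units[roi_units$roi %in% tfr_rois, , drop = FALSE]
    tfr <- list()
    for (cond in c("attend_phoneme", "attend_location")) {
      ep <- segment_epochs(session$sensors, sched, tfr_window(), cond, fs)
      eog <- segment_epochs(session$eog, sched, tfr_window(), cond, fs)
      ep <- reject_artifacts(ep, eog, cfg$spectral$eog_threshold_uv)
      nk <- length(ep$kept); nsamp <- dim(ep$data)[3]
      roi_ep <- array(0, c(nk, nrow(tu), nsamp))
      for (i in seq_len(nk)) {
        s_norm <- apply_inverse(inv, matrix(ep$data[ep$kept[i], , ], ncol = nsamp),
                                component = "normal")
        for (u in seq_len(nrow(tu))) {
          uu <- which(roi_units$roi == tu$roi[u] &
                        roi_units$hemisphere == tu$hemisphere[u])
          roi_ep[i, u, ] <- crossprod(s_norm[flip_w[[uu]]$verts, , drop = FALSE],
                                      flip_w[[uu]]$w)
        }
      }
      roi_set <- structure(list(data = roi_ep, window = tfr_window(),
                                condition = cond, fs = fs, kept = seq_len(nk),
                                rejected = integer(0)), class = "epoch_set")
      roi_set <- subtract_evoked(roi_set)
      tp <- tfr_power(roi_set, cfg$spectral$tfr_freqs,
                      n_cycles = cfg$spectral$n_cycles,
                      stride_s = cfg$spectral$stride_s)
      tfr[[cond]] <- db_normalize(tp, "baseline")
    }
    tfr_units <- tu
  }

  list(vertex_band = vertex_band, roi_table = roi_tbl, tfr = tfr,
       tfr_units = tfr_units, roi_units = roi_units, kept_counts = kept_counts)
}

#' Run the full simulate-invert-spectral-cluster pipeline
#'
#' For each subject: simulate a session, estimate the noise covariance from
#' Passive segments, build the depth-weighted loose-orientation inverse,
#' epoch both window types with EOG rejection, compute sustained band power
#' per vertex (loose-orientation power summed over components) and per ROI
#' (sign-aligned normal component, dB vs Passive), and the evoked-subtracted
#' baseline-normalized ROI time-frequency power. Across subjects: the
#' vertex-level cluster randomization test per band (Phoneme vs Location on
#' 10*log10 power), a-priori ROI t tests, time-frequency cluster tests per
#' ROI, and recovery scoring against the planted truth. Deterministic for a
#' fixed master seed.
#'
#' @param config configuration list, see [default_config()].
#' @param seed master seed; fans out per stage and subject.
#' @param out_dir optional directory for tab-delimited result tables and a
#'   parameter log.
#' @param verbose print stage progress.
#' @return list with \code{mesh}, \code{vertex_tests} (per band),
#'   \code{roi_tests}, \code{roi_polarity_tests}, \code{tfr_tests},
#'   \code{recovery}, \code{roi_table}, \code{kept_counts}, \code{config},
#'   \code{seed}.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L, out_dir = NULL,
                         verbose = TRUE) {
  cfg <- utils::modifyList(default_config(), config)
  say <- function(...) if (verbose) message(sprintf(...))
  say("[%s] building mesh and lead field", format(Sys.time(), "%H:%M:%S"))
  mesh <- build_toy_cortex(cfg$mesh$n_vertices_per_hemisphere,
                           seed = derive_seed(seed, "mesh"))
  gain0 <- compute_gain(mesh, cfg$gain$n_sensors, cfg$gain$smoothness,
                        seed = derive_seed(seed, "gain"),
                        falloff = cfg$gain$falloff)
  adjacency <- vertex_adjacency(mesh)
  schedule <- make_event_schedule(cfg$paradigm)
  truth <- do.call(default_truth, cfg$truth)

  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    say("[%s] subject %d/%d: simulate + invert + spectral",
        format(Sys.time(), "%H:%M:%S"), s, cfg$n_subjects)
    gain_s <- perturb_gain(gain0, cfg$gain$subject_gain_sd,
                           seed = derive_seed(seed, "gainp", s))
    session <- generate_session(mesh, gain_s, schedule, truth,
                                noise_spec = cfg$noise,
                                seed = derive_seed(seed, "session", s),
                                fs = cfg$sampling_rate,
                                subject_id = sprintf("s%02d", s))
    ncov <- estimate_noise_covariance(session,
                                      loading_fraction = cfg$inverse$loading_fraction)
    scov <- build_source_covariance(mesh, gain_s,
                                    cfg$inverse$depth_exponent,
                                    cfg$inverse$loose_factor)
    inv <- make_inverse_operator(gain_s, ncov, scov, snr = cfg$inverse$snr)
    subjects[[s]] <- analyze_subject_session(session, inv, mesh, cfg)
    subjects[[s]]$truth <- session$truth
  }

  say("[%s] group statistics", format(Sys.time(), "%H:%M:%S"))
  out <- group_statistics(subjects, mesh, adjacency, cfg, seed)
  out$mesh <- mesh

  if (!is.null(out_dir)) persist_results(out, out_dir)
  out
}

#' Group statistics stage
#'
#' Runs the across-subject inference on persisted per-subject spectral
#' results: the vertex-level cluster randomization test per band (10*log10
#' power, Phoneme vs Location), the a-priori ROI t tests (condition contrast
#' and polarity vs zero), time-frequency cluster tests per selected ROI, and
#' planted-effect recovery scoring. Re-running this stage on the same inputs
#' reproduces identical reports (all randomization seeds derive from the
#' master seed).
#'
#' @param subjects list of [analyze_subject_session()] results, each with a
#'   \code{truth} element attached.
#' @param mesh \code{cortical_mesh}.
#' @param adjacency \code{mesh_adjacency} of the mesh.
#' @param cfg pipeline configuration.
#' @param seed master seed (same fan-out as [run_pipeline()]).
#' @return list with \code{vertex_tests}, \code{roi_tests},
#'   \code{roi_polarity_tests}, \code{tfr_tests}, \code{recovery},
#'   \code{roi_table}, \code{kept_counts}, \code{config}, \code{seed}.
#' @export
group_statistics <- function(subjects, mesh, adjacency, cfg, seed = 1L) {
  bands <- band_definitions()
  vertex_tests <- list()
  for (b in cfg$stats$cluster_bands) {
    bi <- match(b, bands$name)
    A <- t(sapply(subjects, function(su) 10 * log10(su$vertex_band$attend_phoneme[bi, ])))
    B <- t(sapply(subjects, function(su) 10 * log10(su$vertex_band$attend_location[bi, ])))
    vertex_tests[[b]] <- permutation_cluster_test(
      A, B, adjacency, n_randomizations = cfg$stats$n_randomizations,
      alpha_two_tail = cfg$stats$alpha,
      seed = derive_seed(seed, paste0("vstat_", b)))
  }

  roi_table <- do.call(rbind, lapply(subjects, function(su) su$roi_table))
  roi_tests <- roi_band_tests(roi_table, "phoneme_vs_location")
  roi_polarity_tests <- roi_band_tests(roi_table, "active_vs_zero")

  tfr_tests <- NULL
  if (isTRUE(cfg$stats$run_tfr_stats) && !is.null(subjects[[1]]$tfr)) {
    tu <- subjects[[1]]$tfr_units
    freqs <- subjects[[1]]$tfr$attend_phoneme$freqs_hz
    times <- subjects[[1]]$tfr$attend_phoneme$times_s
    lattice <- tf_adjacency(freqs, times)
    tfr_tests <- list()
    for (u in seq_len(nrow(tu))) {
      A <- t(sapply(subjects, function(su) as.vector(su$tfr$attend_phoneme$values[u, , ])))
      B <- t(sapply(subjects, function(su) as.vector(su$tfr$attend_location$values[u, , ])))
      defined <- which(colSums(is.na(A)) == 0 & colSums(is.na(B)) == 0)
      res <- permutation_cluster_test(
        A[, defined, drop = FALSE], B[, defined, drop = FALSE],
        subset_adjacency(lattice, defined),
        n_randomizations = cfg$stats$n_randomizations,
        alpha_two_tail = cfg$stats$alpha,
        seed = derive_seed(seed, "tfrstat", u))
      res$element_map <- data.frame(
        cell = defined,
        freq_hz = freqs[(defined - 1L) %% length(freqs) + 1L],
        time_s = times[(defined - 1L) %/% length(freqs) + 1L])
      tfr_tests[[paste(tu$roi[u], tu$hemisphere[u], sep = ".")]] <- res
    }
  }

  truth <- subjects[[1]]$truth
  tb <- truth_band_name(truth)
  recovery <- evaluate_recovery(vertex_tests[[tb]], truth, mesh,
                                alpha = cfg$stats$alpha,
                                other_band_results = vertex_tests[setdiff(names(vertex_tests), tb)])

  list(vertex_tests = vertex_tests, roi_tests = roi_tests,
       roi_polarity_tests = roi_polarity_tests, tfr_tests = tfr_tests,
       recovery = recovery, roi_table = roi_table,
       kept_counts = t(sapply(subjects, function(su) su$kept_counts)),
       config = cfg, seed = as.integer(seed))
}

truth_band_name <- function(truth) {
  bands <- band_definitions()
  hit <- which(bands$low_hz <= truth$effect_band[1] & bands$high_hz >= truth$effect_band[2])
  if (length(hit)) bands$name[hit[1]] else "alpha"
}

#' Score recovery of planted effects
#'
#' A planted ROI counts as recovered iff at least one of its vertices
#' belongs to a cluster with p <= alpha whose sign matches the planted
#' direction. ROIs touched by any significant cluster outside the planted
#' set are reported as false positives.
#'
#' @param result \code{cluster_test_result} from the vertex-level test in
#'   the planted band.
#' @param truth \code{simulation_truth}.
#' @param mesh \code{cortical_mesh} the test ran on.
#' @param alpha significance level (default 0.05).
#' @param other_band_results optional named list of vertex-level results in
#'   the remaining bands, used for the band-specificity flag.
#' @return list of class \code{recovery_report}: \code{sensitivity},
#'   \code{recovered_rois}, \code{false_positive_rois}, \code{min_cluster_p},
#'   \code{band_specificity}.
#' @export
evaluate_recovery <- function(result, truth, mesh, alpha = 0.05,
                              other_band_results = NULL) {
  sig <- Filter(function(cl) cl$p <= alpha, result$clusters)
  sig_correct <- Filter(function(cl) cl$sign == truth$sign, sig)
  correct_verts <- unique(unlist(lapply(sig_correct, function(cl) cl$members)))
  all_sig_verts <- unique(unlist(lapply(sig, function(cl) cl$members)))
  recovered <- vapply(truth$planted_rois, function(rn)
    any(mesh$roi[correct_verts] == rn), TRUE)
  fp_rois <- setdiff(unique(mesh$roi[all_sig_verts]), truth$planted_rois)
  band_spec <- NA
  if (!is.null(other_band_results)) {
    band_spec <- !any(vapply(other_band_results, function(r)
      any(vapply(r$clusters, function(cl) cl$p <= alpha, TRUE)), TRUE))
  }
  structure(list(sensitivity = mean(recovered),
                 recovered_rois = names(recovered)[recovered],
                 false_positive_rois = fp_rois,
                 min_cluster_p = if (length(result$clusters))
                   min(vapply(result$clusters, function(cl) cl$p, 1)) else NA_real_,
                 band_specificity = band_spec, alpha = alpha),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: sensitivity %.2f (recovered: %s), min cluster p = %s\n",
              x$sensitivity,
              if (length(x$recovered_rois)) paste(x$recovered_rois, collapse = ", ") else "none",
              format(x$min_cluster_p, digits = 3)))
  if (length(x$false_positive_rois))
    cat(sprintf("  false-positive ROIs: %s\n", paste(x$false_positive_rois, collapse = ", ")))
  if (!is.na(x$band_specificity))
    cat(sprintf("  band specificity: %s\n", x$band_specificity))
  invisible(x)
}

persist_results <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(out$config, file.path(out_dir, "config_echo.yaml"))
  for (b in names(out$vertex_tests))
    write_cluster_report(out$vertex_tests[[b]],
                         file.path(out_dir, sprintf("clusters_vertex_%s.tsv", b)))
  utils::write.table(out$roi_table, file.path(out_dir, "roi_band_power.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(out$roi_tests, file.path(out_dir, "roi_tests_phoneme_vs_location.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(out$roi_polarity_tests, file.path(out_dir, "roi_tests_vs_zero.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(out$tfr_tests))
    for (nm in names(out$tfr_tests))
      write_cluster_report(out$tfr_tests[[nm]],
                           file.path(out_dir, sprintf("clusters_tfr_%s.tsv", nm)))
  rec <- out$recovery
  writeLines(c(sprintf("sensitivity\t%g", rec$sensitivity),
               sprintf("min_cluster_p\t%g", rec$min_cluster_p),
               sprintf("recovered_rois\t%s", paste(rec$recovered_rois, collapse = ",")),
               sprintf("false_positive_rois\t%s", paste(rec$false_positive_rois, collapse = ",")),
               sprintf("band_specificity\t%s", rec$band_specificity),
               sprintf("master_seed\t%d", out$seed)),
             file.path(out_dir, "recovery_report.tsv"))
  log_pipeline_parameters(out, file.path(out_dir, "pipeline_log.txt"))
  invisible(out)
}

log_pipeline_parameters <- function(out, path) {
  cfg <- out$config
  lines <- c(
    sprintf("%s oscmeg pipeline run, master seed %d", format(Sys.time()), out$seed),
    sprintf("subjects: %d, mesh: %d vertices/hemisphere, sensors: %d",
            cfg$n_subjects, cfg$mesh$n_vertices_per_hemisphere, cfg$gain$n_sensors),
    sprintf("inverse: snr=%g (lambda^2=%g), depth_exponent=%g, loose_factor=%g, loading=%g",
            cfg$inverse$snr, 1 / cfg$inverse$snr^2, cfg$inverse$depth_exponent,
            cfg$inverse$loose_factor, cfg$inverse$loading_fraction),
    sprintf("spectral: sustained window [%g, %g] s, tfr window [%g, %g] s, stride %g s, n_cycles %g, EOG threshold %g uV",
            sustained_window()[1], sustained_window()[2], tfr_window()[1],
            tfr_window()[2], cfg$spectral$stride_s, cfg$spectral$n_cycles,
            cfg$spectral$eog_threshold_uv),
    sprintf("stats: alpha=%g, n_randomizations=%d, cluster-forming threshold df=%d",
            cfg$stats$alpha, cfg$stats$n_randomizations, cfg$n_subjects - 1),
    sprintf("truth: planted ROIs %s, power ratio %g, band [%g, %g] Hz",
            paste(cfg$truth$planted_rois, collapse = "+"), cfg$truth$power_ratio,
            cfg$truth$effect_band[1], cfg$truth$effect_band[2]),
    sprintf("kept trials per condition per subject:"),
    utils::capture.output(print(out$kept_counts)))
  writeLines(lines, path)
}
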