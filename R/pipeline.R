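#' Configuration of a full macrovascular-connectivity run
#'
#' Collects every stage parameter in one serializable object: phantom spec
#' (or real-data paths), preprocessing band and smoothing kernel, degree
#' threshold and mode, perivascular shell count and structuring element, and
#' the RNG seed. A config round-trips through YAML, and every run manifest
#' embeds the exact config it was produced from.
#'
#' @param phantom a [phantom_spec()] for synthetic runs, or `NULL` when
#'   real-data `paths` are given.
#' @param paths named list of NIfTI paths for real-data runs: `bold`,
#'   `labels` (artery/vein label map), `gm`, `wm`, `csf`, optionally `brain`
#'   and `tr_s`.
#' @param n_sessions number of phantom sessions (seeds `rng_seed + 0:(n-1)`).
#' @param threshold,mode degree parameters, see [degree_map()].
#' @param band numeric pair, bandpass edges in Hz.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param K,connectivity perivascular shell parameters, see [make_shells()].
#' @param occupancy_min downsampling occupancy policy, see
#'   [downsample_mask()] (recorded for provenance; used when fusing external
#'   segmentations).
#' @param rng_seed base seed of the run.
#' @param write_nifti write per-session metric volumes as NIfTI.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), paths = NULL,
                       n_sessions = 1L, threshold = 0.15,
                       mode = c("absolute", "positive"),
                       band = c(0.01, 0.1), fwhm_mm = 6,
                       K = 3L, connectivity = 26L, occupancy_min = "any",
                       rng_seed = 1L, write_nifti = FALSE) {
  cfg <- list(phantom = phantom, paths = paths,
              n_sessions = as.integer(n_sessions),
              threshold = threshold, mode = match.arg(mode),
              band = as.numeric(band), fwhm_mm = fwhm_mm,
              K = as.integer(K), connectivity = as.integer(connectivity),
              occupancy_min = occupancy_min,
              rng_seed = as.integer(rng_seed),
              write_nifti = isTRUE(write_nifti))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  fail <- function(msg) {
    stop(structure(class = c("vasconn_config_error", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  if (is.null(cfg$phantom) && is.null(cfg$paths)) {
    fail("config needs either a phantom spec or real-data paths")
  }
  if (!is.null(cfg$phantom)) {
    validate_phantom_spec(cfg$phantom)
  } else {
    need <- c("bold", "labels", "gm", "wm", "csf")
    missing <- setdiff(need, names(cfg$paths))
    if (length(missing)) {
      fail(paste0("config paths missing: ", paste(missing, collapse = ", ")))
    }
    for (nm in need) {
      if (!file.exists(cfg$paths[[nm]])) {
        fail(paste0("input file not found: ", cfg$paths[[nm]]))
      }
    }
  }
  if (!(cfg$threshold > 0 && cfg$threshold < 1)) fail("threshold must be in (0, 1)")
  if (!(length(cfg$band) == 2L && cfg$band[1] < cfg$band[2])) {
    fail("band must be (lo, hi) with lo < hi")
  }
  if (cfg$n_sessions < 1L) fail("n_sessions must be >= 1")
  if (cfg$K < 1L) fail("K must be >= 1")
  if (!cfg$connectivity %in% c(6L, 18L, 26L)) fail("connectivity must be 6, 18 or 26")
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$phantom <- if (!is.null(x$phantom)) unclass(x$phantom)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$phantom)) x$phantom <- do.call(phantom_spec, x$phantom)
  do.call(run_config, x)
}

# Load one session's inputs: phantom (seed shifted per session) or real data.
load_session <- function(cfg, session) {
  if (!is.null(cfg$phantom)) {
    spec <- cfg$phantom
    spec$rng_seed <- spec$rng_seed + session - 1L
    ph <- make_phantom(spec)
    list(bold = ph$bold, labels = ph$labels, gm = ph$masks$gm,
         wm = ph$masks$wm, csf = ph$masks$csf, brain = ph$masks$brain)
  } else {
    p <- cfg$paths
    bold <- read_bold_nifti(p$bold, tr_s = p$tr_s %||% NULL)
    out <- list(bold = bold,
                labels = read_labels_nifti(p$labels),
                gm = read_mask_nifti(p$gm),
                wm = read_mask_nifti(p$wm),
                csf = read_mask_nifti(p$csf))
    out$brain <- if (!is.null(p$brain)) read_mask_nifti(p$brain)
    out
  }
}

#' Run the full pipeline: data, masks, preprocessing, connectivity, shells
#'
#' Executes, per session: vessel-mask preparation (artery/vein split,
#' GM restriction), preprocessing (nuisance regression, bandpass,
#' smoothing), the seven category connectivity metrics, the four
#' macrovascular-to-GM ratio sets, and the perivascular profiles for both
#' vessel types; then summarizes across sessions. All tabular outputs are
#' written as TSV, and a JSON manifest records the exact config, software
#' version and per-stage voxel accounting. Rerunning with an identical
#' config produces byte-identical TSVs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sessions_cat <- list()
  sessions_ratio <- list()
  shell_rows <- list()
  accounting <- list()
  for (s in seq_len(config$n_sessions)) {
    dat <- load_session(config, s)
    arterial <- label_mask(dat$labels, "artery")
    venous <- label_mask(dat$labels, "vein")
    art_gm <- restrict_to_gm(arterial, dat$gm)
    ven_gm <- restrict_to_gm(venous, dat$gm)
    pre <- preprocess_bold(dat$bold, dat$wm, dat$csf,
                           config$band[1], config$band[2], config$fwhm_mm)
    cats <- category_metrics(pre, art_gm, ven_gm, dat$gm,
                             config$threshold, config$mode)
    ratios <- list("VV:V_GM" = ratio_maps(cats$VV, cats$V_GM),
                   "AA:A_GM" = ratio_maps(cats$AA, cats$A_GM),
                   "AV:A_GM" = ratio_maps(cats$AV, cats$A_GM),
                   "VA:V_GM" = ratio_maps(cats$VA, cats$V_GM))
    prof <- perivascular_profiles(pre, art_gm, ven_gm, dat$gm,
                                  brain = dat$brain, K = config$K,
                                  connectivity = config$connectivity,
                                  threshold = config$threshold,
                                  mode = config$mode)
    for (vt in names(prof)) {
      pr <- as.data.frame(prof[[vt]])
      pr$session <- s
      shell_rows[[length(shell_rows) + 1L]] <- pr
    }
    sessions_cat[[s]] <- cats
    sessions_ratio[[s]] <- ratios
    accounting[[s]] <- list(
      n_artery_gm = mask_count(art_gm), n_vein_gm = mask_count(ven_gm),
      n_gm = mask_count(dat$gm), n_wm = mask_count(dat$wm),
      n_csf = mask_count(dat$csf))
    if (config$write_nifti) {
      for (nm in names(cats)) {
        write_volume_nifti(metric_volume(cats[[nm]], "D"), pre$grid,
                           file.path(out_dir, sprintf("s%02d_D_%s.nii.gz", s, nm)))
      }
    }
  }
  sum_cat <- group_summarize(sessions_cat)
  sum_ratio <- group_summarize(sessions_ratio)
  shells <- do.call(rbind, shell_rows)

  files <- c(category_per_session = "category_metrics_per_session.tsv",
             category_group = "category_metrics_group.tsv",
             ratio_per_session = "ratio_metrics_per_session.tsv",
             ratio_group = "ratio_metrics_group.tsv",
             shell_profiles = "shell_profiles.tsv")
  files <- stats::setNames(file.path(out_dir, files), names(files))
  write_tsv(sum_cat$per_session, files["category_per_session"])
  write_tsv(sum_cat$group, files["category_group"])
  write_tsv(sum_ratio$per_session, files["ratio_per_session"])
  write_tsv(sum_ratio$group, files["ratio_group"])
  write_tsv(shells, files["shell_profiles"])

  manifest <- list(
    package = "vasconn",
    version = as.character(utils::packageVersion("vasconn")),
    config = serializable_config(config),
    accounting = accounting,
    files = as.list(files),
    n_sessions = config$n_sessions)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$summaries <- list(category = sum_cat, ratio = sum_ratio,
                             shells = shells)
  manifest$sessions <- list(category = sessions_cat, ratio = sessions_ratio)
  invisible(manifest)
}

serializable_config <- function(cfg) {
  x <- unclass(cfg)
  if (!is.null(x$phantom)) x$phantom <- unclass(x$phantom)
  x
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary report: box-plot statistics and metric histograms
#'
#' Condenses per-session spatial means into box-plot statistics per category
#' and metric (median, quartiles by linear interpolation, whiskers spanning
#' the full first-to-fourth quartile extent) and bins per-seed metric values
#' into fixed-edge histograms. Metrics undefined in every session are
#' omitted with a warning.
#'
#' @param manifest a manifest returned by [run_pipeline()] (with in-memory
#'   summaries), or a `group_summary` object.
#' @param out_dir optional directory to write `boxplot_stats.tsv` and
#'   histogram TSVs into.
#' @return List with `boxplot_stats` (data.frame) and `histograms` (named
#'   list of data.frames with columns `bin_lo`, `bin_hi`, `count`).
#' @export
make_report <- function(manifest, out_dir = NULL) {
  if (inherits(manifest, "group_summary")) {
    summaries <- list(metrics = manifest)
    sessions <- NULL
  } else {
    summaries <- manifest$summaries[c("category", "ratio")]
    sessions <- manifest$sessions
  }
  box <- list()
  for (su in summaries) {
    ps <- su$per_session
    for (key in unique(paste(ps$category, ps$metric))) {
      d <- ps[paste(ps$category, ps$metric) == key, ]
      v <- d$value[!is.na(d$value)]
      if (length(v) == 0L) {
        warning("make_report: metric ", key, " undefined in every session; omitted")
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      box[[length(box) + 1L]] <- data.frame(
        category = d$category[1], metric = d$metric[1],
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_lo = min(v), whisker_hi = max(v), n_sessions = length(v))
    }
  }
  box <- do.call(rbind, box)
  hists <- list()
  if (!is.null(sessions)) {
    r_edges <- seq(-1, 1, by = 0.05)
    for (nm in names(sessions$category[[1]])) {
      vals <- unlist(lapply(sessions$category, function(cats) {
        c(cats[[nm]]$S_pos, cats[[nm]]$S_neg)
      }))
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        hists[[paste0("S_", nm)]] <- metric_histogram(vals, r_edges)
      }
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(box, file.path(out_dir, "boxplot_stats.tsv"))
    for (nm in names(hists)) {
      write_tsv(hists[[nm]], file.path(out_dir, paste0("hist_", nm, ".tsv")))
    }
  }
  list(boxplot_stats = box, histograms = hists)
}

#' Histogram of metric values over fixed bin edges
#'
#' Bins are left-open, right-closed, with the first edge included; values
#' outside the edges are dropped. The edges travel with the output so a
#' sidecar can record them.
#'
#' @param values numeric vector.
#' @param edges increasing numeric vector of bin edges.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`; attribute `"edges"`.
#' @export
metric_histogram <- function(values, edges) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges))
  h <- graphics::hist(values[values >= edges[1] & values <= edges[length(edges)]],
                      breaks = edges, plot = FALSE)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = h$counts)
  attr(out, "edges") <- edges
  out
}
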