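#' Run the full group decomposition from one configuration
#'
#' Orchestrates an end-to-end group run: load (or simulate) subject
#' matrices, distance-weight and average them, decompose at dimensionality
#' `K`, threshold every grey- and white-matter map with the Gaussian/gamma
#' mixture, hard-parcellate, and write all artifacts plus a manifest
#' recording the configuration hash and seeds.
#'
#' The configuration is a named list (or path to a JSON file) with blocks:
#' \describe{
#'   \item{input}{either `subjects`, a character vector of container paths
#'     holding per-subject connectivity matrices, or `synthetic`, a list of
#'     arguments for [make_toy_spaces()] / [make_ground_truth()]
#'     (`n_per_hemi`, `grid`, `K_true`, `n_subjects`, ...).}
#'   \item{decompose}{`K` (required), optional `d`, `b`, `domain`.}
#'   \item{threshold}{optional `p` (default 0.5) and `n_classes` (default 2).}
#'   \item{seed}{master integer seed; all stage seeds derive from it.}
#'   \item{distance_weight}{logical, apply length weighting before averaging
#'     (default `TRUE` when lengths are available).}
#' }
#'
#' @param config Named list or path to a JSON config file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `components`, `parcellation`,
#'   `thresholds` (per-map mixture fits/masks), and `manifest`.
#' @export
run_group <- function(config, out_dir) {
  config <- load_config(config)
  validate_config(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inp <- gather_inputs(config, seed)
  mats <- inp$matrices
  do_weight <- config$distance_weight %||% !is.null(inp$lengths)
  if (isTRUE(do_weight)) {
    if (is.null(inp$lengths)) stop("distance_weight requested but no lengths")
    mats <- lapply(mats, distance_weight, lengths = inp$lengths)
  }
  avg <- group_average(mats)
  dec <- config$decompose
  comps <- decompose_group(avg, K = dec$K,
                           d = dec$d %||% NULL, b = dec$b %||% NULL,
                           domain = dec$domain %||% "seed",
                           rng_seed = seed + 1L)
  thr_cfg <- config$threshold %||% list()
  p_cut <- thr_cfg$p %||% 0.5
  n_classes <- as.integer(thr_cfg$n_classes %||% 2L)
  thresholds <- list(
    gm = apply_thresholds(comps$gm_maps, p_cut, n_classes),
    wm = apply_thresholds(comps$wm_maps, p_cut, n_classes)
  )
  parc <- hard_parcellation(comps, inp$seed_space)

  save_container(comps, file.path(out_dir, "components.tractica.rds"))
  save_container(parc, file.path(out_dir, "parcellation.tractica.rds"))
  utils::write.csv(threshold_report(thresholds),
                   file.path(out_dir, "threshold_report.csv"),
                   row.names = FALSE)
  gm_masks <- do.call(rbind, lapply(thresholds$gm, function(t) t$mask))
  utils::write.csv(gm_masks, file.path(out_dir, "gm_masks.csv"),
                   row.names = FALSE)
  manifest <- list(config = config, config_hash = rlang::hash(config),
                   seed = seed, package_version =
                     as.character(utils::packageVersion("tractica")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(components = comps, parcellation = parc,
                 thresholds = thresholds, manifest = manifest))
}

apply_thresholds <- function(maps, p_cut, n_classes) {
  lapply(seq_len(nrow(maps)), function(k)
    threshold_map(maps[k, ], p_threshold = p_cut, n_classes = n_classes))
}

threshold_report <- function(thresholds) {
  rows <- list()
  for (kind in names(thresholds)) {
    for (k in seq_along(thresholds[[kind]])) {
      f <- thresholds[[kind]][[k]]$fit
      rows[[length(rows) + 1L]] <- tibble::tibble(
        map_kind = kind, component = k,
        pi_pos = unname(f$pi["pos"] %||% 0), mu = f$mu, sigma = f$sigma,
        converged = f$converged, n_iter = f$n_iter,
        n_suprathreshold = sum(thresholds[[kind]][[k]]$mask))
    }
  }
  do.call(rbind, rows)
}

#' Split-half reliability study
#'
#' Splits the subject list into two equal halves (dropping one subject,
#' with a message, when the count is odd), averages and decomposes each
#' half at every requested dimensionality, and reports per-component
#' matched correlations (grey and white matter), hard-parcellation Dice,
#' and the contiguous random-parcellation null.
#'
#' @param subject_matrices List of per-subject [connectivity_matrix()]
#'   objects (>= 2).
#' @param K_values Integer vector of dimensionalities to test.
#' @param seed_space Seed space (for parcellation and the Voronoi null).
#' @param d,b MIGP options passed to [decompose_group()].
#' @param n_null Voronoi null iterations per K (default 100).
#' @param rng_seed Master seed: the split assignment and every stage seed
#'   derive from it.
#' @return A list of class `tractica_splithalf`: `report` (one row per (K,
#'   component): matched gm/wm correlations), `dice` (per-K Dice table and
#'   means), `null` (per-K Voronoi null mean Dice draws), `split` (subject
#'   indices per half).
#' @export
run_splithalf <- function(subject_matrices, K_values, seed_space,
                          d = NULL, b = NULL, n_null = 100L, rng_seed = 1L) {
  n_sub <- length(subject_matrices)
  if (n_sub < 2L) stop("need at least 2 subject matrices")
  keep <- n_sub - n_sub %% 2L
  if (keep < n_sub)
    message("odd subject count: dropping subject ", n_sub)
  perm <- withr::with_seed(rng_seed, sample.int(keep))
  half1 <- perm[seq_len(keep / 2L)]
  half2 <- perm[keep / 2L + seq_len(keep / 2L)]
  avg1 <- group_average(subject_matrices[half1])
  avg2 <- group_average(subject_matrices[half2])

  report <- list(); dice_rows <- list(); null_rows <- list()
  for (K in K_values) {
    c1 <- decompose_group(avg1, K = K, d = d, b = b, rng_seed = rng_seed + 10L)
    c2 <- decompose_group(avg2, K = K, d = d, b = b, rng_seed = rng_seed + 11L)
    m_gm <- match_components(c1, c2, use = "gm")
    m_wm <- match_components(c1, c2, use = "wm")
    report[[length(report) + 1L]] <- tibble::tibble(
      K = K, component = m_gm$component,
      gm_r = m_gm$abs_r, gm_matched = m_gm$matched,
      wm_r = m_wm$abs_r, wm_matched = m_wm$matched)
    p1 <- hard_parcellation(c1, seed_space)
    p2 <- hard_parcellation(c2, seed_space)
    dd <- dice(p1, p2)
    dice_rows[[length(dice_rows) + 1L]] <- tibble::tibble(
      K = K, mean_dice = dd$mean)
    null_rows[[length(null_rows) + 1L]] <- tibble::tibble(
      K = K, null_mean_dice = voronoi_dice_null(seed_space, K,
                                                n_iter = n_null,
                                                rng_seed = rng_seed + 100L * K))
  }
  structure(list(report = do.call(rbind, report),
                 dice = do.call(rbind, dice_rows),
                 null = do.call(rbind, null_rows),
                 split = list(half1 = half1, half2 = half2),
                 K_values = K_values, rng_seed = rng_seed),
            class = "tractica_splithalf")
}

#' @export
print.tractica_splithalf <- function(x, ...) {
  med <- stats::aggregate(gm_r ~ K, data = x$report, FUN = stats::median)
  cat("<tractica_splithalf> K = {",
      paste(x$K_values, collapse = ", "), "}\n", sep = "")
  for (i in seq_len(nrow(med))) {
    K <- med$K[i]
    cat(sprintf("  K=%d: median gm |r|=%.3f, mean Dice=%.3f, null=%.3f\n",
                K, med$gm_r[i], x$dice$mean_dice[x$dice$K == K],
                mean(x$null$null_mean_dice[x$null$K == K])))
  }
  invisible(x)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

validate_config <- function(config) {
  errors <- character()
  if (is.null(config$input))
    errors <- c(errors, "missing block 'input'")
  else {
    if (is.null(config$input$subjects) && is.null(config$input$synthetic))
      errors <- c(errors, "input needs 'subjects' paths or a 'synthetic' block")
    if (!is.null(config$input$subjects)) {
      missing <- config$input$subjects[!file.exists(config$input$subjects)]
      if (length(missing))
        errors <- c(errors, paste0("missing input path: ", missing))
    }
  }
  if (is.null(config$decompose) || is.null(config$decompose$K))
    errors <- c(errors, "missing decompose$K")
  else if (config$decompose$K < 1)
    errors <- c(errors, "decompose$K must be >= 1")
  if (!is.null(config$threshold$p) &&
      (config$threshold$p < 0 || config$threshold$p > 1))
    errors <- c(errors, "threshold$p must be in [0, 1]")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  invisible(TRUE)
}

gather_inputs <- function(config, seed) {
  if (!is.null(config$input$subjects)) {
    mats <- lapply(config$input$subjects, load_container)
    ss <- mats[[1L]]$seed_space
    return(list(matrices = mats, lengths = NULL, seed_space = ss))
  }
  syn <- config$input$synthetic
  spaces <- make_toy_spaces(syn$n_per_hemi %||% 32L,
                            grid = syn$grid %||% c(5L, 5L, 5L))
  gt <- make_ground_truth(spaces$seed_space, spaces$target_space,
                          K_true = syn$K_true %||% 5L,
                          sparsity = syn$sparsity %||% 0.15,
                          n_subjects = syn$n_subjects %||% 10L,
                          loading_sd = syn$loading_sd %||% 0.5,
                          count_scale = syn$count_scale %||% 5000,
                          distance_decay = syn$distance_decay %||% 0.02,
                          rng_seed = seed + 500L)
  mats <- lapply(seq_len(nrow(gt$subject_loadings)), function(s)
    sample_subject_matrix(gt, s, rng_seed = seed + 600L + s)$matrix)
  list(matrices = mats, lengths = gt$length_matrix,
       seed_space = spaces$seed_space, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
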