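#' Default configuration
#'
#' Bundles the default parameters of every stage: contraction (down-sample
#' 0.8 mm, k = 100, contraction weight 0.5, attraction weight 4 or 10 by
#' profile, 10 steps, termination ratio 0.003), segmentation (PCA
#' neighbourhood 20, 15 mm assignment radius, end down-sampling k = 5),
#' coarse registration (full rotation cube, half-unit translation cube, MSE
#' threshold 0.001, trim fraction 0.1) and fine ICP (20 iterations, sampling
#' limit 50,000, overlap ratio 1, minimum RMS decrease 1e-6).
#'
#' @param profile `"phantom"` or `"human"`; the human profile raises the
#'   initial attraction weight to 10 and applies feature weighting and end
#'   down-sampling.
#' @param seed global seed fanned out to per-stage streams.
#' @param direction `"ct_to_us"` (moving CT aligned onto fixed US, the
#'   default) or `"us_to_ct"`.
#' @return A list of class `skelreg_config`.
#' @export
default_config <- function(profile = c("phantom", "human"), seed = 0,
                           direction = c("ct_to_us", "us_to_ct")) {
  profile <- match.arg(profile)
  direction <- match.arg(direction)
  structure(list(
    contraction = contraction_params(
      w_attract0 = if (profile == "human") 10 else 4),
    segmentation = segmentation_params(),
    goicp = goicp_params(),
    icp = icp_params(),
    direction = direction,
    seed = as.integer(seed),
    profile = profile), class = "skelreg_config")
}

# alias tables: configuration files may use the tool-level key spellings
goicp_aliases <- c("rNode.a" = "rot_corner_a", "rNode.b" = "rot_corner_b",
                   "rNode.c" = "rot_corner_c", "rNode.w" = "rot_width",
                   "tNode.x" = "trans_corner_x", "tNode.y" = "trans_corner_y",
                   "tNode.z" = "trans_corner_z", "tNode.w" = "trans_width",
                   "Goicp.MSEThresh" = "mse_thresh",
                   "Goicp.trimFraction" = "trim_fraction")
icp_aliases <- c("nbMaxIterations" = "max_iter",
                 "adjustScale" = "adjust_scale",
                 "filterOutFarthestPoints" = "filter_farthest",
                 "randomSamplingLimit" = "random_sampling_limit",
                 "finalOverlapRatio" = "final_overlap_ratio",
                 "transformationFilters" = "transformation_filters",
                 "maxThreadCount" = "max_workers",
                 "minRMSDecrease" = "min_rms_decrease")
contraction_aliases <- c("Down sample size" = "voxel_edge",
                         "Nearest neighbor points k" = "k_neighbors",
                         "Initial contraction weight" = "w_contract0",
                         "Initial attraction weight" = "w_attract0",
                         "Max interaction steps" = "max_iter",
                         "Termination ratio" = "termination_ratio")

apply_aliases <- function(x, aliases) {
  nm <- names(x)
  hit <- nm %in% names(aliases)
  nm[hit] <- aliases[nm[hit]]
  names(x) <- nm
  x
}

#' Load a configuration from YAML
#'
#' The YAML mirrors the stage parameter lists (`contraction`,
#' `segmentation`, `goicp`, `icp`, `direction`, `seed`, `profile`).  The
#' tool-level key spellings are accepted as aliases (for example `rNode.a`,
#' `tNode.w`, `Goicp.MSEThresh`, `nbMaxIterations`, `minRMSDecrease`,
#' `Down sample size`), so a parameter table can be pasted directly.
#' Unknown keys are rejected with the offending key named.
#'
#' @param path YAML file path; `NULL` returns [default_config()].
#' @param profile,seed,direction overrides applied after the file is read.
#' @return A `skelreg_config`.
#' @export
load_config <- function(path = NULL, profile = NULL, seed = NULL,
                        direction = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  top_known <- c("contraction", "segmentation", "goicp", "icp", "direction",
                 "seed", "profile")
  bad <- setdiff(names(raw), top_known)
  if (length(bad)) stop("unknown configuration key: '", bad[1], "'")
  profile <- profile %||% raw$profile %||% "phantom"
  seed <- seed %||% raw$seed %||% 0
  direction <- direction %||% raw$direction %||% "ct_to_us"
  cfg <- default_config(profile = profile, seed = seed,
                        direction = direction)

  merge_section <- function(defaults, given, aliases, ctor) {
    if (is.null(given)) return(defaults)
    given <- apply_aliases(given, aliases)
    known <- names(defaults)
    extra <- setdiff(names(given), c(known, "transformation_filters",
                                     "rot_corner_a", "rot_corner_b",
                                     "rot_corner_c", "trans_corner_x",
                                     "trans_corner_y", "trans_corner_z"))
    if (length(extra)) stop("unknown configuration key: '", extra[1], "'")
    # assemble vector-valued corners from scalar aliases
    if (!is.null(given$rot_corner_a)) {
      given$rot_corner <- c(given$rot_corner_a, given$rot_corner_b,
                            given$rot_corner_c)
    }
    if (!is.null(given$trans_corner_x)) {
      given$trans_corner <- c(given$trans_corner_x, given$trans_corner_y,
                              given$trans_corner_z)
    }
    given$rot_corner_a <- given$rot_corner_b <- given$rot_corner_c <- NULL
    given$trans_corner_x <- given$trans_corner_y <- given$trans_corner_z <- NULL
    if (!is.null(given$transformation_filters)) {
      if (as.numeric(given$transformation_filters) != 0)
        stop("transformation_filters must be 0 (no transform filters)")
      given$transformation_filters <- NULL
    }
    if (!is.null(given$final_overlap_ratio) &&
        is.character(given$final_overlap_ratio)) {
      # accept the "100.0/100.0" table spelling
      parts <- as.numeric(strsplit(given$final_overlap_ratio, "/")[[1]])
      given$final_overlap_ratio <- parts[1] / parts[2]
    }
    merged <- utils::modifyList(unclass(defaults), given)
    do.call(ctor, merged[names(merged) %in% names(formals(ctor))])
  }

  cfg$contraction <- merge_section(cfg$contraction, raw$contraction,
                                   contraction_aliases, contraction_params)
  cfg$segmentation <- merge_section(cfg$segmentation, raw$segmentation,
                                    character(0), segmentation_params)
  cfg$goicp <- merge_section(cfg$goicp, raw$goicp, goicp_aliases,
                             goicp_params)
  cfg$icp <- merge_section(cfg$icp, raw$icp, icp_aliases, icp_params)
  cfg
}

#' Register a full evaluation case
#'
#' Extracts feature curves from both clouds (with the configured profile),
#' registers them in the configured direction (default: the moving CT-like
#' cloud onto the fixed US-like cloud), and evaluates the requested metrics.
#'
#' @param case an `eval_case` (or any list with `fixed` and `moving`
#'   [point_cloud]s plus optional tumour fields).
#' @param config a `skelreg_config`.
#' @return List with `result` (a `registration_result` in the configured
#'   direction), `transform_moving_to_fixed`, `report` (an
#'   `evaluation_report`), `features_fixed`, `features_moving`.
#' @export
register_case <- function(case, config = default_config()) {
  if (is.null(case$fixed) || is.null(case$moving))
    stop("[io] case must contain both a fixed and a moving cloud")
  ff <- extract_features(case$fixed, config$contraction, config$segmentation,
                         config$profile)
  fm <- extract_features(case$moving, config$contraction,
                         config$segmentation, config$profile)
  # the optimizer always takes the US-like (fixed) features as the source and
  # the CT-like (moving) features as the target; the direction flag selects
  # which mapping is reported (default: the CT image transformed onto the US)
  res <- with_stage("registration",
                    register_features(ff, fm, config$goicp, config$icp,
                                      seed = config$seed))
  T_mf <- invert_transform(res$transform)
  # the reported rmse stays in the optimisation direction (US features onto
  # CT): the reverse direction is dominated by CT curve segments that the
  # partial US render never saw
  if (identical(config$direction, "ct_to_us")) res$transform <- T_mf
  report <- evaluate_case(case, T_mf, features_moving = fm,
                          features_fixed = ff)
  list(result = res, transform_moving_to_fixed = T_mf, report = report,
       features_fixed = ff, features_moving = fm)
}
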